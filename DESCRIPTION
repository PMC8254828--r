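Package: synapscreen
Title: Proteome-Wide Homer-Binding Motif Screening and Synaptosome
    Proteomics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Re-implements, as a tested and reusable analysis toolkit, the
    computational pipeline of a study linking the Homer1 scaffold to
    ankyrin-G at glutamatergic synapses: proteome-wide scanning for the
    PPXXF short linear motif with a four-species conservation filter,
    hypergeometric gene-set overrepresentation tests, confidence-thresholded
    protein-protein interaction networks ranked by betweenness centrality,
    a TMT synaptosome differential-abundance procedure (WT-mean
    standardization, one-tailed Student's t, two-tier significance
    classification), and deterministic calculators for imaging-derived
    statistics (FRAP normalization and one-phase association fitting,
    mobile fraction, spine morphological-index dynamics, puncta-size
    filtering).  A synthetic-data module generates every input with known
    ground truth so the full pipeline is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
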