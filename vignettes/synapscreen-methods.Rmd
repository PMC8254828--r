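---
title: "Methods: motif screening, synaptosome proteomics and imaging statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif screening, synaptosome proteomics and imaging statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapscreen)
```

`synapscreen` re-implements, as reusable and tested functions, the
computational pipeline of a synaptic-scaffold study built around the Homer
EVH1 domain and its PPXXF ligand motif (Pro-Pro-any-any-Phe), the
five-residue short linear motif through which Homer scaffolds bind partners
such as ankyrin-G 190 at glutamatergic synapses. The pipeline has three
arms: a proteome-wide motif screen with gene-set and network statistics, a
TMT differential-abundance procedure for synaptosome proteomes, and
deterministic calculators for imaging-derived statistics. A synthetic-data
module generates every input with exact ground truth, so the whole pipeline
runs and validates offline.

## Motif scanning and conservation

A motif pattern is an ordered list of per-position constraints (fixed
residue or wildcard); the default is `PPxxF`. `scan_sequence()` reports
*all* occurrences, including overlapping ones, with 1-based inclusive
coordinates — the convention in which the ankyrin-G 190 motif occupies
residues 1605–1609. Matching rules for the ambiguity code `X` are
conservative: `X` in a sequence satisfies a wildcard but never a fixed
residue, so an uncertain residue can never create a motif call.
`rescan_with_substitution()` models point-mutation controls (e.g. the
Pro→Leu and Phe→Arg substitutions that abolish Homer binding) by
re-scanning after a single-residue change.

```{r}
scan_sequence("PPPAFF")                       # overlapping hits both reported
rescan_with_substitution("PPAAF", 5, "R")$after  # F->R kills the motif
```

The conservation step asks whether the motif is preserved across a
species panel (default human, bovine, mouse, rat). The original screen
established conservation by inspecting multiple-sequence alignments, a
procedure whose exact acceptance rule is unpublished, so
`conservation_filter()` defines two explicit, reproducible criteria and
labels them as this package's conventions:

* **presence** (default): every required species' ortholog carries ≥ 1
  hit anywhere;
* **positional**: additionally, some anchor position has a hit within a
  ±`window` residue tolerance (default ±30) in every species — an
  aligner-free approximation of positional correspondence.

Presence-anywhere is the default because it has no hidden alignment
dependence; the window mode is provided for users who want the stricter
reading. Groups missing a required species are counted as non-conserved
with a warning rather than an error, so one incomplete ortholog family
cannot abort a screen.

## Overrepresentation statistics

Enrichment of a query set (e.g. motif-positive proteins) in an annotation
set (e.g. postsynaptic-density proteins, disease risk genes) within a
universe of size $N$ is tested with the one-sided hypergeometric upper
tail, $P(X \ge k)$ for $X \sim \mathrm{Hyper}(N, K, n)$, evaluated in log
space for stability; fold enrichment is $(k/n)/(K/N)$. Two policies are
deliberate:

* **The universe is a mandatory explicit argument.** Published
  enrichment ratios depend entirely on the background; inferring one
  silently would fabricate statistics.
* **Raw p-values by default.** Single-set enrichment figures in this
  literature report unadjusted hypergeometric p-values; for multi-set
  runs `enrichment_table(..., adjust = "BH")` adds a Benjamini–Hochberg
  column.

Because the hypergeometric statistic is discrete, the exact test is
conservative: at $N=1000$, $K=100$, $n=50$ the attained level
$P(p < 0.05)$ under the null is 0.0214, not 0.05. The calibration tests
therefore compare the empirical rejection rate against the exactly
computed attained level (and additionally require it never to exceed the
nominal level); expecting 0.05 itself would be asking the test to be
anti-conservative.

## PPI networks and betweenness

`build_graph()` consumes STRING-style weighted edge lists (0–1000 scores
auto-rescaled to [0, 1]) and keeps edges with confidence ≥ 0.400 by
default, the "medium confidence" convention; duplicates collapse to the
maximum score and self-loops are dropped. Confidence is an inclusion
filter only — shortest paths are unweighted, matching the
Cytoscape-style workflow the screen used, and tied geodesics are counted
fractionally (standard Brandes semantics). Normalized betweenness
divides by $(n_c-1)(n_c-2)/2$ *per connected component* (component size
$n_c$), so the central node of each component scores 1 regardless of how
many other components exist. `seed_subnetwork()` induces the subgraph on
a seed list (optionally with first neighbors), preserving annotation
flags (PSD membership, disease labels, regulation tier, fold change)
used to style exported GraphML.

Published node/edge counts for such networks depend on the interaction
database version used at the time and are treated as worked examples,
not reproduction targets; the end-to-end validation instead uses
generated edge lists whose threshold-passing edge count and planted
module are known exactly.

## TMT differential abundance

The procedure mirrors the study's recipe for 5 WT vs 5 KO synaptosome
TMT proteomes of normalized average reporter intensities:

1. **Complete-case rule**: a protein is testable only if quantified
   (non-missing) in all ten samples; others are listed with reasons.
2. **Standardization**: each protein's ten values are divided by that
   protein's WT mean, so the standardized WT mean is identically 1.
3. **Fold change** = mean of the five standardized KO values.
4. **One-tailed Student's t** with pooled variance, $df = 8$.
5. **Tiers**: strict $p < 0.05$; relaxed $0.05 \le p < 0.1$ (the wider
   cutoff used to admit more interactors into network seeding);
   direction up/down by fold change vs 1.

The recipe's source states "one-tailed" without fixing the tail. The
default here takes the tail in the direction of the observed difference
($p = p_{two}/2$), the only reading under which a single one-tailed test
can yield both up- and down-regulated calls; it is anti-conservative
under the null (p is uniform on $(0, 0.5]$, so the strict tier admits
10% of nulls), which is documented rather than hidden, and fixed-tail
(`"greater"`/`"less"`) and two-tailed modes are provided — the
calibration test verifies exact null uniformity in the fixed-tail mode,
and the analysis drivers report how the significant counts move across
tail choices. Welch's t is available behind a flag; pooled variance is
the default because the recipe names Student's test. A BH-adjusted
column is always emitted for transparency but plays no role in tiering.

Two degenerate cases are resolved explicitly: zero pooled variance with
equal means gives $t = 0$, $p = 1$; zero pooled variance with unequal
means (the noiseless planted-effect case) gives infinite $t$ and the
smallest representable $p$. Both are flagged `zero_variance`.

## Imaging statistics

**FRAP.** `normalize_frap()` applies three steps in order: divide the
bleached-region trace by an unbleached reference frame-wise (cancelling
acquisition photobleaching exactly when both channels fade together),
divide by the mean of the 5 frames before the bleach (pre-bleach level
≡ 1), and subtract the series minimum (floor ≡ 0). The post-bleach
series is fit to the one-phase association model
$Y(t) = \mathrm{plateau}\,(1 - e^{-\mathrm{rate}\,t})$ with bounded
Levenberg–Marquardt; initialization is deterministic (plateau from the
final value, rate from the first half-recovery crossing) with three
deterministic restarts at scaled rates, so identical input always gives
an identical fit. The mobile fraction is reported both ways the field
computes it — from the endpoints,
$100\,(F_{end}-F_0)/(F_{initial}-F_0)$, and from the fitted plateau —
because recovery at the last frame and the asymptotic plateau differ
whenever the recording ends before full plateau. Values above 110% are
flagged as implausible.

**Spine morphometrics.** The morphological index
$M.I. = P^2/(4\pi A)$ equals 1 for a circle (isoperimetric equality) and
$4/\pi \approx 1.273$ for a square; it grows with contour complexity.
"Dynamics" of a per-frame series (perimeter, area or M.I. over the
default 10-minute, 1-frame-per-minute recording) is not given a formula
in the imaging literature this package follows, so the package defines
it as the mean relative absolute successive change
$\frac{1}{T-1}\sum_i |x_{i+1}-x_i|/x_i$ — unit-free and sensitive to
frame-to-frame remodeling rather than slow drift — and exposes SD and CV
alternatives behind the `method` argument. This definition is a package
convention, not a reproduction of the original figure's.

**Puncta.** `filter_puncta()` excludes puncta strictly smaller than
0.006 µm² ("smaller than" read strictly, so the boundary value is
retained) and summarizes counts per compartment, densities per 10 µm of
dendrite and the spine:dendrite count ratio.

## Synthetic data: what it emulates and what it does not

Each generator is deterministic given `(config, seed)`, restores the
caller's RNG state, and emits a truth table covering every generated
entity.

* `gen_motif_proteome()` — random sequences (uniform residue usage) with
  motifs planted at recorded positions. Truth is defined *post hoc* by
  an explicit window-by-window scan rather than by planting intent, so
  accidental background matches are part of the truth, never an
  ambiguity. Defaults: 500 proteins, lengths 100–1000, rate 0.3.
* `gen_ortholog_groups()` — motif-free backgrounds (accidental hits
  regenerated away) with motifs planted in all species (conserved) or
  lost in ≥ 1 species; anchors jitter by ≤ 5 residues so presence and
  positional criteria agree on the truth.
* `gen_null_gene_sets()` — uniform queries without replacement: the
  exact null of the hypergeometric test.
* `gen_tmt_matrix()` — lognormal baselines, multiplicative effect
  (×`effect` up, ×1/`effect` down), multiplicative Gaussian noise of CV
  `cv`. Defaults (3000 proteins, 90 up vs 12 down at 2×, CV 5%, 5 vs 5)
  echo the emulated study's scale, its strong up-regulation skew and the
  effect/noise regime at which its recovery claims are stated.
* `gen_frap_trace()` — pre-bleach frames at 1, post-bleach
  $F_0 + \mathrm{plateau}(1-e^{-\mathrm{rate}\,t})$ every 10 s for
  200 s, additive Gaussian noise, optional shared linear photobleach
  decay (cancelled exactly by normalization).
* `gen_edge_list()` — Erdős–Rényi background with uniform confidences
  plus a planted high-confidence clique; the count of threshold-passing
  edges is recorded exactly.

These generators emulate the *statistical shape* of the real inputs, not
their biology: sequences have no composition bias or domain structure,
TMT noise is homoscedastic with no missingness or batch structure,
ortholog "conservation" is binary, FRAP noise is white, and networks
have no degree heterogeneity beyond the planted module. Passing tests
therefore demonstrate that the implementations compute their definitions
correctly and recover planted truth under the stated noise models — not
that the biological conclusions of any particular dataset are correct.

## Validation problem sizes

The test suite checks every operation against an independent oracle:
brute-force window scans (1000 random sequences ≤ 200 residues), exact
binomial-coefficient enumeration of the hypergeometric tail (all
parameter combinations with $N \le 30$), exhaustive shortest-path
enumeration for betweenness (200 random graphs ≤ 8 nodes), a full
$\binom{10}{5}$ permutation oracle for the pooled t, and closed forms
for the imaging metrics. Calibration uses $10^4$ null gene-set
replicates and a 3000-protein null TMT matrix; parameter recovery uses
100 seeds of a 100-protein, 20-up/5-down, 2×/CV-5% design and 100 noisy
FRAP traces ($\sigma = 0.02$). These sizes give stable Monte-Carlo
bands while keeping the default suite fast.

## Known limitations

* Conservation is sequence-presence-based; no alignment or synteny
  evidence is used, and the positional mode is an approximation.
* The observed-direction one-tailed default is anti-conservative by
  construction; users wanting strict type-I control should use the
  fixed-tail or two-tailed modes (and note that the emulated recipe
  itself used raw, unadjusted p-values).
* The one-phase association model assumes a single recovering pool;
  two-component recoveries will fit poorly (inspect `rms`).
* Puncta and spine metrics start from segmented ROI measurements; no
  pixel-level image processing is performed.
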