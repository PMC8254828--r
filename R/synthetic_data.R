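# Synthetic-data generators: every input the pipeline consumes, produced
# with a known ground truth so all stages are testable offline.  Every
# generator is deterministic given its seed and leaves the caller's RNG
# state untouched.

random_aa <- function(n) sample(AA_CANONICAL, n, replace = TRUE)

random_sequence <- function(len) paste(random_aa(len), collapse = "")

# Instantiate a pattern as a concrete peptide (wildcards filled at random).
instantiate_motif <- function(pattern) {
  res <- pattern$positions
  res[is.na(res)] <- random_aa(sum(is.na(res)))
  paste(res, collapse = "")
}

# Plant a peptide at a 1-based position.
plant_at <- function(sequence, peptide, start) {
  substr(sequence, start, start + nchar(peptide) - 1L) <- peptide
  sequence
}

# Explicit window-by-window scan, used to define generator ground truth
# post hoc (independent of the production scanner's regex path).
brute_scan_starts <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars); m <- pattern$length
  if (m > L) return(integer(0))
  ok <- vapply(seq_len(L - m + 1L), function(s) {
    win <- chars[s:(s + m - 1L)]
    all(ifelse(is.na(pattern$positions), TRUE, win == pattern$positions))
  }, logical(1))
  which(ok)
}

# Random sequence guaranteed motif-free (regenerates on accidental hits;
# accidental PPxxF hits occur in ~2% of 150-residue sequences).
motif_free_sequence <- function(len, pattern) {
  repeat {
    s <- random_sequence(len)
    if (!length(brute_scan_starts(s, pattern))) return(s)
  }
}

#' Generate a synthetic proteome with planted motifs
#'
#' Random amino-acid sequences; a fraction `motif_rate` of proteins gets a
#' motif instance planted at a recorded position.  Accidental matches
#' arising from the random background are deliberately NOT suppressed:
#' the returned `truth` hit table is defined post hoc by an explicit
#' window-by-window scan of every sequence, so scanner output can be
#' compared to it exactly without planting-versus-chance ambiguity.
#'
#' @param n_proteins number of proteins (default 500).
#' @param length_range min/max sequence length (default 100-1000).
#' @param motif_rate fraction of proteins with a planted motif (default 0.3).
#' @param pattern a [slim_pattern()] or pattern string.
#' @param seed RNG seed (default 7).
#' @return list: `proteome` (data.frame `id`, `species`, `sequence`,
#'   `planted`, `planted_start`), `truth` (hit table: `protein_id`,
#'   `start`, `end`, `matched`), `config`.
#' @export
gen_motif_proteome <- function(n_proteins = 500, length_range = c(100, 1000),
                               motif_rate = 0.3, pattern = slim_pattern(),
                               seed = 7) {
  pattern <- as_slim_pattern(pattern)
  stopifnot(motif_rate >= 0, motif_rate <= 1)
  if (length_range[1] < pattern$length) {
    stop_domain("length_range must be at least the pattern length (",
                pattern$length, ")")
  }
  with_seed(seed, {
    lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                   replace = TRUE)
    planted <- stats::runif(n_proteins) < motif_rate
    seqs <- character(n_proteins)
    planted_start <- rep(NA_integer_, n_proteins)
    for (i in seq_len(n_proteins)) {
      s <- random_sequence(lens[i])
      if (planted[i]) {
        pos <- sample.int(lens[i] - pattern$length + 1L, 1L)
        s <- plant_at(s, instantiate_motif(pattern), pos)
        planted_start[i] <- pos
      }
      seqs[i] <- s
    }
    ids <- sprintf("SYN%04d", seq_len(n_proteins))
    truth_rows <- lapply(seq_len(n_proteins), function(i) {
      st <- brute_scan_starts(seqs[i], pattern)
      if (!length(st)) return(NULL)
      data.frame(protein_id = ids[i], start = st,
                 end = st + pattern$length - 1L,
                 matched = substring(seqs[i], st, st + pattern$length - 1L),
                 stringsAsFactors = FALSE)
    })
    list(proteome = data.frame(id = ids, species = "synthetic",
                               sequence = seqs, planted = planted,
                               planted_start = planted_start,
                               stringsAsFactors = FALSE),
         truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
         config = list(n_proteins = n_proteins, length_range = length_range,
                       motif_rate = motif_rate, pattern = pattern$name,
                       seed = seed))
  })
}

#' Generate synthetic ortholog groups with known conservation status
#'
#' Each group has one ortholog per species.  Backgrounds are generated
#' motif-free; conserved groups then receive a motif instance in every
#' species (at positions jittered by at most 5 residues around a common
#' anchor), while non-conserved groups lose it in at least one species
#' (each species independently lost with `per_species_loss_rate`, with one
#' forced loss).  Ground truth is therefore exact by construction.
#'
#' @param n_groups number of groups (default 100).
#' @param conserved_fraction fraction of fully conserved groups (default 0.6).
#' @param per_species_loss_rate loss probability per species in
#'   non-conserved groups (default 0.5; at least one species always loses).
#' @param length_range ortholog length range (default 80-200).
#' @param species species panel (default human/bovine/mouse/rat).
#' @param pattern a [slim_pattern()] or pattern string.
#' @param seed RNG seed.
#' @return list: `groups` (long data.frame `group_id`, `species`, `id`,
#'   `sequence`, `has_motif`), `truth` (data.frame `group_id`,
#'   `conserved`), `config`.
#' @export
gen_ortholog_groups <- function(n_groups = 100, conserved_fraction = 0.6,
                                per_species_loss_rate = 0.5,
                                length_range = c(80, 200),
                                species = c("human", "bovine", "mouse", "rat"),
                                pattern = slim_pattern(), seed = 11) {
  pattern <- as_slim_pattern(pattern)
  stopifnot(conserved_fraction >= 0, conserved_fraction <= 1,
            per_species_loss_rate >= 0, per_species_loss_rate <= 1)
  with_seed(seed, {
    n_cons <- round(n_groups * conserved_fraction)
    conserved <- c(rep(TRUE, n_cons), rep(FALSE, n_groups - n_cons))
    rows <- vector("list", n_groups * length(species))
    r <- 0L
    for (g in seq_len(n_groups)) {
      gid <- sprintf("OG%04d", g)
      len <- sample(seq(length_range[1], length_range[2]), 1L)
      anchor <- sample.int(max(len - pattern$length - 10L, 1L), 1L) + 5L
      if (conserved[g]) {
        lost <- rep(FALSE, length(species))
      } else {
        lost <- stats::runif(length(species)) < per_species_loss_rate
        if (!any(lost)) lost[sample.int(length(species), 1L)] <- TRUE
      }
      for (si in seq_along(species)) {
        s <- motif_free_sequence(len, pattern)
        if (!lost[si]) {
          pos <- min(max(anchor + sample(-5:5, 1L), 1L),
                     len - pattern$length + 1L)
          s <- plant_at(s, instantiate_motif(pattern), pos)
        }
        r <- r + 1L
        rows[[r]] <- data.frame(group_id = gid, species = species[si],
                                id = paste0(gid, "_", species[si]),
                                sequence = s, has_motif = !lost[si],
                                stringsAsFactors = FALSE)
      }
    }
    list(groups = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         truth = data.frame(group_id = sprintf("OG%04d", seq_len(n_groups)),
                            conserved = conserved, stringsAsFactors = FALSE),
         config = list(n_groups = n_groups,
                       conserved_fraction = conserved_fraction,
                       per_species_loss_rate = per_species_loss_rate,
                       length_range = length_range, species = species,
                       pattern = pattern$name, seed = seed))
  })
}

#' Generate null query gene sets for enrichment calibration
#'
#' A universe of `universe_size` identifiers, an annotation set of the
#' first `K`, and `n_replicates` query sets each drawn uniformly without
#' replacement — the null under which the hypergeometric test's type-I
#' rate is calibrated.
#'
#' @param universe_size universe size N (default 1000).
#' @param K annotation size (default 100).
#' @param n query size (default 50).
#' @param n_replicates number of null queries (default 100).
#' @param seed RNG seed.
#' @return list: `universe`, `annotation` (character vectors), `queries`
#'   (list of character vectors), `config`.
#' @export
gen_null_gene_sets <- function(universe_size = 1000, K = 100, n = 50,
                               n_replicates = 100, seed = 13) {
  stopifnot(K <= universe_size, n <= universe_size)
  with_seed(seed, {
    universe <- sprintf("G%05d", seq_len(universe_size))
    annotation <- universe[seq_len(K)]
    queries <- replicate(n_replicates, sample(universe, n), simplify = FALSE)
    list(universe = universe, annotation = annotation, queries = queries,
         config = list(universe_size = universe_size, K = K, n = n,
                       n_replicates = n_replicates, seed = seed))
  })
}

#' Generate a synthetic TMT intensity matrix with planted regulation
#'
#' Emulates the study's 5-vs-5 TMT synaptosome design: a lognormal
#' baseline per protein, KO intensities multiplied by `effect` for the
#' planted up-regulated proteins and by `1/effect` for the planted
#' down-regulated ones, and multiplicative Gaussian noise with coefficient
#' of variation `cv` on every measurement.  Defaults mirror the study's
#' conditions: ~3000 quantified proteins and a strong up-skew among the
#' regulated ones (90 up vs 12 down).
#'
#' @param n_proteins total proteins (default 3000).
#' @param n_up,n_down planted up/down counts (defaults 90 and 12).
#' @param effect multiplicative effect size (default 2; `effect = 1`
#'   produces a global null).
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param n_per_group samples per group (default 5).
#' @param seed RNG seed.
#' @return list: `values` (matrix, proteins x samples, columns WT_1..KO_5),
#'   `groups` (character vector), `truth` (data.frame `protein_id`,
#'   `planted` in up/down/none, `true_effect`), `config`.
#' @export
gen_tmt_matrix <- function(n_proteins = 3000, n_up = 90, n_down = 12,
                           effect = 2, cv = 0.05, n_per_group = 5,
                           seed = 17) {
  stopifnot(n_up + n_down <= n_proteins, effect > 0, cv >= 0)
  with_seed(seed, {
    ids <- sprintf("P%05d", seq_len(n_proteins))
    planted <- rep("none", n_proteins)
    planted[seq_len(n_up)] <- "up"
    if (n_down > 0) planted[n_up + seq_len(n_down)] <- "down"
    true_effect <- ifelse(planted == "up", effect,
                          ifelse(planted == "down", 1 / effect, 1))
    baseline <- stats::rlnorm(n_proteins, meanlog = log(1e5), sdlog = 1)
    n_samples <- 2L * n_per_group
    expected <- cbind(matrix(baseline, n_proteins, n_per_group),
                      matrix(baseline * true_effect, n_proteins, n_per_group))
    noise <- matrix(1 + stats::rnorm(n_proteins * n_samples, sd = cv),
                    n_proteins, n_samples)
    values <- expected * pmax(noise, 1e-3)
    rownames(values) <- ids
    colnames(values) <- c(paste0("WT_", seq_len(n_per_group)),
                          paste0("KO_", seq_len(n_per_group)))
    list(values = values,
         groups = rep(c("WT", "KO"), each = n_per_group),
         truth = data.frame(protein_id = ids, planted = planted,
                            true_effect = true_effect,
                            stringsAsFactors = FALSE),
         config = list(n_proteins = n_proteins, n_up = n_up, n_down = n_down,
                       effect = effect, cv = cv, n_per_group = n_per_group,
                       seed = seed))
  })
}

#' Generate a synthetic FRAP trace with known recovery parameters
#'
#' Pre-bleach frames at intensity 1, post-bleach signal
#' \eqn{F_0 + plateau (1 - e^{-rate\,t})} sampled every `interval_s`
#' seconds for `duration_s` seconds, additive Gaussian noise on the
#' post-bleach frames, and an optional linear acquisition-photobleaching
#' decay applied identically to the bleached and reference channels (so
#' the frame-wise ratio in [normalize_frap()] cancels it exactly).
#'
#' @param plateau recovery amplitude above the post-bleach floor, in
#'   pre-bleach units (0 to 1.1).
#' @param rate association rate constant per second (> 0).
#' @param noise_sd additive Gaussian noise SD on post-bleach frames.
#' @param n_prebleach number of pre-bleach frames (>= 5).
#' @param f0 post-bleach floor (experimental bleach value), default 0.2.
#' @param interval_s frame interval (default 10 s).
#' @param duration_s post-bleach duration (default 200 s).
#' @param photobleach_frac total fractional linear decay of both channels
#'   across the recording (default 0 = none).
#' @param seed RNG seed.
#' @return list: `trace` (a [frap_trace()]), `truth` (list `plateau`,
#'   `rate`, `f0`, `mobile_fraction`: the noiseless endpoint mobile
#'   fraction at `duration_s`), `config`.
#' @export
gen_frap_trace <- function(plateau = 0.7, rate = 0.02, noise_sd = 0,
                           n_prebleach = 5, f0 = 0.2, interval_s = 10,
                           duration_s = 200, photobleach_frac = 0,
                           seed = 19) {
  stopifnot(plateau >= 0, plateau <= 1.1, rate > 0, n_prebleach >= 5)
  with_seed(seed, {
    t_pre <- -rev(seq_len(n_prebleach)) * interval_s
    t_post <- seq(0, duration_s, by = interval_s)
    times <- c(t_pre, t_post)
    signal <- c(rep(1, n_prebleach),
                f0 + plateau * (1 - exp(-rate * t_post)))
    if (noise_sd > 0) {
      signal[-seq_len(n_prebleach)] <- signal[-seq_len(n_prebleach)] +
        stats::rnorm(length(t_post), sd = noise_sd)
    }
    nf <- length(times)
    decay <- 1 - photobleach_frac * (seq_len(nf) - 1) / (nf - 1)
    trace <- frap_trace(time_s = times,
                        bleached = signal * decay,
                        reference = decay,
                        phase = rep(c("pre", "post"),
                                    c(n_prebleach, length(t_post))))
    f_end <- f0 + plateau * (1 - exp(-rate * duration_s))
    list(trace = trace,
         truth = list(plateau = plateau, rate = rate, f0 = f0,
                      mobile_fraction = 100 * (f_end - f0) / (1 - f0)),
         config = list(plateau = plateau, rate = rate, noise_sd = noise_sd,
                       n_prebleach = n_prebleach, f0 = f0,
                       interval_s = interval_s, duration_s = duration_s,
                       photobleach_frac = photobleach_frac, seed = seed))
  })
}

#' Generate a synthetic STRING-style edge list with a planted module
#'
#' Erdős–Rényi background edges with uniform confidence scores, plus an
#' optional planted module: a clique over `module_size` nodes whose edges
#' carry high scores (`module_score_range`), guaranteeing they survive the
#' default 0.400 confidence threshold.  The truth table records the
#' module members and the exact count of edges at or above threshold.
#'
#' @param n_nodes number of nodes (default 50).
#' @param edge_prob background edge probability (default 0.1).
#' @param score_range background confidence score range (default 0-1).
#' @param module_size planted clique size (default 5; 0 disables).
#' @param module_score_range confidence range of module edges
#'   (default 0.8-1).
#' @param threshold confidence threshold recorded in the truth table
#'   (default 0.400).
#' @param seed RNG seed.
#' @return list: `edges` (data.frame `protein1`, `protein2`,
#'   `combined_score`), `truth` (list `module_members`,
#'   `module_internal_edges`, `n_edges_above_threshold`, `threshold`),
#'   `config`.
#' @export
gen_edge_list <- function(n_nodes = 50, edge_prob = 0.1,
                          score_range = c(0, 1), module_size = 5,
                          module_score_range = c(0.8, 1),
                          threshold = 0.400, seed = 23) {
  stopifnot(edge_prob >= 0, edge_prob <= 1, module_size %in% c(0, 2:n_nodes))
  with_seed(seed, {
    nodes <- sprintf("N%03d", seq_len(n_nodes))
    pairs <- utils::combn(nodes, 2)
    present <- stats::runif(ncol(pairs)) < edge_prob
    score <- stats::runif(ncol(pairs), score_range[1], score_range[2])
    members <- character(0)
    if (module_size >= 2) {
      members <- sort(sample(nodes, module_size))
      in_module <- pairs[1, ] %in% members & pairs[2, ] %in% members
      present[in_module] <- TRUE
      score[in_module] <- stats::runif(sum(in_module),
                                       module_score_range[1],
                                       module_score_range[2])
    }
    edges <- data.frame(protein1 = pairs[1, present],
                        protein2 = pairs[2, present],
                        combined_score = score[present],
                        stringsAsFactors = FALSE)
    list(edges = edges,
         truth = list(module_members = members,
                      module_internal_edges = if (length(members)) {
                        choose(length(members), 2)
                      } else 0,
                      n_edges_above_threshold =
                        sum(edges$combined_score >= threshold),
                      threshold = threshold),
         config = list(n_nodes = n_nodes, edge_prob = edge_prob,
                       score_range = score_range, module_size = module_size,
                       module_score_range = module_score_range,
                       threshold = threshold, seed = seed))
  })
}
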