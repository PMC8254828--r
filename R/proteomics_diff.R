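# TMT synaptosome differential-abundance procedure: WT-mean standardization,
# fold change as mean of standardized KO values, one-tailed Student's t,
# two-tier significance classification.

check_groups <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (length(groups) != ncol(values)) {
    stop_domain("groups must label every sample column (", ncol(values),
                " columns, ", length(groups), " labels)")
  }
  if (!all(groups %in% c("WT", "KO"))) {
    stop_domain("group labels must be 'WT' or 'KO'")
  }
  if (sum(groups == "WT") < 2L || sum(groups == "KO") < 2L) {
    stop_domain("need at least 2 samples per group")
  }
  if (is.null(rownames(values))) {
    stop_domain("intensity matrix must have protein ids as rownames")
  }
  invisible(TRUE)
}

#' Read a TMT intensity matrix
#'
#' Reads a CSV/TSV of normalized average reporter intensities (rows =
#' proteins, first column = protein id, remaining columns = samples).
#' Group labels come either from a two-column sidecar file
#' (`sample`, `group`) or from sample names of the form `WT_1`/`KO_3`.
#'
#' @param path matrix file; delimiter inferred from the extension
#'   (`.csv` vs `.tsv`/`.txt`).
#' @param groups_path optional sidecar TSV mapping sample to WT/KO.
#' @return list with `values` (numeric matrix, proteins x samples) and
#'   `groups` (character vector of "WT"/"KO" per column).
#' @export
read_intensity_matrix <- function(path, groups_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- df[[1]]
  if (!is.null(groups_path)) {
    gmap <- utils::read.table(groups_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    groups <- gmap$group[match(colnames(values), gmap$sample)]
  } else {
    groups <- sub("[._-].*$", "", colnames(values))
  }
  if (anyNA(groups) || !all(groups %in% c("WT", "KO"))) {
    stop_domain("could not resolve WT/KO group labels for all samples")
  }
  list(values = values, groups = groups)
}

#' Standardize intensities to the WT mean and compute fold changes
#'
#' Each protein's intensities are divided by that protein's mean over the
#' WT samples, so the standardized WT mean is identically 1; the fold
#' change is the mean of the standardized KO values (1 = no change).
#' Proteins with any missing value are excluded from testing (complete-case
#' rule: a protein must be quantified in all samples), as are proteins with
#' a non-positive WT mean; both are listed with reasons in `excluded`.
#'
#' @param values numeric matrix, proteins x samples, protein ids as
#'   rownames.
#' @param groups character vector of "WT"/"KO" per column.
#' @return list: `standardized` (matrix restricted to testable proteins),
#'   `fold_change` (named numeric), `excluded` (data.frame `protein_id`,
#'   `reason`).
#' @export
standardize_to_wt <- function(values, groups) {
  check_groups(values, groups)
  wt <- groups == "WT"
  ko <- groups == "KO"
  incomplete <- rowSums(is.na(values)) > 0
  wt_mean <- rowMeans(values[, wt, drop = FALSE])
  bad_mean <- !incomplete & (wt_mean <= 0)
  keep <- !incomplete & !bad_mean
  excluded <- data.frame(
    protein_id = c(rownames(values)[incomplete], rownames(values)[bad_mean]),
    reason = c(rep("not quantified in all samples", sum(incomplete)),
               rep("non-positive WT mean", sum(bad_mean))),
    stringsAsFactors = FALSE)
  std <- values[keep, , drop = FALSE] / wt_mean[keep]
  fc <- rowMeans(std[, ko, drop = FALSE])
  list(standardized = std, fold_change = fc, excluded = excluded)
}

#' Pooled-variance Student's t test with a one-tailed option
#'
#' Student's t with pooled variance, df = n1 + n2 - 2 (Welch available via
#' `var_equal = FALSE`).  The t statistic is oriented as KO minus WT.
#' Tail handling:
#' \describe{
#'   \item{`"observed"`}{(default) tail in the direction of the observed
#'     difference, i.e. p = p_two/2.  This matches reporting up- and
#'     down-regulated sets from the same one-tailed test, at the price of
#'     being anti-conservative (null p is uniform on (0, 0.5]).}
#'   \item{`"greater"`/`"less"`}{fixed a-priori direction (KO > WT / KO < WT).}
#'   \item{`"two"`}{ordinary two-tailed p.}
#' }
#' Zero pooled variance is flagged `"zero_variance"`: equal means return
#' t = 0, p = 1; unequal means return infinite t with the smallest
#' representable p (the noiseless planted-effect case).
#'
#' @param wt,ko numeric vectors (>= 2 values each).
#' @param tail one of "observed", "greater", "less", "two".
#' @param var_equal pooled (TRUE, default) or Welch (FALSE).
#' @return list: `t_stat`, `df`, `p_value`, `flag`.
#' @export
pooled_t_test <- function(wt, ko, tail = c("observed", "greater", "less", "two"),
                          var_equal = TRUE) {
  tail <- match.arg(tail)
  if (length(wt) < 2L || length(ko) < 2L) {
    stop_domain("need at least 2 values per group")
  }
  n1 <- length(wt); n2 <- length(ko)
  d <- mean(ko) - mean(wt)
  if (var_equal) {
    sp2 <- ((n1 - 1) * stats::var(wt) + (n2 - 1) * stats::var(ko)) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- stats::var(wt) / n1; v2 <- stats::var(ko) / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else n1 + n2 - 2
  }
  if (!is.finite(se) || se == 0) {
    # degenerate spread: no evidence against equality when the means agree,
    # unbounded evidence when they differ (the noiseless planted case)
    if (d == 0) {
      return(list(t_stat = 0, df = df, p_value = 1, flag = "zero_variance"))
    }
    return(list(t_stat = sign(d) * Inf, df = df,
                p_value = .Machine$double.xmin, flag = "zero_variance"))
  }
  t <- d / se
  p <- switch(tail,
    observed = stats::pt(abs(t), df, lower.tail = FALSE),
    greater  = stats::pt(t, df, lower.tail = FALSE),
    less     = stats::pt(t, df, lower.tail = TRUE),
    two      = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  list(t_stat = t, df = df, p_value = p, flag = "")
}

#' Differential-abundance pipeline for a TMT intensity matrix
#'
#' Runs the full per-protein procedure: WT-mean standardization, fold
#' change as the mean of standardized KO values, Student's t test
#' (one-tailed by default), tier classification (strict: p < `alpha`;
#' relaxed: `alpha` <= p < `relaxed`; else none) and direction (up when
#' fold change > 1, else down).  A Benjamini-Hochberg column `p_bh` is
#' emitted for transparency; tiers use the raw p.
#'
#' @inheritParams standardize_to_wt
#' @inheritParams pooled_t_test
#' @param alpha strict-tier cutoff (default 0.05, strict inequality).
#' @param relaxed relaxed-tier upper bound (default 0.1).
#' @return data.frame `protein_id`, `fold_change`, `t_stat`, `df`,
#'   `p_value`, `p_bh`, `tier`, `direction`, `flag`, in input protein
#'   order; attribute `excluded` carries the exclusion table.
#' @export
diff_abundance <- function(values, groups,
                           tail = c("observed", "greater", "less", "two"),
                           var_equal = TRUE, alpha = 0.05, relaxed = 0.1) {
  tail <- match.arg(tail)
  std <- standardize_to_wt(values, groups)
  wt <- groups == "WT"; ko <- groups == "KO"
  n <- nrow(std$standardized)
  t_stat <- p <- numeric(n); flag <- character(n); df <- numeric(n)
  for (i in seq_len(n)) {
    tt <- pooled_t_test(std$standardized[i, wt], std$standardized[i, ko],
                        tail = tail, var_equal = var_equal)
    t_stat[i] <- tt$t_stat; p[i] <- tt$p_value; df[i] <- tt$df
    flag[i] <- tt$flag
  }
  tier <- ifelse(p < alpha, "strict", ifelse(p < relaxed, "relaxed", "none"))
  direction <- ifelse(std$fold_change > 1, "up", "down")
  out <- data.frame(protein_id = rownames(std$standardized),
                    fold_change = unname(std$fold_change),
                    t_stat = t_stat, df = df, p_value = p,
                    p_bh = stats::p.adjust(p, "BH"),
                    tier = tier, direction = direction, flag = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- std$excluded
  attr(out, "config") <- list(tail = tail, var_equal = var_equal,
                              alpha = alpha, relaxed = relaxed)
  out
}

#' Partition differential-abundance results by tier and direction
#'
#' @param results data.frame from [diff_abundance()].
#' @return list with character vectors `up_strict`, `down_strict`,
#'   `up_relaxed`, `down_relaxed` and a named integer `counts` (also
#'   reporting `strict` and `regulated` totals).
#' @export
classify_regulated <- function(results) {
  pick <- function(tier, dir) {
    results$protein_id[results$tier == tier & results$direction == dir]
  }
  out <- list(up_strict = pick("strict", "up"),
              down_strict = pick("strict", "down"),
              up_relaxed = pick("relaxed", "up"),
              down_relaxed = pick("relaxed", "down"))
  out$counts <- c(up_strict = length(out$up_strict),
                  down_strict = length(out$down_strict),
                  up_relaxed = length(out$up_relaxed),
                  down_relaxed = length(out$down_relaxed),
                  strict = length(out$up_strict) + length(out$down_strict),
                  regulated = sum(results$tier != "none"))
  out
}

#' Regulated protein lists as gene sets
#'
#' Formats the tier/direction partition for [write_gmt()] so regulated
#' lists can be handed to the enrichment and network stages.
#'
#' @param classification list from [classify_regulated()].
#' @return Named list of character vectors (empty tiers dropped).
#' @export
regulated_gene_sets <- function(classification) {
  sets <- classification[c("up_strict", "down_strict",
                           "up_relaxed", "down_relaxed")]
  sets[vapply(sets, length, integer(1)) > 0]
}

#' Volcano-plot coordinates
#'
#' @param results data.frame from [diff_abundance()].
#' @return data.frame `protein_id`, `log2_fold_change`, `neg_log10_p`,
#'   `tier`, `direction`.
#' @export
volcano_data <- function(results) {
  data.frame(protein_id = results$protein_id,
             log2_fold_change = log2(results$fold_change),
             neg_log10_p = -log10(results$p_value),
             tier = results$tier, direction = results$direction,
             stringsAsFactors = FALSE)
}

#' Write a differential-abundance results table to TSV
#'
#' @param results data.frame from [diff_abundance()].
#' @param path output file.
#' @export
write_diff_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
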