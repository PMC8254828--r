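# TMT differential-abundance procedure: standardization, fold change,
# one-tailed pooled t, tier classification.

mk_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("WT_", 1:5), paste0("KO_", 1:5))
  m
}
GROUPS <- rep(c("WT", "KO"), each = 5)

test_that("standardization sets the WT mean to 1 and fold change to the KO mean", {
  m <- mk_matrix(list(flat = rep(1, 10),
                      up2 = c(0.9, 1.0, 1.1, 1.0, 1.0, 1.9, 2.0, 2.1, 2.0, 2.0)))
  std <- standardize_to_wt(m, GROUPS)
  expect_equal(unname(rowMeans(std$standardized[, 1:5])), c(1, 1))
  expect_equal(std$fold_change, c(flat = 1, up2 = 2))

  # scaling an entire protein row leaves the fold change unchanged
  m10 <- m
  m10["up2", ] <- m["up2", ] * 10
  expect_equal(standardize_to_wt(m10, GROUPS)$fold_change, std$fold_change)
})

test_that("incomplete or non-positive proteins are excluded with reasons", {
  m <- mk_matrix(list(good = rep(1, 10),
                      has_na = c(1, NA, rep(1, 8)),
                      zero_wt = c(rep(0, 5), rep(1, 5))))
  std <- standardize_to_wt(m, GROUPS)
  expect_equal(rownames(std$standardized), "good")
  excl <- std$excluded
  expect_equal(excl$reason[excl$protein_id == "has_na"],
               "not quantified in all samples")
  expect_equal(excl$reason[excl$protein_id == "zero_wt"],
               "non-positive WT mean")
})

test_that("pooled one-tailed t matches stats::t.test and a permutation oracle", {
  wt <- c(0.9, 1.0, 1.1, 1.0, 1.0)
  ko <- c(1.9, 2.0, 2.1, 2.0, 2.0)
  tt <- pooled_t_test(wt, ko)
  ref <- t.test(ko, wt, var.equal = TRUE)
  expect_equal(tt$t_stat, unname(ref$statistic))
  expect_equal(tt$df, 8)
  expect_equal(tt$p_value, ref$p.value / 2)
  expect_lt(tt$p_value, 0.001)
  # exhaustive relabeling: the observed split is the most extreme of C(10,5)
  expect_equal(oracle_perm_p(wt, ko), 1 / choose(10, 5))

  # identical (non-constant) groups sit at the one-tailed boundary
  expect_equal(pooled_t_test(wt, wt)$p_value, 0.5)

  # zero pooled variance is flagged with t = 0, p = 1
  const <- pooled_t_test(rep(1, 5), rep(1, 5))
  expect_equal(const$t_stat, 0)
  expect_equal(const$p_value, 1)
  expect_equal(const$flag, "zero_variance")

  expect_error(pooled_t_test(1, c(1, 2)), "at least 2")

  # fixed-direction and two-tailed modes relate as expected
  expect_equal(pooled_t_test(wt, ko, tail = "greater")$p_value, tt$p_value)
  expect_equal(pooled_t_test(wt, ko, tail = "less")$p_value, 1 - tt$p_value)
  expect_equal(pooled_t_test(wt, ko, tail = "two")$p_value, ref$p.value)

  # Welch option matches stats::t.test default
  welch <- pooled_t_test(wt, ko * c(1, 1.2, 0.8, 1.1, 0.9), var_equal = FALSE)
  refw <- t.test(ko * c(1, 1.2, 0.8, 1.1, 0.9), wt)
  expect_equal(welch$t_stat, unname(refw$statistic))
  expect_equal(welch$p_value, refw$p.value / 2)
})

test_that("tier boundaries are strict-left and directions follow fold change", {
  m <- mk_matrix(list(p1 = c(0.9, 1.0, 1.1, 1.0, 1.0, 1.15, 1.2, 1.25, 1.2, 1.2)))
  res <- diff_abundance(m, GROUPS)
  # re-running with alpha equal to the achieved p must demote strict -> relaxed
  res_at_p <- diff_abundance(m, GROUPS, alpha = res$p_value,
                             relaxed = res$p_value + 0.05)
  expect_equal(res_at_p$tier, "relaxed")
  res_above <- diff_abundance(m, GROUPS, alpha = res$p_value * 1.001)
  expect_equal(res_above$tier, "strict")
  expect_equal(res$direction, "up")
})

test_that("classification partitions tiers and recovers planted regulation", {
  m <- mk_matrix(list(a = rep(1, 10), b = rep(c(1, 1.0001), 5)))
  res <- diff_abundance(m, GROUPS)
  cls <- classify_regulated(res)
  expect_equal(unname(cls$counts["regulated"]), 0L)

  gen <- gen_tmt_matrix(n_proteins = 100, n_up = 20, n_down = 5,
                        effect = 2, cv = 0.05, seed = 31)
  res <- diff_abundance(gen$values, gen$groups)
  cls <- classify_regulated(res)
  planted_up <- gen$truth$protein_id[gen$truth$planted == "up"]
  planted_down <- gen$truth$protein_id[gen$truth$planted == "down"]
  expect_gte(length(intersect(c(cls$up_strict, cls$up_relaxed), planted_up)), 19)
  expect_length(intersect(c(cls$up_strict, cls$up_relaxed), planted_down), 0)
  sets <- regulated_gene_sets(cls)
  expect_true(all(lengths(sets) > 0))
  expect_setequal(unlist(sets), res$protein_id[res$tier != "none"])
})

test_that("fold change and p are invariant to row scaling and within-group relabeling", {
  gen <- gen_tmt_matrix(n_proteins = 30, n_up = 5, n_down = 2, seed = 8)
  base <- diff_abundance(gen$values, gen$groups)
  scaled <- diff_abundance(gen$values * 7, gen$groups)
  expect_equal(scaled$fold_change, base$fold_change)
  expect_equal(scaled$p_value, base$p_value)

  perm <- c(sample(1:5), 5 + sample(1:5))
  relab <- diff_abundance(gen$values[, perm], gen$groups[perm])
  expect_equal(relab$p_value, base$p_value)

  # determinism: identical input and config give identical tables
  expect_identical(diff_abundance(gen$values, gen$groups), base)
})

test_that("matrix reading resolves groups from sidecar or sample names", {
  gen <- gen_tmt_matrix(n_proteins = 10, n_up = 2, n_down = 1, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(protein = rownames(gen$values), gen$values,
                   check.names = FALSE)
  write.csv(df, f, row.names = FALSE)
  got <- read_intensity_matrix(f)
  expect_equal(got$values, gen$values)
  expect_equal(got$groups, gen$groups)

  gmap <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample = colnames(gen$values),
                         group = gen$groups),
              gmap, sep = "\t", row.names = FALSE, quote = FALSE)
  got2 <- read_intensity_matrix(f, gmap)
  expect_equal(got2$groups, gen$groups)
})

test_that("volcano coordinates and TSV export are consistent with results", {
  gen <- gen_tmt_matrix(n_proteins = 20, n_up = 4, n_down = 2, seed = 10)
  res <- diff_abundance(gen$values, gen$groups)
  v <- volcano_data(res)
  expect_equal(v$log2_fold_change, log2(res$fold_change))
  expect_equal(v$neg_log10_p, -log10(res$p_value))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_diff_tsv(res, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$protein_id, res$protein_id)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-10)
})
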