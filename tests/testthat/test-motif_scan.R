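# Motif scanning, point-substitution rescans and conservation filtering.

test_that("scan_sequence finds all occurrences with 1-based inclusive coordinates", {
  one <- scan_sequence("PPAAF")
  expect_equal(one$start, 1L)
  expect_equal(one$end, 5L)
  expect_equal(one$matched, "PPAAF")

  expect_equal(nrow(scan_sequence("AAAAA")), 0L)
  expect_equal(nrow(scan_sequence("PPA")), 0L)  # pattern longer than sequence

  # overlapping hits are all reported, sorted by start
  two <- scan_sequence("PPPAFF")
  expect_equal(two$start, c(1L, 2L))
  expect_equal(two$matched, c("PPPAF", "PPAFF"))
})

test_that("the ambiguity code X never satisfies a fixed residue but always a wildcard", {
  expect_equal(scan_sequence("PPXXF")$start, 1L)      # wildcards accept X
  expect_equal(nrow(scan_sequence("PPAAX")), 0L)      # X is not F
  expect_equal(nrow(scan_sequence("XPAAF")), 0L)      # X is not P
})

test_that("invalid sequences and patterns are rejected with position information", {
  expect_error(scan_sequence("PPA1F"), "position 4")
  expect_error(scan_sequence("PP AF"), "position 3")
  expect_error(scan_sequence(""), "non-empty")
  expect_error(slim_pattern("PP1xF"), "invalid pattern character")
  expect_error(scan_proteome(data.frame(id = c("a", "a"),
                                        sequence = c("PPAAF", "AAAAA"))),
               "unique")
})

test_that("custom patterns and wildcard syntax work", {
  p <- slim_pattern("Gx.G", name = "toy")
  hits <- scan_sequence("AGAAGA", p)
  expect_equal(hits$start, 2L)
  expect_equal(hits$pattern, "toy")
})

test_that("point substitutions destroy or spare hits as the pattern dictates", {
  # F at the last fixed position is required
  r <- rescan_with_substitution("PPAAF", 5, "R")
  expect_equal(nrow(r$before), 1L)
  expect_equal(nrow(r$after), 0L)

  # wildcard positions tolerate substitution
  r <- rescan_with_substitution("PPAAF", 3, "G")
  expect_equal(nrow(r$after), 1L)
  expect_equal(r$after$matched, "PPGAF")

  # overlapping case: killing the first P leaves the second hit
  r <- rescan_with_substitution("PPPAFF", 1, "A")
  expect_equal(nrow(r$before), 2L)
  expect_equal(r$after$start, 2L)
  # oracle agreement on both sequences
  expect_equal(r$before$start, oracle_scan_starts("PPPAFF"))
  expect_equal(r$after$start, oracle_scan_starts(r$mutated_sequence))

  expect_error(rescan_with_substitution("PPAAF", 6, "A"), "out of range")
  expect_error(rescan_with_substitution("PPAAF", 2, "X"), "canonical")
})

test_that("scan_sequence matches the brute-force window oracle on random sequences", {
  set.seed(42)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  # enrich P/F so motifs actually occur by chance
  probs <- ifelse(aa %in% c("P", "F"), 6, 1)
  for (i in 1:300) {
    len <- sample(5:200, 1)
    s <- paste(sample(aa, len, replace = TRUE, prob = probs), collapse = "")
    hits <- scan_sequence(s)
    expect_identical(hits$start, as.integer(oracle_scan_starts(s)))
    # coordinate round-trip
    if (nrow(hits)) {
      expect_identical(substring(s, hits$start, hits$end), hits$matched)
    }
  }
})

test_that("appending residues never removes existing hits", {
  set.seed(43)
  for (i in 1:50) {
    s <- paste(sample(c("P", "F", "A", "G"), 30, replace = TRUE), collapse = "")
    before <- scan_sequence(s)$start
    extended <- scan_sequence(paste0(s, "PAYF"))$start
    expect_true(all(before %in% extended))
  }
})

test_that("conservation filter requires the motif in every required species", {
  mk <- function(gid, seqs, species = c("human", "bovine", "mouse", "rat")) {
    data.frame(group_id = gid, species = species[seq_along(seqs)],
               sequence = seqs, stringsAsFactors = FALSE)
  }
  pad <- function(core) paste0("GG", core, "GG")
  all4 <- mk("g1", rep(pad("PPAAF"), 4))
  lost1 <- mk("g2", c(rep(pad("PPAAF"), 3), pad("PLAAF")))
  groups <- rbind(all4, lost1)

  expect_equal(conservation_filter(groups), "g1", ignore_attr = TRUE)

  # smaller required set is less stringent (superset relation)
  few <- conservation_filter(groups, required_species = c("human", "bovine"))
  expect_true(all(conservation_filter(groups) %in% few))
  expect_setequal(few, c("g1", "g2"))

  # missing species: warned, treated as non-conserved
  expect_warning(
    res <- conservation_filter(mk("g3", rep(pad("PPAAF"), 3),
                                  species = c("human", "bovine", "mouse"))),
    "missing required species")
  expect_equal(length(res), 0L)
})

test_that("positional conservation mode enforces a common motif location", {
  far <- paste0(strrep("G", 100), "PPAAF", strrep("G", 10))
  near <- paste0("G", "PPAAF", strrep("G", 109))
  groups <- data.frame(group_id = "g1",
                       species = c("human", "bovine", "mouse", "rat"),
                       sequence = c(near, near, near, far),
                       stringsAsFactors = FALSE)
  expect_equal(conservation_filter(groups, mode = "presence"), "g1",
               ignore_attr = TRUE)
  expect_equal(length(conservation_filter(groups, mode = "positional",
                                          window = 30)), 0L)
  expect_equal(conservation_filter(groups, mode = "positional", window = 120),
               "g1", ignore_attr = TRUE)
})

test_that("conservation filter recovers exactly the planted conserved groups", {
  gen <- gen_ortholog_groups(n_groups = 10, conserved_fraction = 0.6, seed = 5)
  got <- conservation_filter(gen$groups)
  expect_setequal(got, gen$truth$group_id[gen$truth$conserved])
  expect_equal(sum(gen$truth$conserved), 6)
  # positional mode agrees here: planted anchors are jittered by <= 5
  expect_setequal(conservation_filter(gen$groups, mode = "positional"), got)
})

test_that("FASTA round-trips ids, species tokens and sequences", {
  prot <- data.frame(id = c("AnkG", "Homer1"),
                     species = c("human", NA),
                     sequence = c("MPPAAFGG", "MAAAA"),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_proteome_fasta(prot, f)
  back <- read_proteome_fasta(f)
  expect_equal(back, prot)

  hits_file <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(scan_proteome(prot), hits_file)
  tab <- read.delim(hits_file)
  expect_equal(tab$protein_id, "AnkG")
  expect_equal(tab$start, 2L)
})
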