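# Graph construction, betweenness centrality and seeded subnetworks.

edges_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(protein1 = m[, 1], protein2 = m[, 2],
             combined_score = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

test_that("build_graph thresholds inclusively, collapses duplicates, drops loops", {
  g <- build_graph(edges_df("A", "B", 0.9, "B", "C", 0.3))
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1L)

  # keep_nodes retains an isolated node below threshold
  g2 <- build_graph(edges_df("A", "B", 0.9, "B", "C", 0.3), keep_nodes = "C")
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
  expect_equal(igraph::degree(g2)[["C"]], 0)

  # duplicate pair (either orientation) keeps the max score
  g3 <- build_graph(edges_df("A", "B", 0.5, "B", "A", 0.7))
  expect_equal(igraph::ecount(g3), 1L)
  expect_equal(igraph::E(g3)$score, 0.7)

  # threshold is inclusive; self-loops dropped with a message
  g4 <- build_graph(edges_df("A", "B", 0.4), threshold = 0.4)
  expect_equal(igraph::ecount(g4), 1L)
  expect_message(g5 <- build_graph(edges_df("A", "A", 0.9, "A", "B", 0.9)),
                 "self-loop")
  expect_equal(igraph::ecount(g5), 1L)

  expect_error(build_graph(edges_df("A", "B", 1.2)), "\\[0, 1\\]")
})

test_that("STRING-style edge files are parsed with scale auto-detection", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "Ank3\tHomer1\t900", "Shank3\tHomer1\t400"), f)
  e <- read_string_edges(f)
  expect_equal(e$combined_score, c(0.9, 0.4))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score",
               "A\tB\t0.9", "A\tC\tnot_a_number"), f2)
  expect_error(read_string_edges(f2), "line 3")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein1\tprotein2\tcombined_score", "A\tB"), f3)
  expect_error(read_string_edges(f3), "malformed edge row at line 2")
})

test_that("betweenness matches closed-form values on canonical graphs", {
  path3 <- build_graph(edges_df("A", "B", 1, "B", "C", 1))
  bt <- betweenness_table(path3)
  expect_equal(bt$betweenness[bt$node == "B"], 1)
  expect_equal(bt$betweenness[bt$node != "B"], c(0, 0))
  expect_equal(bt$betweenness_normalized[bt$node == "B"], 1)

  # star: center carries all C(4,2) = 6 leaf pairs; leaves score 0
  star <- build_graph(edges_df("C0", "L1", 1, "C0", "L2", 1,
                               "C0", "L3", 1, "C0", "L4", 1))
  bs <- betweenness_table(star)
  expect_equal(bs$betweenness[bs$node == "C0"], 6)
  expect_equal(max(bs$betweenness[bs$node != "C0"]), 0)

  # complete graph: every pair is directly connected
  k5 <- do.call(rbind, lapply(combn(LETTERS[1:5], 2, simplify = FALSE),
                              function(p) edges_df(p[1], p[2], 1)))
  expect_equal(betweenness_table(build_graph(k5))$betweenness, rep(0, 5))

  expect_equal(nrow(betweenness_table(build_graph(edges_df("A", "B", 0.1)))), 0L)
})

test_that("normalization is per connected component", {
  # two components: a 3-path (n_c = 3) and a 5-path (n_c = 5)
  g <- build_graph(edges_df("A", "B", 1, "B", "C", 1,
                            "V", "W", 1, "W", "X", 1, "X", "Y", 1, "Y", "Z", 1))
  bt <- betweenness_table(g)
  get <- function(n, col) bt[[col]][bt$node == n]
  expect_equal(get("B", "betweenness_normalized"), 1)        # 1 / C(2,2)
  expect_equal(get("X", "betweenness"), 4)                   # middle of 5-path
  expect_equal(get("X", "betweenness_normalized"), 4 / 6)    # (5-1)(5-2)/2
})

test_that("betweenness equals exhaustive shortest-path enumeration on random graphs", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    rg <- random_graph(n, runif(1, 0.25, 0.7))
    if (is.null(rg$edges)) next
    g <- build_graph(rg$edges, keep_nodes = rownames(rg$adj))
    bt <- betweenness_table(g)
    oracle <- oracle_betweenness(rg$adj)
    expect_equal(bt$betweenness[match(names(oracle), bt$node)],
                 unname(oracle), tolerance = 1e-10)
  }
})

test_that("tree betweenness sums to the total interior path length", {
  # on a tree each pair has one geodesic; summed betweenness counts its
  # interior nodes, so the total equals sum over pairs of (path length - 1)
  set.seed(100)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    # random recursive tree
    edges <- do.call(rbind, lapply(2:n, function(v) {
      edges_df(LETTERS[sample(v - 1, 1)], LETTERS[v], 1)
    }))
    g <- build_graph(edges)
    d <- igraph::distances(g, weights = NA)
    expected <- sum(d[upper.tri(d)] - 1)
    expect_equal(sum(betweenness_table(g)$betweenness), expected)
  }
})

test_that("build/export round-trips (idempotent rebuild)", {
  gen <- gen_edge_list(n_nodes = 30, edge_prob = 0.15, seed = 4)
  g <- build_graph(gen$edges)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edges_tsv(g, f)
  g2 <- build_graph(read_string_edges(f))
  # same node set and same scored edges
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  el1 <- igraph::as_data_frame(g); el2 <- igraph::as_data_frame(g2)
  key <- function(d) sort(paste(pmin(d$from, d$to), pmax(d$from, d$to),
                                round(d$score, 9)))
  expect_equal(key(el2), key(el1))
})

test_that("seeded subnetworks induce the expected nodes and edges", {
  g <- build_graph(edges_df("A", "B", 1, "B", "C", 1, "C", "D", 1),
                   keep_nodes = c("I1", "I2"))
  # seeds that are isolated nodes: nodes kept, no edges
  iso <- seed_subnetwork(g, c("I1", "I2"))
  expect_equal(igraph::vcount(iso), 2L)
  expect_equal(igraph::ecount(iso), 0L)

  # induced subgraph on a path
  sub <- seed_subnetwork(g, c("A", "B", "C"))
  expect_equal(igraph::ecount(sub), 2L)

  # first neighbors pull in D via C
  subn <- seed_subnetwork(g, "C", include_first_neighbors = TRUE)
  expect_setequal(igraph::V(subn)$name, c("B", "C", "D"))

  # all nodes reproduce the graph
  all_sub <- seed_subnetwork(g, igraph::V(g)$name)
  expect_equal(igraph::vcount(all_sub), igraph::vcount(g))
  expect_equal(igraph::ecount(all_sub), igraph::ecount(g))

  expect_warning(empty <- seed_subnetwork(g, "ZZZ"), "none of the seeds")
  expect_equal(igraph::vcount(empty), 0L)
})

test_that("node annotations are carried as vertex attributes and survive induction", {
  g <- build_graph(edges_df("Ank3", "Homer1", 1, "Shank3", "Homer1", 1))
  ann <- data.frame(node = c("Ank3", "Shank3"),
                    is_psd = c(TRUE, TRUE),
                    regulation = c("up", "down"),
                    significance_tier = c("relaxed", "strict"),
                    fold_change = c(1.2, 0.8),
                    stringsAsFactors = FALSE)
  g <- annotate_nodes(g, ann)
  expect_equal(igraph::V(g)$regulation[igraph::V(g)$name == "Shank3"], "down")
  sub <- seed_subnetwork(g, c("Ank3", "Homer1"))
  expect_equal(igraph::V(sub)$fold_change[igraph::V(sub)$name == "Ank3"], 1.2)

  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
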