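# Independent oracles, deliberately implemented with different algorithms
# than the package (explicit window loops, binomial-coefficient
# enumeration, exhaustive path enumeration, exhaustive relabeling).

# Brute-force sliding-window motif scan: returns 1-based start positions.
oracle_scan_starts <- function(sequence, pattern_str = "PPxxF") {
  pat <- strsplit(pattern_str, "", fixed = TRUE)[[1]]
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  m <- length(pat)
  L <- length(chars)
  starts <- integer(0)
  if (L < m) return(starts)
  for (s in seq_len(L - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (pat[j] %in% c("x", ".")) next
      if (chars[s + j - 1L] != pat[j]) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# Exact upper-tail hypergeometric probability by direct enumeration of the
# pmf with binomial coefficients.
oracle_hyper_upper <- function(N, K, n, k) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Betweenness by exhaustive enumeration: list every simple path between
# each node pair, keep the shortest, count fractional pass-through.
# adj: symmetric logical adjacency matrix with dimnames.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bw <- stats::setNames(numeric(n), rownames(adj))
  if (n < 3) return(bw)
  all_paths <- function(s, t) {
    res <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- path
        return(invisible())
      }
      for (w in which(adj[v, ])) {
        if (!(w %in% path)) rec(c(path, w))
      }
    }
    rec(s)
    res
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      ps <- all_paths(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, length, integer(1))
      geodesics <- ps[lens == min(lens)]
      sigma <- length(geodesics)
      for (p in geodesics) {
        inner <- p[-c(1, length(p))]
        bw[inner] <- bw[inner] + 1 / sigma
      }
    }
  }
  bw
}

# Random undirected graph as adjacency matrix + edge data.frame.
random_graph <- function(n, p) {
  adj <- matrix(FALSE, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  edges <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        adj[i, j] <- adj[j, i] <- TRUE
        edges <- rbind(edges, data.frame(protein1 = LETTERS[i],
                                         protein2 = LETTERS[j],
                                         combined_score = 1,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  list(adj = adj, edges = edges)
}

# Exact permutation p-value for the pooled-t group comparison over all
# C(n1+n2, n1) relabelings, one-sided in the direction of the observed
# difference.
oracle_perm_p <- function(wt, ko) {
  vals <- c(wt, ko)
  n1 <- length(wt)
  pooled_t <- function(a, b) {
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    (mean(b) - mean(a)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  t_obs <- pooled_t(wt, ko)
  idx <- utils::combn(length(vals), n1)
  t_perm <- apply(idx, 2, function(ii) pooled_t(vals[ii], vals[-ii]))
  mean(sign(t_obs) * t_perm >= abs(t_obs))
}

# Convenience: scan hit starts for one protein id from a package hit table.
hits_starts <- function(hits, id) sort(hits$start[hits$protein_id == id])
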