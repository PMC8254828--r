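# Hypergeometric gene-set overrepresentation tests (PSD and disease-gene
# enrichment of PPXXF-motif proteins; PSD enrichment among regulated
# proteins).

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` of which `K` carry the annotation, the probability of
#' observing `k` or more annotated genes.  Evaluated in log space
#' (`phyper(..., log.p = TRUE)`) for numerical stability at extreme tails.
#'
#' @param N universe size.
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param k observed overlap.
#' @return The one-sided overrepresentation p-value, in (0, 1].
#' @examples
#' hypergeom_upper_tail(10, 4, 3, 2)  # 40/120
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  for (v in list(N = N, K = K, n = n, k = k)) {
    stopifnot(is.numeric(v), length(v) == 1L, v == round(v), v >= 0)
  }
  if (K > N) stop_domain("bounds violated: K <= N required (K=", K, ", N=", N, ")")
  if (n > N) stop_domain("bounds violated: n <= N required (n=", n, ", N=", N, ")")
  if (k > min(K, n)) {
    stop_domain("bounds violated: k <= min(K, n) required (k=", k,
                ", K=", K, ", n=", n, ")")
  }
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then members, tab-separated.
#' Identifiers are case-normalized to uppercase on load.
#'
#' @param path GMT file.
#' @return Named list of character vectors of members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_domain("malformed GMT line (need name, description, >=1 member): ",
                  substr(l, 1, 60))
    }
    unique(toupper(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene-set overrepresentation test
#'
#' Intersects query and annotation with an explicit universe, counts the
#' overlap and returns the one-sided (upper-tail) hypergeometric p-value
#' together with fold enrichment `(k/n)/(K/N)`.  The universe is a mandatory
#' input: it is never inferred, because the choice of background determines
#' the statistic.  Identifiers are case-normalized; identifiers absent from
#' the universe are dropped and reported in the `discarded` attribute.
#'
#' @param query character vector (or single-set list) of query identifiers.
#' @param annotation character vector of annotated identifiers.
#' @param universe character vector defining the background.
#' @param set_name label for the result row.
#' @return One-row data.frame: `set_name`, `N`, `K`, `n`, `k`,
#'   `fold_enrichment`, `p_value`, `flag` (`"empty_query"` when no query
#'   identifier is in the universe, else `""`).  Attribute `discarded`
#'   lists dropped query/annotation identifiers.
#' @examples
#' enrichment_test(c("a", "b"), c("b", "c"), letters[1:10])
#' @export
enrichment_test <- function(query, annotation, universe, set_name = "query") {
  norm <- function(x) unique(toupper(unlist(x, use.names = FALSE)))
  query <- norm(query); annotation <- norm(annotation); universe <- norm(universe)
  if (!length(universe)) stop_domain("universe must be non-empty")
  q_in <- intersect(query, universe)
  a_in <- intersect(annotation, universe)
  discarded <- list(query = setdiff(query, universe),
                    annotation = setdiff(annotation, universe))
  N <- length(universe); K <- length(a_in); n <- length(q_in)
  k <- length(intersect(q_in, a_in))
  if (n == 0L) {
    res <- data.frame(set_name = set_name, N = N, K = K, n = 0L, k = 0L,
                      fold_enrichment = 0, p_value = 1, flag = "empty_query",
                      stringsAsFactors = FALSE)
  } else {
    fold <- if (K == 0L) 0 else (k / n) / (K / N)
    res <- data.frame(set_name = set_name, N = N, K = K, n = n, k = k,
                      fold_enrichment = fold,
                      p_value = hypergeom_upper_tail(N, K, n, k),
                      flag = "", stringsAsFactors = FALSE)
  }
  attr(res, "discarded") <- discarded
  res
}

#' Overrepresentation tests for several query sets
#'
#' Runs [enrichment_test()] per query set against one annotation and
#' universe.  Raw hypergeometric p-values are reported (the convention in
#' single-set enrichment figures); `adjust = "BH"` adds a
#' Benjamini-Hochberg column for multi-set runs.
#'
#' @param queries named list of character vectors.
#' @param annotation,universe as in [enrichment_test()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame, one row per query set; `p_adjust` column when
#'   `adjust = "BH"`.
#' @export
enrichment_table <- function(queries, annotation, universe,
                             adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.list(queries), !is.null(names(queries)))
  rows <- lapply(names(queries), function(nm) {
    enrichment_test(queries[[nm]], annotation, universe, set_name = nm)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (adjust == "BH") out$p_adjust <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Write an enrichment results table to TSV
#'
#' @param results data.frame from [enrichment_test()]/[enrichment_table()].
#' @param path output file.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
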