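# Confidence-thresholded protein-protein interaction networks and
# betweenness-centrality hub ranking (STRING-style edge lists, Cytoscape-style
# seeded subnetworks).

#' Read a STRING-style edge list
#'
#' Expects tab-separated columns `protein1`, `protein2`, `combined_score`.
#' STRING exports scores as integers 0-1000; these are auto-detected (any
#' score > 1) and divided by 1000 so scores are always on [0, 1].
#' Malformed rows are reported with their line number.
#'
#' @param path TSV file with a header row.
#' @return data.frame `protein1`, `protein2`, `combined_score` (numeric in
#'   [0, 1]).
#' @export
read_string_edges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop_domain("empty edge file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("protein1", "protein2", "combined_score")
  idx <- match(need, header)
  if (anyNA(idx)) {
    stop_domain("edge file must have columns protein1, protein2, ",
                "combined_score; got: ", paste(header, collapse = ", "))
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < max(idx)) {
      stop_domain("malformed edge row at line ", i, ": ", lines[i])
    }
    sc <- suppressWarnings(as.numeric(f[idx[3]]))
    if (is.na(sc)) {
      stop_domain("non-numeric combined_score at line ", i, ": ", f[idx[3]])
    }
    data.frame(protein1 = f[idx[1]], protein2 = f[idx[2]],
               combined_score = sc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (any(out$combined_score > 1)) {
    out$combined_score <- out$combined_score / 1000
  }
  if (any(out$combined_score < 0 | out$combined_score > 1)) {
    stop_domain("combined_score outside [0, 1] after scale detection")
  }
  out
}

#' Build a confidence-thresholded PPI graph
#'
#' Retains edges with confidence >= `threshold` (inclusive; default 0.400,
#' the STRING "medium confidence" cutoff), collapses duplicate pairs keeping
#' the maximum score, and drops self-loops with a message.  Confidence is
#' used only as an inclusion filter, never as a path length.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score` in [0, 1] (see [read_string_edges()]).
#' @param threshold minimum retained confidence.
#' @param keep_nodes optional identifiers kept as (possibly isolated) nodes
#'   even if all their edges fall below threshold.
#' @return An undirected [igraph::igraph] with edge attribute `score`.
#' @export
build_graph <- function(edges, threshold = 0.400, keep_nodes = character(0)) {
  stopifnot(is.data.frame(edges),
            all(c("protein1", "protein2", "combined_score") %in% names(edges)))
  if (any(edges$combined_score < 0 | edges$combined_score > 1)) {
    stop_domain("edge scores must lie in [0, 1]")
  }
  loops <- edges$protein1 == edges$protein2
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges)) {
    a <- pmin(edges$protein1, edges$protein2)
    b <- pmax(edges$protein1, edges$protein2)
    key <- paste(a, b, sep = "\r")
    score <- tapply(edges$combined_score, key, max)
    keys <- strsplit(names(score), "\r", fixed = TRUE)
    edges <- data.frame(protein1 = vapply(keys, `[`, character(1), 1),
                        protein2 = vapply(keys, `[`, character(1), 2),
                        combined_score = as.numeric(score),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$combined_score >= threshold, , drop = FALSE]
  }
  vnames <- unique(c(edges$protein1, edges$protein2, keep_nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$protein1, to = edges$protein2,
               score = edges$combined_score, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = vnames, stringsAsFactors = FALSE))
  igraph::graph_attr(g, "threshold") <- threshold
  g
}

#' Attach node annotations to a PPI graph
#'
#' Sets per-node flags used in the study's network figures: PSD membership,
#' disease-gene labels, known Homer interactor status, and (for the
#' differential-abundance network) regulation direction, significance tier
#' and fold change.
#'
#' @param graph igraph from [build_graph()].
#' @param annotations data.frame with a `node` column and any of `is_psd`,
#'   `disease_labels`, `known_homer_interactor`, `regulation`,
#'   `significance_tier`, `fold_change`.
#' @return The annotated graph.
#' @export
annotate_nodes <- function(graph, annotations) {
  stopifnot(is.data.frame(annotations), "node" %in% names(annotations))
  idx <- match(igraph::V(graph)$name, annotations$node)
  for (col in setdiff(names(annotations), "node")) {
    igraph::vertex_attr(graph, col) <- annotations[[col]][idx]
  }
  graph
}

#' Betweenness centrality table
#'
#' Unweighted shortest-path betweenness with standard fractional counting
#' over tied geodesics (Brandes semantics): the raw score of node v is the
#' sum over unordered pairs (s, t), s != v != t, of the fraction of s-t
#' geodesics passing through v.  The normalized score divides by
#' (n_c - 1)(n_c - 2)/2 where n_c is the size of v's connected component
#' (0 when n_c < 3), so a component's maximally central node scores 1.
#'
#' @param graph igraph from [build_graph()].
#' @return data.frame `node`, `betweenness` (raw), `betweenness_normalized`,
#'   sorted by decreasing raw score.
#' @export
betweenness_table <- function(graph) {
  if (igraph::vcount(graph) == 0L) {
    return(data.frame(node = character(), betweenness = numeric(),
                      betweenness_normalized = numeric(),
                      stringsAsFactors = FALSE))
  }
  raw <- igraph::betweenness(graph, directed = FALSE, weights = NA,
                             normalized = FALSE)
  comp <- igraph::components(graph)
  nc <- comp$csize[comp$membership]
  denom <- (nc - 1) * (nc - 2) / 2
  normalized <- ifelse(denom > 0, raw / denom, 0)
  out <- data.frame(node = igraph::V(graph)$name, betweenness = as.numeric(raw),
                    betweenness_normalized = as.numeric(normalized),
                    stringsAsFactors = FALSE)
  out[order(-out$betweenness, out$node), , drop = FALSE]
}

#' Seeded subnetwork extraction
#'
#' Induces the subgraph on a seed protein list (e.g. disease-associated
#' motif proteins, or the regulated proteins of the differential-abundance
#' analysis), optionally expanded by first neighbors.  Annotation
#' attributes are preserved.
#'
#' @param graph igraph from [build_graph()].
#' @param seeds character vector of node identifiers.
#' @param include_first_neighbors also include direct neighbors of seeds.
#' @return The induced igraph; empty (with a warning) when no seed is
#'   present in the graph.
#' @export
seed_subnetwork <- function(graph, seeds, include_first_neighbors = FALSE) {
  stopifnot(length(seeds) > 0)
  present <- intersect(seeds, igraph::V(graph)$name)
  if (!length(present)) {
    warning("none of the seeds are present in the graph", call. = FALSE)
    return(igraph::induced_subgraph(graph, integer(0)))
  }
  keep <- present
  if (include_first_neighbors) {
    nb <- unlist(igraph::adjacent_vertices(graph, present))
    keep <- union(present, igraph::V(graph)$name[nb])
  }
  igraph::induced_subgraph(graph, keep)
}

#' Export a graph to GraphML
#'
#' @param graph igraph object.
#' @param path output file.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Export graph edges to TSV
#'
#' Writes `protein1`, `protein2`, `combined_score` — the same format
#' [read_string_edges()] accepts, so build/export round-trips.
#'
#' @param graph igraph with edge attribute `score`.
#' @param path output file.
#' @export
write_edges_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  out <- data.frame(protein1 = el[, 1], protein2 = el[, 2],
                    combined_score = igraph::E(graph)$score %||%
                      rep(1, igraph::ecount(graph)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
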