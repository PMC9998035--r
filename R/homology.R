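#' Reciprocal best matches from a profile-vs-profile E-value matrix
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best non-self hit, `a` is
#' `b`'s best non-self hit, and both directional E-values are at or below
#' `threshold`. Ties for "best" are broken toward the lexicographically
#' smallest target label. The matrix may be asymmetric (query vs target
#' direction); both directions must individually pass the threshold.
#'
#' @param evalues Numeric matrix, queries x targets, `NA` = no hit.
#' @param threshold Positive E-value cutoff.
#' @return `data.frame` with columns `a`, `b` (a < b lexicographically),
#'   `evalue` (minimum of the two directions); zero rows when no pair.
#' @export
reciprocal_best_matches <- function(evalues, threshold) {
  stopifnot(is.matrix(evalues), threshold > 0)
  q <- rownames(evalues); t <- colnames(evalues)
  best <- function(query) {
    row <- evalues[query, ]
    row[t == query] <- NA  # ignore self-hits
    if (all(is.na(row))) return(NA_character_)
    m <- min(row, na.rm = TRUE)
    cand <- sort(t[!is.na(row) & row == m])
    cand[1L]
  }
  best_of <- vapply(q, best, character(1))
  pairs <- list()
  for (a in q) {
    b <- best_of[[a]]
    if (is.na(b) || !(b %in% q)) next
    if (!identical(best_of[[b]], a)) next
    if (a >= b) next  # report each unordered pair once
    ea <- evalues[a, b]; eb <- evalues[b, a]
    if (is.na(ea) || is.na(eb) || ea > threshold || eb > threshold) next
    pairs[[length(pairs) + 1L]] <- data.frame(a = a, b = b,
                                              evalue = min(ea, eb))
  }
  if (!length(pairs)) {
    return(data.frame(a = character(0), b = character(0),
                      evalue = numeric(0)))
  }
  out <- do.call(rbind, pairs)
  out[order(out$a, out$b), , drop = FALSE]
}

#' Homology network and connected components at an E-value threshold
#'
#' Builds the undirected graph whose edges connect profile pairs with
#' `min(E(a->b), E(b->a)) <= threshold` (direction-collapsed weight) and
#' returns its connected components, so that transitively linked subunits
#' (homologous via an intermediate profile) fall in one component even
#' when their direct comparison is above threshold.
#'
#' @inheritParams reciprocal_best_matches
#' @return `homology_network`: list with `edges` (a, b, evalue), `nodes`,
#'   `membership` (named component id per node), `n_components`, `graph`
#'   (igraph), and `path_length(a, b)` is available via
#'   [homology_path_length()].
#' @export
homology_components <- function(evalues, threshold) {
  stopifnot(is.matrix(evalues), threshold > 0)
  nodes <- sort(union(rownames(evalues), colnames(evalues)))
  rows <- list()
  for (a in rownames(evalues)) {
    for (b in colnames(evalues)) {
      if (a >= b) next
      ab <- evalues[a, b]
      ba <- if (b %in% rownames(evalues) && a %in% colnames(evalues))
        evalues[b, a] else NA_real_
      w <- suppressWarnings(min(ab, ba, na.rm = TRUE))
      if (is.finite(w) && w <= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(a = a, b = b, evalue = w)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(0), b = character(0), evalue = numeric(0))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  structure(list(edges = edges, nodes = nodes,
                 membership = comp$membership,
                 n_components = comp$no, graph = g,
                 threshold = threshold),
            class = "homology_network")
}

#' @export
print.homology_network <- function(x, ...) {
  cat("homology_network: ", length(x$nodes), " profiles, ",
      nrow(x$edges), " edges (E <= ", format(x$threshold), "), ",
      x$n_components, " components\n", sep = "")
  invisible(x)
}

#' Shortest-path length between two profiles in a homology network
#'
#' Path length 1 means direct linkage, 2 transitive via one intermediate,
#' `Inf` means different components.
#'
#' @param network A [homology_components()] result.
#' @param a,b Profile labels.
#' @return Numeric path length (edge count).
#' @export
homology_path_length <- function(network, a, b) {
  as.numeric(igraph::distances(network$graph, v = a, to = b))
}

#' Write a homology network as a weighted edge list
#'
#' @param network A [homology_components()] result.
#' @param path Output TSV path (columns a, b, evalue).
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check the expected ordering of hit classes per query
#'
#' For merged-pair query profiles, good deep-homology signal shows hits
#' ordered, by increasing E-value: the pair's own subunit profiles first,
#' then the other merged pairs, and only then external (outside-complex)
#' profiles. This reports, per query, the sorted hits with class
#' annotations and a flag for whether that ordering holds.
#'
#' @param evalues Numeric matrix, queries x targets.
#' @param node_classes Named character vector over all profiles with
#'   values in `subunit`, `merged_pair`, `external`.
#' @param queries Which queries to report (default: all queries of class
#'   `merged_pair`).
#' @return List: `hits` (named list of per-query data.frames sorted by
#'   E-value), `ordering_ok` (named logical per query).
#' @export
rank_hit_classes <- function(evalues, node_classes, queries = NULL) {
  miss <- setdiff(union(rownames(evalues), colnames(evalues)),
                  names(node_classes))
  if (length(miss)) stop("profiles without a class: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  rank_of <- c(subunit = 1L, merged_pair = 2L, external = 3L)
  if (is.null(queries)) {
    queries <- rownames(evalues)[
      node_classes[rownames(evalues)] == "merged_pair"]
  }
  hits <- list(); ok <- logical(0)
  for (qy in queries) {
    row <- evalues[qy, ]
    row <- row[!is.na(row) & colnames(evalues) != qy]
    ordq <- order(row)
    df <- data.frame(target = names(row)[ordq], evalue = unname(row[ordq]),
                     class = unname(node_classes[names(row)[ordq]]))
    hits[[qy]] <- df
    ok[qy] <- !is.unsorted(rank_of[df$class])
  }
  list(hits = hits, ordering_ok = ok)
}
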