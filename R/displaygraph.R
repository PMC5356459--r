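# The display graph of a fully labeled profile: the graph obtained from
# the disjoint union of the input trees by identifying nodes with the
# same label, collapsing parallel edges.  Under full+singular labeling
# its vertices are in bijection with the labels, so vertices are labels.

#' Build the display graph of a fully labeled profile
#'
#' Vertices are the labels of the profile; an edge joins two labels
#' exactly when one is the parent of the other in some input tree
#' (parallel edges collapsed).  Alongside the graph the multiplicity
#' `k_l` of every label -- the number of input trees containing it -- is
#' recorded; the engine's semi-universality test compares per-component
#' singleton counts against `k_l`.
#'
#' @param profile An `slprofile` whose trees are all fully and singularly
#'   labeled (apply [add_distinct_labels()] first otherwise).
#' @return An object of class `dgraph`: `labels` (vertex order), `index`
#'   (label to id), `edges` (two-column integer matrix, `u < v`), `adj`
#'   (neighbor lists), `mult` (integer `k_l` per vertex), `trees_of`
#'   (per vertex, the indices of the trees containing it).
#' @export
build_display_graph <- function(profile) {
  for (i in seq_along(profile$trees)) {
    tr <- profile$trees[[i]]
    bad <- slt_validate(tr, require_full = TRUE, require_singular = TRUE)
    if (length(bad))
      stop(sprintf(paste0("tree %d is not fully and singularly labeled ",
                          "(run add_distinct_labels first): %s"), i, bad[1]))
  }
  labels <- profile$label_universe
  n <- length(labels)
  index <- structure(seq_len(n), names = labels)
  trees_of <- vector("list", n)
  eu <- integer(0); ev <- integer(0)
  for (i in seq_along(profile$trees)) {
    tr <- profile$trees[[i]]
    node_lab <- vapply(tr$labels, function(x) x[1], "")
    ids <- index[node_lab]                     # node -> vertex id
    for (v in which(ids > 0L)) trees_of[[ids[v]]] <- c(trees_of[[ids[v]]], i)
    has_par <- tr$parent > 0L
    eu <- c(eu, ids[tr$parent[has_par]])
    ev <- c(ev, ids[which(has_par)])
  }
  lo <- pmin(eu, ev); hi <- pmax(eu, ev)
  if (any(lo == hi)) stop("self-loop in display graph (corrupt labeling)")
  keep <- !duplicated(lo * (n + 1) + hi)
  edges <- cbind(lo[keep], hi[keep])
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  if (nrow(edges)) {
    spl1 <- split(edges[, 2], edges[, 1])
    spl2 <- split(edges[, 1], edges[, 2])
    for (k in names(spl1)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], spl1[[k]])
    for (k in names(spl2)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], spl2[[k]])
  }
  structure(
    list(labels = labels, index = index, edges = edges, adj = adj,
         mult = lengths(trees_of), trees_of = trees_of),
    class = "dgraph")
}

#' @export
print.dgraph <- function(x, ...) {
  cat(sprintf("Display graph: %d vertices, %d edges\n",
              length(x$labels), nrow(x$edges)))
  invisible(x)
}

#' Connected components of a display graph
#'
#' If the display graph is disconnected the profile decomposes into
#' label-disjoint sub-profiles that can be solved independently;
#' [build_supertree()] uses this to pre-split the input.
#'
#' @param graph A `dgraph`.
#' @return List of character vectors, one per component (sorted labels).
#' @export
static_components <- function(graph) {
  n <- length(graph$labels)
  if (nrow(graph$edges)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(graph$edges))
    memb <- igraph::components(g)$membership
  } else memb <- seq_len(n)
  unname(lapply(split(graph$labels, memb), sort))
}

#' Export a display graph as an edge list
#'
#' Debug helper: two labels per line, tab-separated.
#'
#' @param graph A `dgraph`.
#' @param path Optional file; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when writing to a file).
#' @export
dgraph_edgelist <- function(graph, path = NULL) {
  lines <- apply(graph$edges, 1, function(e)
    paste(graph$labels[e[1]], graph$labels[e[2]], sep = "\t"))
  lines <- as.character(lines)
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
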