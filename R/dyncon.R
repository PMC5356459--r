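# Decremental dynamic connectivity over labeled vertices: a thin,
# label-aware wrapper around the C++ HDT hierarchy (Euler-tour forests
# with edge levels).  The compatibility engine consults this contract to
# detect component splits as it deletes display-graph edges.

#' Create a dynamic-connectivity structure
#'
#' Vertices are labels, mapped once to dense integer ids; edges are
#' inserted with [dc_insert_edge()] and deleted with [dc_delete_edge()],
#' which reports whether the deletion split a component.  Edge updates
#' cost amortized `O(log^2 N)`; component size is `O(log N)` and member
#' enumeration is proportional to the component size.
#'
#' @param labels Character vector of vertex names (or a single integer,
#'   for anonymous vertices `"1"..."n"`).
#' @return An object of class `dyncon`.
#' @export
dc_new <- function(labels) {
  if (is.numeric(labels) && length(labels) == 1L) labels <- as.character(seq_len(labels))
  labels <- as.character(labels)
  stopifnot(!anyDuplicated(labels))
  structure(
    list(ptr = hdt_new(length(labels)),
         labels = labels,
         index = structure(seq_along(labels), names = labels)),
    class = "dyncon")
}

.dc_id <- function(dc, v) {
  id <- unname(dc$index[as.character(v)])
  if (is.na(id)) stop("unknown vertex: ", v)
  id
}

#' Insert an edge
#'
#' Inserting an already-present edge is a no-op.
#'
#' @param dc A `dyncon` object.
#' @param u,v Vertex labels.
#' @return `dc`, invisibly.
#' @export
dc_insert_edge <- function(dc, u, v) {
  hdt_insert(dc$ptr, .dc_id(dc, u), .dc_id(dc, v))
  invisible(dc)
}

#' Delete an edge, reporting any component split
#'
#' @param dc A `dyncon` object.
#' @param u,v Vertex labels; the edge must be present.
#' @return If the component stayed connected, `list(split = FALSE)`.
#'   Otherwise `list(split = TRUE, size_u =, size_v =)` with the sizes of
#'   the two resulting components (the ones containing `u` and `v`);
#'   `u` and `v` themselves serve as the component handles.
#' @export
dc_delete_edge <- function(dc, u, v) {
  hdt_delete(dc$ptr, .dc_id(dc, u), .dc_id(dc, v))
}

#' Are two vertices in the same component?
#' @param dc A `dyncon` object.
#' @param u,v Vertex labels.
#' @return `TRUE` or `FALSE`.
#' @export
dc_connected <- function(dc, u, v) {
  hdt_connected(dc$ptr, .dc_id(dc, u), .dc_id(dc, v))
}

#' Size of a vertex's component
#' @param dc A `dyncon` object.
#' @param v Vertex label.
#' @return Integer count of vertices in `v`'s component.
#' @export
dc_component_size <- function(dc, v) {
  hdt_size(dc$ptr, .dc_id(dc, v))
}

#' Members of a vertex's component
#' @param dc A `dyncon` object.
#' @param v Vertex label.
#' @return Character vector of the component's vertex labels (each once).
#' @export
dc_component_members <- function(dc, v) {
  dc$labels[hdt_members(dc$ptr, .dc_id(dc, v))]
}

#' Operation counters of a connectivity structure
#' @param dc A `dyncon` object.
#' @return List with `n_insert`, `n_delete`, `n_splits`, `n_edges`.
#' @export
dc_stats <- function(dc) hdt_stats(dc$ptr)

#' @export
print.dyncon <- function(x, ...) {
  s <- dc_stats(x)
  cat(sprintf("Dynamic connectivity: %d vertices, %d edges (%d inserts, %d deletes)\n",
              length(x$labels), s$n_edges, s$n_insert, s$n_delete))
  invisible(x)
}
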