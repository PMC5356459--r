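#' @useDynLib nestcomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif
#' @importFrom utils head
NULL

# Canonical key for a label set; \r never occurs in labels (parser rejects it).
.setkey <- function(x) paste(sort(x), collapse = "\r")

#' Construct a semi-labeled tree
#'
#' A semi-labeled tree is a rooted tree together with a labeling function
#' that maps a set of taxa onto its nodes.  Every leaf must carry at least
#' one label, as must every node (the root included) with exactly one
#' child; nodes with two or more children may be unlabeled.  Input trees
#' are *singularly* labeled (at most one label per node); supertrees
#' returned by [build_supertree()] may carry several labels on one node.
#'
#' @param parent Integer vector; `parent[v]` is the parent of node `v`,
#'   with `0` marking the root.  Nodes are indexed `1..length(parent)`.
#' @param labels Either a character vector with `NA` for unlabeled nodes,
#'   or a list of character vectors (possibly empty) per node.
#' @param check Validate the result (default `TRUE`).
#' @return An object of class `slt` with fields `nnode`, `parent`,
#'   `children`, `root`, `labels` (list of character vectors) and
#'   `label2node` (named integer vector).
#' @export
slt <- function(parent, labels, check = TRUE) {
  parent <- as.integer(parent)
  n <- length(parent)
  if (is.character(labels) || all(is.na(labels))) {
    labels <- lapply(seq_len(n), function(v) {
      l <- labels[[v]]
      if (is.na(l)) character(0) else as.character(l)
    })
  }
  stopifnot(length(labels) == n)
  labels <- lapply(labels, as.character)
  children <- vector("list", n)
  for (v in seq_len(n)) children[[v]] <- integer(0)
  for (v in seq_len(n)) {
    p <- parent[v]
    if (p > 0L) children[[p]] <- c(children[[p]], v)
  }
  root <- which(parent == 0L)
  lab_nodes <- rep.int(seq_len(n), lengths(labels))
  lab_names <- unlist(labels, use.names = FALSE)
  label2node <- structure(lab_nodes, names = lab_names)
  tr <- structure(
    list(nnode = n, parent = parent, children = children,
         root = if (length(root) == 1L) root else NA_integer_,
         labels = labels, label2node = label2node),
    class = "slt")
  if (check) {
    bad <- slt_validate(tr)
    if (length(bad)) stop("invalid semi-labeled tree: ", paste(bad, collapse = "; "))
  }
  tr
}

#' All labels of a semi-labeled tree
#' @param tree An `slt` object.
#' @return Character vector of the tree's label set.
#' @export
slt_labels <- function(tree) names(tree$label2node)

#' Validate a semi-labeled tree
#'
#' Checks the structural invariants of the class: a unique root, a proper
#' parent/child relation, labeled leaves and labeled single-child nodes,
#' and mutual consistency of the labeling maps.  Violations are returned
#' as data, not raised as conditions.
#'
#' @param tree An `slt` object.
#' @param require_full Also require every node to be labeled.
#' @param require_singular Also require at most one label per node.
#' @return Character vector of violation messages (empty if valid).
#' @export
slt_validate <- function(tree, require_full = FALSE, require_singular = FALSE) {
  out <- character(0)
  n <- tree$nnode
  if (n < 1L) return("tree has no nodes")
  roots <- which(tree$parent == 0L)
  if (length(roots) != 1L)
    out <- c(out, sprintf("expected exactly one root, found %d", length(roots)))
  # reachability from root (also catches cycles)
  if (length(roots) == 1L) {
    seen <- logical(n); stack <- roots
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[v]) { out <- c(out, sprintf("node %d revisited (cycle)", v)); break }
      seen[v] <- TRUE
      stack <- c(stack, tree$children[[v]])
    }
    if (!all(seen)) out <- c(out, sprintf("node %d unreachable from root", which(!seen)[1]))
  }
  for (v in seq_len(n)) {
    nch <- length(tree$children[[v]])
    nl <- length(tree$labels[[v]])
    if (nch == 0L && nl == 0L) out <- c(out, sprintf("unlabeled leaf (node %d)", v))
    if (nch == 1L && nl == 0L) out <- c(out, sprintf("unlabeled single-child node (node %d)", v))
    if (require_full && nl == 0L) out <- c(out, sprintf("unlabeled node %d with require_full", v))
    if (require_singular && nl > 1L) out <- c(out, sprintf("node %d carries %d labels", v, nl))
  }
  labs <- unlist(tree$labels, use.names = FALSE)
  if (anyDuplicated(labs))
    out <- c(out, sprintf("duplicate label '%s'", labs[duplicated(labs)][1]))
  m <- tree$label2node
  for (l in names(m)) {
    if (!(l %in% tree$labels[[m[[l]]]]))
      out <- c(out, sprintf("label2node inconsistent for '%s'", l))
  }
  out
}

# Breadth-first node order from the root; parents precede children.
.slt_bfs <- function(tree) {
  ord <- integer(tree$nnode); ord[1] <- tree$root; i <- 1L; j <- 1L
  while (i <= j) {
    ch <- tree$children[[ord[i]]]
    if (length(ch)) { ord[(j + 1L):(j + length(ch))] <- ch; j <- j + length(ch) }
    i <- i + 1L
  }
  ord
}

# DFS entry/exit intervals: u is an ancestor of v iff
# tin[u] <= tin[v] && tout[v] <= tout[u].
.slt_intervals <- function(tree) {
  n <- tree$nnode
  tin <- integer(n); tout <- integer(n)
  clock <- 0L
  stack <- c(tree$root); state <- c(0L)  # 0 = enter, 1 = exit
  while (length(stack)) {
    v <- stack[length(stack)]; s <- state[length(stack)]
    if (s == 0L) {
      clock <- clock + 1L; tin[v] <- clock
      state[length(stack)] <- 1L
      ch <- tree$children[[v]]
      if (length(ch)) {
        stack <- c(stack, rev(ch)); state <- c(state, rep(0L, length(ch)))
      }
    } else {
      clock <- clock + 1L; tout[v] <- clock
      stack <- stack[-length(stack)]; state <- state[-length(state)]
    }
  }
  list(tin = tin, tout = tout)
}

#' Cluster set of a semi-labeled tree
#'
#' The cluster of a node is the set of all labels carried by the node and
#' its descendants.  A semi-labeled tree is completely determined by its
#' cluster set, which is the basis of [slt_isomorphic()] and of the
#' restriction cross-check.
#'
#' @param tree An `slt` object.
#' @return A list of character vectors (sorted, one per distinct cluster).
#' @export
slt_clusters <- function(tree) {
  ord <- rev(.slt_bfs(tree))
  acc <- vector("list", tree$nnode)
  for (v in ord) {
    x <- tree$labels[[v]]
    for (c in tree$children[[v]]) x <- c(x, acc[[c]])
    acc[[v]] <- x
  }
  acc <- lapply(acc, function(x) sort(unique(x)))
  acc[!duplicated(vapply(acc, .setkey, ""))]
}

#' Restrict a semi-labeled tree to a subset of its labels
#'
#' Returns the tree whose cluster set is `{X ∩ A : X a cluster, X ∩ A
#' nonempty}`: the minimal rooted subtree connecting the nodes labeled
#' from `A`, with every degree-two node not carrying an `A`-label
#' suppressed.
#'
#' @param tree An `slt` object.
#' @param subset Nonempty character vector, a subset of `slt_labels(tree)`.
#' @return An `slt` object with label set `subset`.
#' @export
slt_restrict <- function(tree, subset) {
  subset <- unique(as.character(subset))
  if (length(subset) == 0L) stop("subset must be nonempty")
  if (!all(subset %in% slt_labels(tree)))
    stop("subset contains labels not in the tree: ",
         paste(head(setdiff(subset, slt_labels(tree)), 3), collapse = ", "))
  n <- tree$nnode
  labA <- lapply(tree$labels, function(x) x[x %in% subset])
  cntA <- lengths(labA)
  ord <- rev(.slt_bfs(tree))
  for (v in ord) {
    p <- tree$parent[v]
    if (p > 0L) cntA[p] <- cntA[p] + cntA[v]
  }
  keep <- logical(n)
  for (v in seq_len(n)) {
    if (length(labA[[v]])) keep[v] <- TRUE
    else {
      nchA <- sum(cntA[tree$children[[v]]] > 0L)
      if (nchA >= 2L) keep[v] <- TRUE
    }
  }
  kept <- which(keep)
  newid <- integer(n); newid[kept] <- seq_along(kept)
  # nearest kept proper ancestor, walking top-down
  anc <- integer(n)  # 0 = none
  for (v in .slt_bfs(tree)) {
    p <- tree$parent[v]
    if (p == 0L) anc[v] <- 0L
    else anc[v] <- if (keep[p]) p else anc[p]
  }
  newpar <- integer(length(kept))
  for (i in seq_along(kept)) {
    a <- anc[kept[i]]
    newpar[i] <- if (a == 0L) 0L else newid[a]
  }
  slt(newpar, labA[kept], check = FALSE)
}

#' Proper ancestor/descendant label pairs
#'
#' All ordered pairs `(l, l2)` such that the node of `l2` is a proper
#' descendant of the node of `l`.  Labels sharing one node yield no pair.
#'
#' @param tree An `slt` object.
#' @return A two-column character matrix (ancestor, descendant).
#' @export
slt_desc_pairs <- function(tree) {
  iv <- .slt_intervals(tree)
  labs <- names(tree$label2node); nodes <- unname(tree$label2node)
  m <- length(labs)
  if (m < 2L) return(matrix(character(0), ncol = 2))
  a <- rep(seq_len(m), each = m); b <- rep(seq_len(m), m)
  ok <- nodes[a] != nodes[b] &
    iv$tin[nodes[a]] < iv$tin[nodes[b]] & iv$tout[nodes[b]] < iv$tout[nodes[a]]
  cbind(labs[a[ok]], labs[b[ok]])
}

#' Incomparable label pairs
#'
#' All unordered pairs of labels whose nodes are not comparable (neither
#' is an ancestor of the other).
#'
#' @param tree An `slt` object.
#' @return A two-column character matrix; each pair appears once, with
#'   the lexicographically smaller label first.
#' @export
slt_incomp_pairs <- function(tree) {
  iv <- .slt_intervals(tree)
  labs <- names(tree$label2node); nodes <- unname(tree$label2node)
  m <- length(labs)
  if (m < 2L) return(matrix(character(0), ncol = 2))
  a <- rep(seq_len(m), each = m); b <- rep(seq_len(m), m)
  sel <- a < b
  a <- a[sel]; b <- b[sel]
  anc_ab <- iv$tin[nodes[a]] <= iv$tin[nodes[b]] & iv$tout[nodes[b]] <= iv$tout[nodes[a]]
  anc_ba <- iv$tin[nodes[b]] <= iv$tin[nodes[a]] & iv$tout[nodes[a]] <= iv$tout[nodes[b]]
  ok <- !anc_ab & !anc_ba
  lo <- pmin(labs[a[ok]], labs[b[ok]]); hi <- pmax(labs[a[ok]], labs[b[ok]])
  cbind(lo, hi, deparse.level = 0)
}

.pairkeys <- function(m) if (nrow(m)) paste(m[, 1], m[, 2], sep = "\r") else character(0)

#' Does one semi-labeled tree ancestrally display another?
#'
#' `big` ancestrally displays `small` when every proper
#' ancestor/descendant pair of `small` is a proper ancestor/descendant
#' pair of `big`, and every incomparable pair of `small` is incomparable
#' in `big`.  This is the verification oracle applied to every supertree
#' the package outputs.
#'
#' @param big,small `slt` objects with `slt_labels(small)` a subset of
#'   `slt_labels(big)`.
#' @return `TRUE` or `FALSE`.
#' @export
ancestrally_displays <- function(big, small) {
  if (!all(slt_labels(small) %in% slt_labels(big)))
    stop("label set of 'small' is not contained in label set of 'big'")
  all(.pairkeys(slt_desc_pairs(small)) %in% .pairkeys(slt_desc_pairs(big))) &&
    all(.pairkeys(slt_incomp_pairs(small)) %in% .pairkeys(slt_incomp_pairs(big)))
}

#' Isomorphism of semi-labeled trees
#'
#' Two semi-labeled trees are isomorphic exactly when they have the same
#' label set and the same cluster set; child order is irrelevant.
#'
#' @param t1,t2 `slt` objects.
#' @return `TRUE` or `FALSE`.
#' @export
slt_isomorphic <- function(t1, t2) {
  if (!setequal(slt_labels(t1), slt_labels(t2))) return(FALSE)
  k1 <- sort(vapply(slt_clusters(t1), .setkey, ""))
  k2 <- sort(vapply(slt_clusters(t2), .setkey, ""))
  identical(k1, k2)
}

#' @export
print.slt <- function(x, ...) {
  cat(sprintf("Semi-labeled tree: %d nodes, %d labels\n",
              x$nnode, length(x$label2node)))
  cat(" ", write_newick(x), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Profiles

#' Construct a profile of semi-labeled trees
#'
#' A profile is an ordered collection of semi-labeled input trees with
#' partially overlapping label sets.  Its size `M_P` -- the total number
#' of nodes plus edges over all trees -- is the parameter every running
#' time bound of the engine is expressed in.
#'
#' @param trees List of `slt` objects.
#' @return An object of class `slprofile` with fields `trees`,
#'   `label_universe` and `size_MP`.
#' @export
new_profile <- function(trees) {
  stopifnot(length(trees) >= 1L, all(vapply(trees, inherits, TRUE, "slt")))
  structure(
    list(trees = trees,
         label_universe = sort(unique(unlist(lapply(trees, slt_labels)))),
         size_MP = sum(vapply(trees, function(t) 2L * t$nnode - 1L, 0L))),
    class = "slprofile")
}

#' @export
print.slprofile <- function(x, ...) {
  cat(sprintf("Profile of %d semi-labeled trees, %d labels, size M_P = %d\n",
              length(x$trees), length(x$label_universe), x$size_MP))
  invisible(x)
}

#' Make every tree of a profile fully labeled
#'
#' Assigns one fresh label (prefix `"__aux"`) to every unlabeled node of
#' every tree.  A profile is ancestrally compatible if and only if the
#' fully labeled profile is, and any supertree for the fully labeled
#' profile also displays the original; the engine therefore always works
#' on fully labeled trees, and the auxiliary labels can be stripped again
#' on output.
#'
#' @param profile An `slprofile`.
#' @return List with elements `profile` (fully labeled) and `added`
#'   (character vector of the fresh labels).
#' @export
add_distinct_labels <- function(profile) {
  existing <- profile$label_universe
  counter <- 0L
  fresh <- function() {
    repeat {
      counter <<- counter + 1L
      cand <- paste0("__aux", counter)
      if (!(cand %in% existing)) return(cand)
    }
  }
  added <- character(0)
  trees <- lapply(profile$trees, function(tr) {
    un <- which(lengths(tr$labels) == 0L)
    if (!length(un)) return(tr)
    labs <- tr$labels
    for (v in un) {
      l <- fresh()
      labs[[v]] <- l
      added <<- c(added, l)
    }
    slt(tr$parent, labs, check = FALSE)
  })
  list(profile = new_profile(trees), added = added)
}

#' Strip auxiliary labels from a tree
#'
#' Removes labels added by [add_distinct_labels()] (prefix `"__aux"`) and
#' suppresses any node left unlabeled with a single child, so the result
#' is again a valid semi-labeled tree on the original label set.
#'
#' @param tree An `slt` object (possibly multi-labeled).
#' @return An `slt` object.
#' @export
strip_aux_labels <- function(tree) {
  keep_labels <- names(tree$label2node)[!startsWith(names(tree$label2node), "__aux")]
  if (length(keep_labels) == 0L)
    stop("stripping auxiliary labels would leave the tree unlabeled")
  slt_restrict(tree, keep_labels)
}
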