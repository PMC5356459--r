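# The ancestral-compatibility engine.
#
# The iterative engine walks the profile top-down.  A *position* assigns
# each input tree a frontier of sibling labels; a label is
# *semi-universal* when its frontier entry is exactly itself in every
# tree containing it.  The semi-universal set S of a position labels the
# next supertree node; replacing each member of S by its children and
# deleting the corresponding display-graph edges splits the current
# component into the sub-profiles processed next.  An empty S proves
# incompatibility.  Components are tracked by the HDT structure
# (dyncon); per-component bookkeeping (frontier map / singleton counts /
# exposed set / weight) makes S retrieval proportional to |S| and keeps
# split handling amortized near-linear via two smaller-side scans: the
# node-count-smaller side is scanned to compute weights, and the
# weight-smaller side is scanned to move its frontier entries into a
# fresh component record.
#
# A naive recursive engine (explicit positions, from-scratch
# semi-universal counting, BFS components) serves as the cross-check
# oracle for the iterative one.

# --- engine state ----------------------------------------------------------

.new_record <- function(st, weight, rep) {
  r <- new.env(parent = emptyenv())
  r$cells <- new.env(parent = emptyenv())   # tree index -> env of label ids
  r$csize <- new.env(parent = emptyenv())   # tree index -> cell size
  r$exposed <- new.env(parent = emptyenv()) # label ids with count == k_l
  r$weight <- weight
  r$rep <- rep
  st$nrec <- st$nrec + 1L
  r$id <- st$nrec
  st$recs[[st$nrec]] <- r
  r
}

.record_position <- function(st, r) {
  out <- vector("list", st$k)
  for (i in seq_len(st$k)) out[[i]] <- character(0)
  for (ic in ls(r$cells))
    out[[as.integer(ic)]] <- sort(st$labels[as.integer(ls(r$cells[[ic]]))])
  out
}

.kids_of <- function(st, l, i) st$kids[[l]][[match(i, st$trees_of[[l]])]]

# Initialize engine state and the root component record for a fully
# labeled profile with connected display graph.
.engine_init <- function(fp, g, trace = FALSE) {
  st <- new.env(parent = emptyenv())
  st$k <- length(fp$trees)
  st$labels <- g$labels
  n <- length(g$labels)
  st$n <- n
  st$mult <- as.integer(g$mult)
  st$trees_of <- g$trees_of
  # children of each label in each containing tree, aligned with trees_of
  kids <- vector("list", n)
  for (l in seq_len(n)) kids[[l]] <- vector("list", length(g$trees_of[[l]]))
  rid <- integer(st$k)
  for (i in seq_len(st$k)) {
    tr <- fp$trees[[i]]
    ids <- g$index[vapply(tr$labels, `[`, "", 1L)]
    rid[i] <- ids[tr$root]
    for (v in seq_len(tr$nnode)) {
      l <- ids[v]
      j <- match(i, g$trees_of[[l]])
      kids[[l]][[j]] <- as.integer(sort(ids[tr$children[[v]]]))
    }
  }
  st$kids <- kids
  st$rid <- rid
  st$adj <- lapply(g$adj, as.integer)
  st$dead <- logical(n)      # label consumed (removed from every frontier)
  st$gone <- logical(n)      # label's incident edges all deleted
  st$infront <- vector("list", n)   # trees where the label sits in a frontier cell
  st$count <- integer(n)
  st$rec_of <- integer(n)
  st$recs <- vector("list", 16L)
  st$nrec <- 0L
  st$ptr <- hdt_new(n)
  if (nrow(g$edges))
    for (e in seq_len(nrow(g$edges)))
      hdt_insert(st$ptr, g$edges[e, 1], g$edges[e, 2])
  st$deletions <- 0L
  st$updates <- 0L
  st$scans <- 0L
  st$trace <- if (trace) list() else NULL
  # root record: frontier = the root label of every tree
  r <- .new_record(st, weight = sum(st$mult), rep = rid[1])
  for (i in seq_len(st$k)) {
    l <- rid[i]
    cell <- new.env(parent = emptyenv())
    assign(as.character(l), TRUE, envir = cell)
    assign(as.character(i), cell, envir = r$cells)
    assign(as.character(i), 1L, envir = r$csize)
    st$count[l] <- st$count[l] + 1L
    st$infront[[l]] <- c(st$infront[[l]], i)
    st$updates <- st$updates + 2L
  }
  for (i in seq_len(st$k)) {
    l <- rid[i]
    if (st$count[l] == st$mult[l])
      assign(as.character(l), TRUE, envir = r$exposed)
  }
  st$rec_of[] <- r$id
  st
}

# Semi-universal labels of a component record, in label-sorted order.
.semi_universal <- function(st, r) {
  s <- as.integer(ls(r$exposed))
  s[order(st$labels[s])]
}

# Move label b's frontier entries from record `from` to record `to`,
# maintaining singleton counts and exposed sets on both sides.
.move_label <- function(st, from, to, b) {
  bc <- as.character(b)
  for (i in st$infront[[b]]) {
    ic <- as.character(i)
    cell <- from$cells[[ic]]
    cs <- from$csize[[ic]]
    rm(list = bc, envir = cell)
    if (cs == 1L) {                       # cell was exactly {b}
      st$count[b] <- st$count[b] - 1L
      if (exists(bc, envir = from$exposed, inherits = FALSE))
        rm(list = bc, envir = from$exposed)
      rm(list = ic, envir = from$cells)
      rm(list = ic, envir = from$csize)
    } else {
      cs <- cs - 1L
      assign(ic, cs, envir = from$csize)
      if (cs == 1L) {                     # cell shrank to a singleton {g}
        gm <- as.integer(ls(cell))
        st$count[gm] <- st$count[gm] + 1L
        if (st$count[gm] == st$mult[gm])
          assign(as.character(gm), TRUE, envir = from$exposed)
      }
    }
    cellN <- to$cells[[ic]]
    if (is.null(cellN)) {
      cellN <- new.env(parent = emptyenv())
      assign(bc, TRUE, envir = cellN)
      assign(ic, cellN, envir = to$cells)
      assign(ic, 1L, envir = to$csize)
      st$count[b] <- st$count[b] + 1L
      if (st$count[b] == st$mult[b])
        assign(bc, TRUE, envir = to$exposed)
    } else {
      csN <- to$csize[[ic]]
      if (csN == 1L) {                    # cell {d} loses singleton status
        dm <- as.integer(ls(cellN))
        st$count[dm] <- st$count[dm] - 1L
        dmc <- as.character(dm)
        if (exists(dmc, envir = to$exposed, inherits = FALSE))
          rm(list = dmc, envir = to$exposed)
      }
      assign(bc, TRUE, envir = cellN)
      assign(ic, csN + 1L, envir = to$csize)
    }
    st$updates <- st$updates + 4L
  }
}

# Delete edge (u, v) inside record r's component; on a split, scan the
# node-count-smaller side for weights, then move the weight-smaller
# side's labels into a fresh record.
.split_update <- function(st, r, u, v) {
  res <- hdt_delete(st$ptr, u, v)
  st$deletions <- st$deletions + 1L
  if (!res$split) return(invisible(NULL))
  su <- res$size_u; sv <- res$size_v
  scanv <- if (su <= sv) u else v
  other <- if (scanv == u) v else u
  mem_s <- hdt_members(st$ptr, scanv)
  st$scans <- st$scans + length(mem_s)
  w_s <- sum(st$mult[mem_s])
  w_o <- r$weight - w_s
  if (w_s < w_o) {
    small_members <- mem_s; w_small <- w_s; big_rep <- other
  } else if (w_o < w_s) {
    small_members <- hdt_members(st$ptr, other)
    st$scans <- st$scans + length(small_members)
    w_small <- w_o; big_rep <- scanv
  } else {  # weight tie: the side holding the lexicographically smallest
            # label counts as smaller
    mem_o <- hdt_members(st$ptr, other)
    if (min(st$labels[mem_s]) < min(st$labels[mem_o])) {
      small_members <- mem_s; w_small <- w_s; big_rep <- other
    } else {
      small_members <- mem_o; w_small <- w_o; big_rep <- scanv
      st$scans <- st$scans + length(mem_o)
    }
  }
  rn <- .new_record(st, weight = w_small, rep = small_members[1])
  r$weight <- r$weight - w_small
  r$rep <- big_rep
  assign(as.character(rn$id), TRUE, envir = st$fragset)
  for (b in small_members) {
    st$rec_of[b] <- rn$id
    if (length(st$infront[[b]])) .move_label(st, r, rn, b)
  }
  invisible(NULL)
}

# Advance record r past its semi-universal set S: replace frontier
# entries by child sets, then delete every display-graph edge incident
# to S, tracking the resulting component records.  Returns the records
# (fragments) with a nonempty frontier.
.successor_apply <- function(st, r, S) {
  st$fragset <- new.env(parent = emptyenv())
  assign(as.character(r$id), TRUE, envir = st$fragset)
  for (l in S) {
    lc <- as.character(l)
    for (i in st$trees_of[[l]]) {
      ic <- as.character(i)
      rm(list = ic, envir = r$cells)
      rm(list = ic, envir = r$csize)
      st$count[l] <- st$count[l] - 1L
      st$infront[[l]] <- setdiff(st$infront[[l]], i)
      st$updates <- st$updates + 2L
      kv <- .kids_of(st, l, i)
      if (length(kv)) {
        cell <- new.env(parent = emptyenv())
        for (a in kv) {
          assign(as.character(a), TRUE, envir = cell)
          st$infront[[a]] <- c(st$infront[[a]], i)
        }
        assign(ic, cell, envir = r$cells)
        assign(ic, length(kv), envir = r$csize)
        st$updates <- st$updates + length(kv)
        if (length(kv) == 1L) {
          a <- kv
          st$count[a] <- st$count[a] + 1L
          if (st$count[a] == st$mult[a])
            assign(as.character(a), TRUE, envir = r$exposed)
        }
      }
    }
    if (exists(lc, envir = r$exposed, inherits = FALSE))
      rm(list = lc, envir = r$exposed)
    st$dead[l] <- TRUE
  }
  if (!is.null(st$trace))
    st$trace[[length(st$trace)]]$successor <- .record_position(st, r)
  for (l in S) {
    nbrs <- st$adj[[l]]
    nbrs <- sort(nbrs[!st$gone[nbrs]])
    for (a in nbrs) .split_update(st, st$recs[[st$rec_of[l]]], l, a)
    st$gone[l] <- TRUE
  }
  frag_ids <- as.integer(ls(st$fragset))
  frags <- list()
  for (id in sort(frag_ids)) {
    fr <- st$recs[[id]]
    if (length(ls(fr$cells))) frags[[length(frags) + 1L]] <- fr
  }
  frags
}

# Iterative engine over one connected, fully labeled sub-profile.
.engine_iterative <- function(fp, g, trace = FALSE) {
  st <- .engine_init(fp, g, trace = trace)
  qrec <- list(st$recs[[1]])
  qpred <- list(0L)
  qhead <- 1L
  out_parent <- integer(0)
  out_labels <- list()
  while (qhead <= length(qrec)) {
    r <- qrec[[qhead]]
    pred <- qpred[[qhead]]
    qhead <- qhead + 1L
    S <- .semi_universal(st, r)
    if (!length(S)) {
      return(list(compatible = FALSE, tree = NULL, stats = .engine_stats(st),
                  trace = st$trace,
                  witness_position = .record_position(st, r)))
    }
    if (!is.null(st$trace))
      st$trace[[length(st$trace) + 1L]] <- list(
        position = .record_position(st, r),
        members = sort(st$labels[hdt_members(st$ptr, r$rep)]),
        S = st$labels[S], successor = NULL, n_fragments = 0L)
    node <- length(out_parent) + 1L
    out_parent[node] <- pred
    out_labels[[node]] <- st$labels[S]
    if (length(S) == 1L &&
        all(lengths(st$kids[[S]]) == 0L)) next   # leaf: no proper descendants
    frags <- .successor_apply(st, r, S)
    if (!is.null(st$trace))
      st$trace[[length(st$trace)]]$n_fragments <- length(frags)
    for (fr in frags) {
      qrec[[length(qrec) + 1L]] <- fr
      qpred[[length(qpred) + 1L]] <- node
    }
  }
  tree <- slt(out_parent, out_labels, check = FALSE)
  list(compatible = TRUE, tree = tree, stats = .engine_stats(st), trace = st$trace)
}

.engine_stats <- function(st) {
  hs <- hdt_stats(st$ptr)
  list(deletions = st$deletions, field_updates = st$updates,
       scanned_labels = st$scans, hdt_splits = hs$n_splits)
}

# --- recursive reference engine -------------------------------------------

# Naive implementation used as the oracle: positions as explicit
# vectors, semi-universal detection by counting from scratch, components
# by breadth-first search on the surviving subgraph.
.engine_recursive <- function(fp, g) {
  k <- length(fp$trees)
  n <- length(g$labels)
  st <- .engine_init(fp, g)   # reuse precomputed kids / trees_of / adj
  alive <- rep(TRUE, n)
  U0 <- vector("list", k)
  for (i in seq_len(k)) U0[[i]] <- st$rid[i]
  rec_fn <- function(U, comp) {
    cand <- sort(unique(unlist(U)))
    is_su <- vapply(cand, function(l)
      all(vapply(st$trees_of[[l]], function(i)
        length(U[[i]]) == 1L && U[[i]] == l, TRUE)), TRUE)
    S <- cand[is_su]
    if (!length(S)) return(NULL)
    S <- S[order(st$labels[S])]
    U2 <- U
    for (i in seq_len(k)) {
      if (length(U[[i]]) == 1L && U[[i]] %in% S)
        U2[[i]] <- .kids_of(st, U[[i]], i)
    }
    surv <- setdiff(comp, S)
    if (!length(surv))
      return(list(labels = st$labels[S], children = list()))
    # BFS components of the induced subgraph on `surv`
    inset <- logical(n); inset[surv] <- TRUE
    seen <- logical(n)
    children <- list()
    for (s0 in surv) {
      if (seen[s0]) next
      compW <- integer(0); queue <- s0; seen[s0] <- TRUE
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        compW <- c(compW, v)
        nb <- st$adj[[v]]
        nb <- nb[inset[nb] & !seen[nb]]
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
      UW <- lapply(U2, function(x) x[x %in% compW])
      sub <- rec_fn(UW, sort(compW))
      if (is.null(sub)) return(NULL)
      children[[length(children) + 1L]] <- sub
    }
    list(labels = st$labels[S], children = children)
  }
  res <- rec_fn(U0, seq_len(n))
  if (is.null(res)) return(list(compatible = FALSE, tree = NULL))
  # flatten the nested node list into an slt
  parent <- integer(0); labs <- list()
  emit <- function(node, pred) {
    id <- length(parent) + 1L
    parent[id] <<- pred
    labs[[id]] <<- node$labels
    for (ch in node$children) emit(ch, id)
  }
  emit(res, 0L)
  list(compatible = TRUE, tree = slt(parent, labs, check = FALSE))
}

# --- driver ----------------------------------------------------------------

#' Test ancestral compatibility and build a supertree
#'
#' Decides whether a profile of rooted semi-labeled trees is ancestrally
#' compatible and, when it is, returns a supertree that preserves every
#' proper ancestor/descendant pair and every incomparable pair of every
#' input tree (verifiable with [ancestrally_displays()]).  Unlabeled
#' nodes are first given fresh auxiliary labels; if the display graph is
#' disconnected, each connected sub-profile is solved independently and
#' the resulting supertrees are joined under a fresh unlabeled root (or
#' returned as a forest).
#'
#' @param profile An `slprofile` of singularly labeled trees.
#' @param engine `"iterative"` (default; near-linear-time engine),
#'   `"recursive"` (naive reference), or `"both"` (run both and stop if
#'   their verdicts or trees disagree).
#' @param join_components How to combine supertrees of disconnected
#'   sub-profiles: `TRUE` joins them under a fresh unlabeled root,
#'   `FALSE` returns a forest.
#' @param strip_aux Remove auxiliary labels from the output (default
#'   `TRUE`).
#' @param trace Record the engine's per-position trace (dequeued
#'   positions, semi-universal sets, successors, fragment counts).
#' @return A list of class `compat_result`: `compatible` (logical),
#'   `tree` (`slt`, or `NULL` if incompatible or when a forest was
#'   requested), `forest` (list of `slt`, when `join_components =
#'   FALSE`), `stats` (edge deletions, field updates, scanned labels),
#'   and `trace` (when requested).
#' @export
build_supertree <- function(profile,
                            engine = c("iterative", "recursive", "both"),
                            join_components = TRUE,
                            strip_aux = TRUE,
                            trace = FALSE) {
  engine <- match.arg(engine)
  for (i in seq_along(profile$trees)) {
    bad <- slt_validate(profile$trees[[i]], require_singular = TRUE)
    if (length(bad)) stop(sprintf("input tree %d invalid: %s", i, bad[1]))
  }
  full <- add_distinct_labels(profile)
  fp <- full$profile
  g <- build_display_graph(fp)
  comps <- static_components(g)
  subtrees <- list()
  stats <- list(deletions = 0L, field_updates = 0L, scanned_labels = 0L,
                M_P = fp$size_MP,
                graph_vertices = length(g$labels),
                graph_edges = nrow(g$edges))
  traces <- list()
  for (cc in comps) {
    keep <- vapply(fp$trees, function(t) slt_labels(t)[1] %in% cc, TRUE)
    sub <- new_profile(fp$trees[keep])
    gs <- if (length(comps) == 1L) g else build_display_graph(sub)
    if (engine == "recursive") {
      run <- .engine_recursive(sub, gs)
      run$stats <- list(deletions = 0L, field_updates = 0L, scanned_labels = 0L)
    } else {
      run <- .engine_iterative(sub, gs, trace = trace)
      if (engine == "both") {
        run2 <- .engine_recursive(sub, gs)
        if (run$compatible != run2$compatible)
          stop("engine cross-check failed: verdicts disagree")
        if (run$compatible && !slt_isomorphic(run$tree, run2$tree))
          stop("engine cross-check failed: supertrees not isomorphic")
      }
    }
    stats$deletions <- stats$deletions + run$stats$deletions
    stats$field_updates <- stats$field_updates + run$stats$field_updates
    stats$scanned_labels <- stats$scanned_labels + run$stats$scanned_labels
    if (trace) traces[[length(traces) + 1L]] <- run$trace
    if (!run$compatible) {
      out <- list(compatible = FALSE, tree = NULL, stats = stats,
                  trace = if (trace) traces else NULL)
      class(out) <- "compat_result"
      return(out)
    }
    subtrees[[length(subtrees) + 1L]] <- run$tree
  }
  if (strip_aux) subtrees <- lapply(subtrees, strip_aux_labels)
  out <- list(compatible = TRUE, stats = stats,
              trace = if (trace) traces else NULL)
  if (length(subtrees) == 1L) {
    out$tree <- subtrees[[1]]
  } else if (join_components) {
    parent <- 0L; labs <- list(character(0))
    for (tr in subtrees) {
      off <- length(parent)
      pp <- ifelse(tr$parent == 0L, 1L, tr$parent + off)
      parent <- c(parent, pp)
      labs <- c(labs, tr$labels)
    }
    out$tree <- slt(parent, labs, check = FALSE)
  } else {
    out$tree <- NULL
    out$forest <- subtrees
  }
  class(out) <- "compat_result"
  out
}

#' @export
print.compat_result <- function(x, ...) {
  if (x$compatible) {
    cat("Profile is ancestrally compatible.\n")
    if (!is.null(x$tree)) cat(" Supertree:", write_newick(x$tree), "\n")
    if (!is.null(x$forest))
      for (tr in x$forest) cat(" Component supertree:", write_newick(tr), "\n")
  } else cat("Profile is INCOMPATIBLE.\n")
  cat(sprintf(" work: %d edge deletions, %d field updates\n",
              x$stats$deletions, x$stats$field_updates))
  invisible(x)
}
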