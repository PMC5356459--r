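# Newick reading and writing for semi-labeled trees.
#
# The dialect: labels may sit on any node (after the closing parenthesis
# for internal nodes), single-child nodes are allowed, labels may be
# single-quoted (with '' escaping an embedded quote), and branch lengths
# are parsed but discarded -- compatibility testing is topology-only.
# Multi-label nodes (supertree output) are rendered as the labels joined
# by a separator, "+" by default.

.nwk_state <- function(text) {
  env <- new.env(parent = emptyenv())
  env$s <- text
  env$i <- 1L
  env$n <- nchar(text)
  env
}

.nwk_peek <- function(st) if (st$i > st$n) "" else substr(st$s, st$i, st$i)

.nwk_err <- function(st, msg) {
  before <- substr(st$s, 1L, st$i - 1L)
  line <- 1L + lengths(regmatches(before, gregexpr("\n", before, fixed = TRUE)))
  col <- st$i - ifelse(line > 1L,
                       max(gregexpr("\n", before, fixed = TRUE)[[1]]), 0L)
  stop(sprintf("Newick syntax error at line %d, column %d: %s", line, col, msg),
       call. = FALSE)
}

.nwk_ws <- c(" ", "\t", "\r", "\n")
.nwk_stop <- c("(", ")", ",", ":", ";", "[", "]", "'", " ", "\t", "\r", "\n")

.nwk_skip_ws <- function(st) {
  while (st$i <= st$n && substr(st$s, st$i, st$i) %in% .nwk_ws) st$i <- st$i + 1L
}

.nwk_label <- function(st) {
  .nwk_skip_ws(st)
  ch <- .nwk_peek(st)
  if (ch == "'") {
    st$i <- st$i + 1L
    out <- character(0)
    repeat {
      if (st$i > st$n) .nwk_err(st, "unterminated quoted label")
      ch <- substr(st$s, st$i, st$i)
      if (ch == "'") {
        if (st$i + 1L <= st$n && substr(st$s, st$i + 1L, st$i + 1L) == "'") {
          out <- c(out, "'"); st$i <- st$i + 2L
        } else { st$i <- st$i + 1L; break }
      } else { out <- c(out, ch); st$i <- st$i + 1L }
    }
    paste(out, collapse = "")
  } else {
    start <- st$i
    while (st$i <= st$n && !(substr(st$s, st$i, st$i) %in% .nwk_stop))
      st$i <- st$i + 1L
    if (st$i == start) "" else substr(st$s, start, st$i - 1L)
  }
}

# Parses one subtree into builder `b` (env with parent/labels growing
# vectors); returns the node id.
.nwk_subtree <- function(st, b) {
  .nwk_skip_ws(st)
  v <- length(b$parent) + 1L
  b$parent[v] <- NA_integer_
  b$labels[[v]] <- character(0)
  if (.nwk_peek(st) == "(") {
    st$i <- st$i + 1L
    repeat {
      c <- .nwk_subtree(st, b)
      b$parent[c] <- v
      .nwk_skip_ws(st)
      ch <- .nwk_peek(st)
      if (ch == ",") { st$i <- st$i + 1L; next }
      if (ch == ")") { st$i <- st$i + 1L; break }
      .nwk_err(st, sprintf("expected ',' or ')', got '%s'", ch))
    }
  }
  lab <- .nwk_label(st)
  if (nzchar(lab)) b$labels[[v]] <- lab
  .nwk_skip_ws(st)
  if (.nwk_peek(st) == ":") {   # branch length: parse and discard
    st$i <- st$i + 1L
    .nwk_skip_ws(st)
    start <- st$i
    while (st$i <= st$n && grepl("^[0-9eE.+-]$", substr(st$s, st$i, st$i)))
      st$i <- st$i + 1L
    if (st$i == start) .nwk_err(st, "expected branch length after ':'")
    b$saw_brlen <- TRUE
  }
  v
}

#' Parse a single Newick tree
#'
#' @param text Newick text for one tree (trailing `;` optional).
#' @param multi_sep If non-`NULL`, every parsed label is split on this
#'   separator, so that multi-label supertree nodes written by
#'   [write_newick()] round-trip.  `NULL` (default) keeps labels intact.
#' @return An `slt` object.
#' @export
parse_newick <- function(text, multi_sep = NULL) {
  st <- .nwk_state(text)
  b <- new.env(parent = emptyenv())
  b$parent <- integer(0); b$labels <- list(); b$saw_brlen <- FALSE
  root <- .nwk_subtree(st, b)
  .nwk_skip_ws(st)
  if (.nwk_peek(st) == ";") st$i <- st$i + 1L
  .nwk_skip_ws(st)
  if (st$i <= st$n) .nwk_err(st, "trailing characters after tree")
  if (b$saw_brlen) warning("branch lengths present in input were discarded")
  parent <- b$parent; parent[root] <- 0L
  labels <- b$labels
  if (!is.null(multi_sep))
    labels <- lapply(labels, function(x)
      if (length(x)) strsplit(x, multi_sep, fixed = TRUE)[[1]] else x)
  labs <- unlist(labels, use.names = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate label in one tree: '", labs[duplicated(labs)][1], "'")
  slt(parent, labels)
}

#' Read a profile of semi-labeled trees from Newick text
#'
#' One tree per semicolon-terminated statement (newlines are
#' insignificant).  Labels may sit on any node; unlabeled internal nodes
#' are permitted and later receive fresh labels via
#' [add_distinct_labels()].
#'
#' @param path File to read, or `NULL` when `text` is given.
#' @param text Character scalar of Newick text (alternative to `path`).
#' @param multi_sep Passed to [parse_newick()].
#' @return An `slprofile`.
#' @export
read_profile <- function(path = NULL, text = NULL, multi_sep = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  }
  stmts <- strsplit(text, ";", fixed = TRUE)[[1]]
  stmts <- stmts[grepl("[^ \t\r\n]", stmts)]
  if (!length(stmts)) stop("empty profile: no trees found")
  new_profile(lapply(stmts, parse_newick, multi_sep = multi_sep))
}

.nwk_quote <- function(lab) {
  if (grepl("^[A-Za-z0-9_.|-]+$", lab)) lab
  else paste0("'", gsub("'", "''", lab, fixed = TRUE), "'")
}

#' Write a semi-labeled tree as Newick text
#'
#' Children of every node are ordered by the lexicographically smallest
#' label in their subtree, and label sets are rendered sorted, so output
#' is canonical: isomorphic trees serialize identically.
#'
#' @param tree An `slt` object (possibly multi-labeled).
#' @param multi_sep Separator joining co-located labels (default `"+"`).
#' @param strip_aux Drop `"__aux"` labels (via [strip_aux_labels()])
#'   before writing.
#' @return A character scalar ending in `";"`.
#' @export
write_newick <- function(tree, multi_sep = "+", strip_aux = FALSE) {
  if (strip_aux) tree <- strip_aux_labels(tree)
  ord <- rev(.slt_bfs(tree))
  minlab <- character(tree$nnode)
  txt <- character(tree$nnode)
  for (v in ord) {
    own <- sort(tree$labels[[v]])
    ch <- tree$children[[v]]
    cand <- c(own, minlab[ch])
    minlab[v] <- if (length(cand)) min(cand) else ""
    labtxt <- if (length(own)) .nwk_quote(paste(own, collapse = multi_sep)) else ""
    if (length(ch)) {
      ch <- ch[order(minlab[ch])]
      txt[v] <- paste0("(", paste(txt[ch], collapse = ","), ")", labtxt)
    } else txt[v] <- labtxt
  }
  paste0(txt[tree$root], ";")
}

#' Write a profile as Newick text
#'
#' @param profile An `slprofile`.
#' @param path Optional file; when `NULL` the text is returned.
#' @param ... Passed to [write_newick()].
#' @return Character vector of Newick statements (invisibly when writing
#'   to a file).
#' @export
write_profile <- function(profile, path = NULL, ...) {
  lines <- vapply(profile$trees, write_newick, "", ...)
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
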