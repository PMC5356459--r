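# Deterministic profile generators: a small fully worked example
# profile, compatible profiles obtained as restrictions of a hidden
# random supertree (compatible by construction, with the hidden tree as
# witness), and minimal incompatible profiles embedding known
# contradictions.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' The worked example profile
#'
#' A profile of three small semi-labeled trees over the labels
#' `a`..`i`: a phylogeny-like tree, a second tree with the nested group
#' `g(a,d)`, and a taxonomy-like third tree rooted at the higher-order
#' taxon `g`.  With `labeled = TRUE` (default) the internal nodes that
#' would otherwise be unlabeled carry the explicit labels `1`,`2`,`3`,`4`,
#' making the trees fully labeled; with `labeled = FALSE` those nodes
#' are unlabeled, as a user would supply them.
#'
#' @param labeled Include the four auxiliary numeral labels.
#' @return An `slprofile` of three trees.
#' @export
example_profile <- function(labeled = TRUE) {
  txt <- if (labeled)
    "(((b,c)a,d,e)3,f)1;
     (e,(h,i)f,(a,d)g)2;
     ((b,c)4,d)g;"
  else
    "(((b,c)a,d,e),f);
     (e,(h,i)f,(a,d)g);
     ((b,c),d)g;"
  read_profile(text = txt)
}

#' Generator configuration
#'
#' @param n_labels Size of the hidden supertree (number of nodes; all
#'   leaves plus a `label_density` fraction of internal nodes carry
#'   labels).
#' @param k_trees Number of input trees to emit.
#' @param label_density Probability that an internal node of the hidden
#'   supertree is labeled (leaves and single-child nodes always are).
#' @param subset_fraction Expected fraction of the hidden labels
#'   appearing in each input tree.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(n_labels = 100L, k_trees = 8L, label_density = 0.25,
                       subset_fraction = 0.2, seed = 1L) {
  stopifnot(n_labels >= 2L, k_trees >= 1L,
            label_density >= 0, label_density <= 1,
            subset_fraction > 0, subset_fraction <= 1)
  structure(list(n_labels = as.integer(n_labels), k_trees = as.integer(k_trees),
                 label_density = label_density,
                 subset_fraction = subset_fraction, seed = as.integer(seed)),
            class = "gen_config")
}

# Random tree by preferential attachment (new node picks a parent with
# probability proportional to degree), giving the heavy-tailed node
# degrees characteristic of taxonomies.
.random_topology <- function(m) {
  parent <- integer(m); parent[1] <- 0L
  if (m == 1L) return(parent)
  reps <- integer(2L * m); reps[1] <- 1L; nrep <- 1L
  for (v in 2:m) {
    parent[v] <- reps[sample.int(nrep, 1L)]
    reps[nrep + 1L] <- parent[v]
    reps[nrep + 2L] <- v
    nrep <- nrep + 2L
  }
  parent
}

#' Generate a compatible profile with a known witness
#'
#' Samples a hidden semi-labeled supertree, then emits `k_trees`
#' restrictions of it to random nonempty label subsets.  Restrictions of
#' a common tree are always ancestrally compatible, and the hidden tree
#' ancestrally displays every one of them, so it is returned as the
#' witness.
#'
#' @param config A [gen_config()].
#' @return List with `profile` (an `slprofile`) and `witness` (`slt`).
#' @export
gen_compatible <- function(config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  .with_seed(config$seed, {
    m <- config$n_labels
    parent <- .random_topology(m)
    nchild <- tabulate(parent, nbins = m)
    must <- nchild <= 1L                      # leaves and single-child nodes
    extra <- !must & runif(m) < config$label_density
    labeled <- which(must | extra)
    labs <- rep(NA_character_, m)
    labs[labeled] <- sprintf("t%d", seq_along(labeled))
    witness <- slt(parent, labs)
    all_labs <- slt_labels(witness)
    trees <- vector("list", config$k_trees)
    for (i in seq_len(config$k_trees)) {
      pick <- all_labs[runif(length(all_labs)) < config$subset_fraction]
      if (!length(pick)) pick <- sample(all_labs, 1L)
      trees[[i]] <- slt_restrict(witness, pick)
    }
    list(profile = new_profile(trees), witness = witness)
  })
}

#' Generate a minimal incompatible profile
#'
#' Each kind embeds a known contradiction:
#' \describe{
#'   \item{`ancestor-cycle`}{one tree makes `a` a proper ancestor of
#'     `b`, the other makes `b` a proper ancestor of `a`.}
#'   \item{`triplet-conflict`}{the rooted triplets `ab|c` and `ac|b`
#'     (internal nodes unlabeled; the engine's fresh labels complete
#'     them).}
#'   \item{`nesting-vs-separation`}{one tree nests `b` strictly below
#'     `a`; the other places `a` and `b` as incomparable siblings under
#'     the labeled parent `p`.}
#' }
#'
#' @param kind One of `"ancestor-cycle"`, `"triplet-conflict"`,
#'   `"nesting-vs-separation"`.
#' @param seed Unused by the fixed constructions; kept for interface
#'   symmetry with [gen_compatible()].
#' @return An `slprofile` of valid input trees.
#' @export
gen_incompatible <- function(kind = c("ancestor-cycle", "triplet-conflict",
                                      "nesting-vs-separation"),
                             seed = 1L) {
  kind <- match.arg(kind)
  txt <- switch(kind,
    "ancestor-cycle" = "(b)a; (a)b;",
    "triplet-conflict" = "((a,b),c); ((a,c),b);",
    "nesting-vs-separation" = "(b)a; (a,b)p;")
  read_profile(text = txt)
}
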