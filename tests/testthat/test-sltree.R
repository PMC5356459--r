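# Semi-labeled tree calculus: clusters, restriction, the D/N pair sets,
# ancestral display, and full labeling.

t1 <- function() parse_newick("(((b,c)a,d,e)3,f)1;")
t2 <- function() parse_newick("(e,(h,i)f,(a,d)g)2;")
t3 <- function() parse_newick("((b,c)4,d)g;")

test_that("clusters enumerate label sets of all subtrees", {
  single <- parse_newick("a;")
  expect_equal(cluster_keys(single), setkey("a"))
  expect_equal(cluster_keys(t3()),
               sort(c(setkey(c("g", "4", "d", "b", "c")), setkey(c("4", "b", "c")),
                      setkey("b"), setkey("c"), setkey("d"))))
  k1 <- cluster_keys(t1())
  expect_true(setkey(c("a", "b", "c")) %in% k1)
  expect_true(setkey(c("3", "a", "b", "c", "d", "e")) %in% k1)
  # root cluster is the full label set; one cluster per node when fully
  # and singularly labeled with distinct clusters
  expect_true(setkey(slt_labels(t1())) %in% k1)
  expect_length(k1, t1()$nnode)
})

test_that("restriction matches the cluster-set definition", {
  # identity restriction
  expect_true(slt_isomorphic(slt_restrict(t1(), slt_labels(t1())), t1()))
  # hand-computed example: t2 restricted to {a, d, h}
  r <- slt_restrict(t2(), c("a", "d", "h"))
  expect_equal(cluster_keys(r),
               sort(c(setkey(c("a", "d", "h")), setkey("h"),
                      setkey(c("a", "d")), setkey("a"), setkey("d"))))
  # chain a -> b -> c restricted to {a, c} is the chain a -> c
  chain <- parse_newick("((c)b)a;")
  expect_equal(cluster_keys(slt_restrict(chain, c("a", "c"))),
               sort(c(setkey(c("a", "c")), setkey("c"))))
  # errors
  expect_error(slt_restrict(t1(), character(0)), "nonempty")
  expect_error(slt_restrict(t1(), c("a", "zz")), "not in the tree")
})

test_that("suppression construction agrees with cluster intersection on random trees", {
  for (s in 1:10) {
    w <- gen_compatible(gen_config(n_labels = 40, k_trees = 1, seed = s))$witness
    labs <- slt_labels(w)
    set.seed(s)
    A <- sample(labs, max(2L, rbinom(1, length(labs), 0.4)))
    r <- slt_restrict(w, A)
    expected <- unique(vapply(slt_clusters(w), function(X) {
      setkey(intersect(X, A))
    }, ""))
    expected <- sort(expected[expected != ""])
    expect_equal(cluster_keys(r), expected)
    expect_length(slt_validate(r), 0)
  }
})

test_that("descendant and incomparable pair sets are as defined", {
  expect_equal(nrow(slt_desc_pairs(parse_newick("a;"))), 0)
  expect_equal(pairkeys(slt_desc_pairs(t3())),
               sort(c("g\r4", "g\rd", "g\rb", "g\rc", "4\rb", "4\rc")))
  expect_equal(pairkeys(slt_desc_pairs(parse_newick("(b)a;"))), "a\rb")
  expect_equal(nrow(slt_incomp_pairs(parse_newick("(b)a;"))), 0)
  expect_equal(pairkeys(slt_incomp_pairs(t3())),
               sort(c("4\rd", "b\rc", "b\rd", "c\rd")))
  star <- parse_newick("(x,y,z)r;")
  expect_equal(pairkeys(slt_incomp_pairs(star)),
               sort(c("x\ry", "x\rz", "y\rz")))
})

test_that("every label pair is in exactly one of D or N for full singular trees", {
  for (s in 1:5) {
    prof <- new_profile(list(gen_compatible(gen_config(n_labels = 30, k_trees = 1,
                                                       seed = s))$witness))
    w <- add_distinct_labels(prof)$profile$trees[[1]]
    labs <- slt_labels(w)
    d <- slt_desc_pairs(w); nn <- slt_incomp_pairs(w)
    both <- nrow(d) + nrow(nn)
    expect_equal(both, choose(length(labs), 2))  # singular => no co-located pairs
    dk <- unique(c(paste(d[, 1], d[, 2]), paste(d[, 2], d[, 1])))
    nk <- c(paste(nn[, 1], nn[, 2]), paste(nn[, 2], nn[, 1]))
    expect_length(intersect(dk, nk), 0)
  }
})

test_that("ancestral display holds reflexively and fails on reversed chains", {
  expect_true(ancestrally_displays(t1(), t1()))
  ab <- parse_newick("(b)a;"); ba <- parse_newick("(a)b;")
  expect_false(ancestrally_displays(ab, ba))
  expect_error(ancestrally_displays(ab, parse_newick("(z)a;")), "not contained")
})

test_that("restrictions of a displaying tree display the restricted profile", {
  for (s in 1:5) {
    gcp <- gen_compatible(gen_config(n_labels = 50, k_trees = 4, seed = s))
    w <- gcp$witness
    set.seed(100 + s)
    X <- sample(slt_labels(w), 20)
    wX <- slt_restrict(w, X)
    for (tr in gcp$profile$trees) {
      xi <- intersect(X, slt_labels(tr))
      if (length(xi))
        expect_true(ancestrally_displays(wX, slt_restrict(tr, xi)))
    }
  }
})

test_that("isomorphism ignores child order and detects direction", {
  a <- parse_newick("((b,c)a,d)r;")
  b <- parse_newick("(d,(c,b)a)r;")
  expect_true(slt_isomorphic(a, b))
  expect_false(slt_isomorphic(parse_newick("(b)a;"), parse_newick("(a)b;")))
  expect_true(slt_isomorphic(t1(), slt_restrict(t1(), slt_labels(t1()))))
})

test_that("adding distinct labels completes a profile and is invertible", {
  full <- add_distinct_labels(example_profile(labeled = TRUE))
  expect_length(full$added, 0)
  part <- add_distinct_labels(example_profile(labeled = FALSE))
  expect_length(part$added, 4)  # two unlabeled in tree 1, one each in 2 and 3
  expect_true(all(startsWith(part$added, "__aux")))
  for (tr in part$profile$trees)
    expect_length(slt_validate(tr, require_full = TRUE, require_singular = TRUE), 0)
  # original labels untouched
  expect_setequal(setdiff(part$profile$label_universe, part$added),
                  example_profile(labeled = FALSE)$label_universe)
  single <- new_profile(list(parse_newick("(x,y);")))
  expect_length(add_distinct_labels(single)$added, 1)
})

test_that("validation reports unlabeled leaves and single-child nodes", {
  expect_length(slt_validate(t1(), require_full = TRUE, require_singular = TRUE), 0)
  bad_leaf <- slt(c(0L, 1L), list("a", character(0)), check = FALSE)
  expect_match(slt_validate(bad_leaf), "unlabeled leaf", all = FALSE)
  bad_chain <- slt(c(0L, 1L), list(character(0), "a"), check = FALSE)
  expect_match(slt_validate(bad_chain), "single-child", all = FALSE)
  two_roots <- slt(c(0L, 0L), list("a", "b"), check = FALSE)
  expect_match(slt_validate(two_roots), "one root", all = FALSE)
})
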