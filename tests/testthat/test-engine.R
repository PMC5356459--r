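# The compatibility engine: root-state bookkeeping, semi-universal
# labels, successor/split updates, and the two engine implementations.

test_that("root state carries the root frontier, exposed set and weight", {
  fp <- add_distinct_labels(example_profile())$profile
  g <- build_display_graph(fp)
  st <- nestcomp:::.engine_init(fp, g)
  r <- st$recs[[1]]
  expect_equal(pos_keys(nestcomp:::.record_position(st, r)), c("1", "2", "g"))
  S <- nestcomp:::.semi_universal(st, r)
  expect_equal(sort(st$labels[S]), c("1", "2"))
  expect_equal(r$weight, sum(g$mult))   # sum of k_l over all labels
})

test_that("a single-node profile exposes its only label", {
  fp <- new_profile(list(parse_newick("x;")))
  g <- build_display_graph(fp)
  st <- nestcomp:::.engine_init(fp, g)
  r <- st$recs[[1]]
  expect_equal(pos_keys(nestcomp:::.record_position(st, r)), "x")
  expect_equal(st$labels[nestcomp:::.semi_universal(st, r)], "x")
  expect_equal(r$weight, 1)
})

test_that("successor splits the worked root position into the printed components", {
  fp <- add_distinct_labels(example_profile())$profile
  g <- build_display_graph(fp)
  st <- nestcomp:::.engine_init(fp, g)
  r <- st$recs[[1]]
  frags <- nestcomp:::.successor_apply(st, r, nestcomp:::.semi_universal(st, r))
  expect_length(frags, 2)
  mems <- lapply(frags, function(fr) sort(st$labels[nestcomp:::hdt_members(st$ptr, fr$rep)]))
  keys <- vapply(mems, paste, "", collapse = ",")
  expect_setequal(keys, c("3,4,a,b,c,d,e,g", "f,h,i"))
  wts <- vapply(frags, function(fr) fr$weight, 0)
  expect_setequal(wts, c(15, 4))   # sums of k_l over the two member sets
  poss <- lapply(frags, function(fr)
    paste(pos_keys(nestcomp:::.record_position(st, fr)), collapse = "|"))
  expect_setequal(unlist(poss), c("3|e,g|g", "f|f|"))
})

test_that("an empty semi-universal set means incompatibility", {
  res <- build_supertree(gen_incompatible("ancestor-cycle"))
  expect_false(res$compatible)
  expect_null(res$tree)
  res2 <- build_supertree(gen_incompatible("ancestor-cycle"), engine = "recursive")
  expect_false(res2$compatible)
})

test_that("worked example produces the expected supertree from both engines", {
  for (eng in c("iterative", "recursive")) {
    res <- build_supertree(example_profile(), engine = eng)
    expect_true(res$compatible)
    expect_true(slt_isomorphic(res$tree, expected_supertree()))
    for (tr in example_profile()$trees)
      expect_true(ancestrally_displays(res$tree, tr))
  }
  expect_equal(write_newick(build_supertree(example_profile())$tree),
               "((((b,c)'4+a',d)g,e)3,(h,i)f)'1+2';")
})

test_that("leaf consumption terminates cleanly", {
  # the same single label in two trees: one supertree node, no recursion
  fp <- new_profile(list(parse_newick("e;"), parse_newick("e;")))
  res <- build_supertree(fp)
  expect_true(res$compatible)
  expect_equal(res$tree$nnode, 1L)
  expect_equal(slt_labels(res$tree), "e")
})

test_that("disconnected profiles are solved per component", {
  two <- new_profile(list(parse_newick("(a,b)r;"), parse_newick("(x,y)s;")))
  res <- build_supertree(two)
  expect_true(res$compatible)
  expect_length(res$tree$labels[[res$tree$root]], 0)   # fresh unlabeled join root
  expect_length(res$tree$children[[res$tree$root]], 2)
  for (tr in two$trees) expect_true(ancestrally_displays(res$tree, tr))
  forest <- build_supertree(two, join_components = FALSE)
  expect_null(forest$tree)
  expect_length(forest$forest, 2)
})

test_that("unlabeled inputs are completed and auxiliary labels stripped", {
  res <- build_supertree(example_profile(labeled = FALSE))
  expect_true(res$compatible)
  expect_false(any(startsWith(slt_labels(res$tree), "__aux")))
  for (tr in example_profile(labeled = FALSE)$trees)
    expect_true(ancestrally_displays(res$tree, tr))
  kept <- build_supertree(example_profile(labeled = FALSE), strip_aux = FALSE)
  expect_true(any(startsWith(slt_labels(kept$tree), "__aux")))
})

test_that("engines agree on random mixed profiles", {
  for (s in 1:20) {
    gcp <- gen_compatible(gen_config(n_labels = sample(10:120, 1),
                                     k_trees = sample(2:6, 1), seed = s))
    prof <- if (s %% 3 == 0) perturb_incompatible(gcp$profile, s) else gcp$profile
    r1 <- build_supertree(prof, engine = "iterative")
    r2 <- build_supertree(prof, engine = "recursive")
    expect_equal(r1$compatible, r2$compatible)
    if (r1$compatible) expect_true(slt_isomorphic(r1$tree, r2$tree))
  }
})

test_that("each label becomes semi-universal at most once", {
  res <- build_supertree(example_profile(), trace = TRUE)
  s_all <- unlist(lapply(res$trace[[1]], `[[`, "S"))
  expect_false(anyDuplicated(s_all) > 0)
  gcp <- gen_compatible(gen_config(n_labels = 80, seed = 5))
  res2 <- build_supertree(gcp$profile, trace = TRUE)
  s_all2 <- unlist(lapply(res2$trace, function(tr) lapply(tr, `[[`, "S")))
  expect_false(anyDuplicated(s_all2) > 0)
})

test_that("work counters respect the deletion bound", {
  for (s in 1:5) {
    gcp <- gen_compatible(gen_config(n_labels = 100, seed = s))
    res <- build_supertree(gcp$profile)
    expect_lte(res$stats$deletions,
               res$stats$graph_vertices + res$stats$graph_edges)
  }
})
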