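# Dynamic connectivity: contract semantics and agreement with a
# from-scratch BFS oracle.

test_that("insert and delete obey the basic contract", {
  dc <- dc_new(c("a", "b", "c"))
  dc_insert_edge(dc, "a", "b")
  expect_true(dc_connected(dc, "a", "b"))
  expect_false(dc_connected(dc, "a", "c"))
  expect_equal(dc_component_size(dc, "a"), 2)
  expect_equal(dc_component_size(dc, "c"), 1)
  dc_insert_edge(dc, "a", "b")                  # duplicate: no-op
  expect_equal(dc_stats(dc)$n_edges, 1)
  res <- dc_delete_edge(dc, "a", "b")
  expect_true(res$split)
  expect_equal(sort(c(res$size_u, res$size_v)), c(1, 1))
  expect_error(dc_delete_edge(dc, "a", "b"), "not present")
  expect_error(dc_insert_edge(dc, "a", "z"), "unknown vertex")
  expect_true(dc_connected(dc, "c", "c"))
  expect_equal(dc_component_members(dc, "c"), "c")
})

test_that("cycle edges do not split", {
  dc <- dc_new(c("a", "b", "c"))
  dc_insert_edge(dc, "a", "b"); dc_insert_edge(dc, "b", "c"); dc_insert_edge(dc, "a", "c")
  expect_false(dc_delete_edge(dc, "a", "b")$split)
  expect_true(dc_connected(dc, "a", "b"))
  expect_true(dc_delete_edge(dc, "b", "c")$split)
})

test_that("the worked display graph splits as printed", {
  g <- build_display_graph(example_profile())
  dc <- dc_new(g$labels)
  for (e in seq_len(nrow(g$edges)))
    dc_insert_edge(dc, g$labels[g$edges[e, 1]], g$labels[g$edges[e, 2]])
  expect_equal(dc_component_size(dc, "b"), 13)
  expect_true(dc_connected(dc, "b", "i"))
  # consume the roots: delete all edges incident to labels 1 and 2
  for (v in c("3", "f")) dc_delete_edge(dc, "1", v)
  for (v in c("e", "f", "g")) dc_delete_edge(dc, "2", v)
  expect_false(dc_connected(dc, "e", "h"))
  expect_equal(dc_component_size(dc, "f"), 3)
  expect_setequal(dc_component_members(dc, "f"), c("f", "h", "i"))
  expect_setequal(dc_component_members(dc, "e"),
                  c("3", "4", "a", "b", "c", "d", "e", "g"))
})

test_that("split reports partition the old component", {
  set.seed(11)
  n <- 25
  dc <- dc_new(n)
  edges <- t(combn(n, 2)); edges <- edges[sample(nrow(edges), 40), ]
  for (e in seq_len(nrow(edges))) dc_insert_edge(dc, edges[e, 1], edges[e, 2])
  cur <- edges
  while (nrow(cur)) {
    i <- sample(nrow(cur), 1)
    u <- cur[i, 1]; v <- cur[i, 2]
    before <- dc_component_members(dc, u)
    res <- dc_delete_edge(dc, u, v)
    cur <- cur[-i, , drop = FALSE]
    if (res$split) {
      mu <- dc_component_members(dc, u); mv <- dc_component_members(dc, v)
      expect_false(dc_connected(dc, u, v))
      expect_length(intersect(mu, mv), 0)
      expect_setequal(c(mu, mv), before)
      expect_equal(length(mu), res$size_u)
      expect_equal(length(mv), res$size_v)
    } else {
      expect_true(dc_connected(dc, u, v))
      expect_setequal(dc_component_members(dc, u), before)
    }
  }
})

test_that("randomized delete sequences agree with the BFS oracle", {
  total_ops <- 0
  for (s in 1:6) {
    set.seed(s)
    n <- sample(20:60, 1)
    m <- min(choose(n, 2), 4 * n)
    edges <- t(combn(n, 2)); edges <- edges[sample(nrow(edges), m), , drop = FALSE]
    dc <- dc_new(n)
    for (e in seq_len(nrow(edges))) dc_insert_edge(dc, edges[e, 1], edges[e, 2])
    cur <- edges
    while (nrow(cur)) {
      i <- sample(nrow(cur), 1)
      res <- dc_delete_edge(dc, cur[i, 1], cur[i, 2])
      cur <- cur[-i, , drop = FALSE]
      total_ops <- total_ops + 1
      memb <- bfs_membership(n, cur)
      w <- sample(n, 1)
      expect_equal(dc_component_size(dc, w), sum(memb == memb[w]))
      expect_setequal(as.integer(dc_component_members(dc, w)), which(memb == memb[w]))
      u2 <- sample(n, 1); v2 <- sample(n, 1)
      expect_equal(dc_connected(dc, u2, v2), memb[u2] == memb[v2])
    }
  }
  expect_gte(total_ops, 500)
})
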