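test_that("identical points produce unit membership weights", {
  block <- matrix(1, nrow = 3, ncol = 4)
  g <- build_fuzzy_graph(block, embedding_params(2, 0.5, 0.2, 1.5, "canberra"))
  off <- g$w[upper.tri(g$w)]
  expect_true(all(off == 1))
  expect_equal(unname(diag(g$w)), rep(0, 3))
})

test_that("well-separated clouds get no strong cross-cloud edge", {
  set.seed(2)
  cloud1 <- matrix(sample(0:1, 60, replace = TRUE), nrow = 12)
  cloud2 <- cloud1 + 40  # same shape, shifted far away in code space
  block <- rbind(cloud1, cloud2)
  g <- build_fuzzy_graph(block, embedding_params(5, 0.5, 0.2, 1.5, "canberra"))
  cross <- g$w[1:12, 13:24]
  expect_true(all(cross <= 0.5))
  within <- g$w[1:12, 1:12]
  expect_gt(max(within), 0.9)
})

test_that("graph weights are symmetric and bounded", {
  set.seed(9)
  block <- matrix(sample(0:9, 200, replace = TRUE), nrow = 20)
  g <- build_fuzzy_graph(block, embedding_params(6, 0.5, 0.2, 1.5, "canberra"))
  expect_lt(max(abs(g$w - t(g$w))), 1e-12)
  expect_true(all(g$w >= 0 & g$w <= 1))
  # permutation equivariance
  perm <- sample(20)
  g2 <- build_fuzzy_graph(block[perm, ], embedding_params(6, 0.5, 0.2, 1.5, "canberra"))
  expect_equal(g2$w, g$w[perm, perm], tolerance = 1e-12)
})

test_that("intersection obeys the product t-norm algebra", {
  set.seed(3)
  block <- matrix(sample(0:9, 120, replace = TRUE), nrow = 12)
  g <- build_fuzzy_graph(block, embedding_params(4, 0.5, 0.2, 1.5, "canberra"))
  ones <- bcrlmap:::new_fuzzy_graph(matrix(1, 12, 12) - diag(12))
  # identity of the product t-norm, up to the floor on absent edges
  fused <- intersect_graphs(g, ones, reset_local_connectivity = FALSE)
  expect_equal(fused$w[g$w > 0], g$w[g$w > 0])
  # self-intersection squares the weights (before flooring)
  sq <- intersect_graphs(g, g, reset_local_connectivity = FALSE)
  expect_equal(sq$w[g$w > 0], g$w[g$w > 0]^2)
  # commutativity
  block2 <- matrix(sample(0:9, 120, replace = TRUE), nrow = 12)
  g2 <- build_fuzzy_graph(block2, embedding_params(4, 0.5, 0.2, 1.5, "canberra"))
  ab <- intersect_graphs(g, g2, reset_local_connectivity = FALSE)
  ba <- intersect_graphs(g2, g, reset_local_connectivity = FALSE)
  expect_equal(ab$w, ba$w)
})

test_that("disjoint strong edge sets fuse to at most the floor ceiling", {
  w1 <- matrix(0, 6, 6); w1[1, 2] <- w1[2, 1] <- 0.9; w1[3, 4] <- w1[4, 3] <- 0.8
  w2 <- matrix(0, 6, 6); w2[5, 6] <- w2[6, 5] <- 0.9; w2[1, 3] <- w2[3, 1] <- 0.7
  g <- intersect_graphs(bcrlmap:::new_fuzzy_graph(w1),
                        bcrlmap:::new_fuzzy_graph(w2),
                        eps_ratio = 1e-3, reset_local_connectivity = FALSE)
  expect_true(all(g$w <= 1e-3 * 0.9^2 + 1e-12))
  expect_error(
    intersect_graphs(bcrlmap:::new_fuzzy_graph(w1),
                     bcrlmap:::new_fuzzy_graph(matrix(0, 5, 5))),
    "same number of nodes"
  )
})

test_that("the default fusion keeps every patient attached with weights in (0,1]", {
  set.seed(5)
  b1 <- matrix(sample(0:9, 300, replace = TRUE), nrow = 30)
  b2 <- matrix(sample(0:1, 300, replace = TRUE), nrow = 30)
  g <- intersect_graphs(
    build_fuzzy_graph(b1, embedding_params(5, 0.5, 0.2, 1.5, "canberra")),
    build_fuzzy_graph(b2, embedding_params(5, 0.5, 0.99, 3, "correlation"))
  )
  expect_true(all(g$w >= 0 & g$w <= 1))
  expect_true(all(apply(g$w, 1, max) > 0.99))  # local connectivity reset
  edges <- graph_edges(g)
  expect_true(all(edges$i < edges$j))
  expect_true(all(edges$weight > 0))
})
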