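toy_W <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["a", "c"] <- W["c", "a"] <- 0.4
  W["b", "c"] <- W["c", "b"] <- 0.6
  W
}

test_that("strength matches direct evaluation and closed forms", {
  expect_equal(unname(node_strength(toy_W())), c(0.9, 1.1, 1.0))
  expect_equal(node_strength(matrix(0, 4, 4)), rep(0, 4))
  # star: center strength k * w
  k <- 5; w <- 0.7
  W <- matrix(0, k + 1, k + 1)
  W[1, 2:(k + 1)] <- W[2:(k + 1), 1] <- w
  expect_equal(node_strength(W)[1], k * w)
})

test_that("inverse participation matches direct evaluation and its bounds", {
  Y <- inverse_participation(toy_W())
  expect_equal(unname(Y[1]), (0.5 / 0.9)^2 + (0.4 / 0.9)^2)
  # k equal weights -> 1/k; single edge -> 1; isolated -> 0
  k <- 6
  W <- matrix(0, k + 1, k + 1)
  W[1, 2:(k + 1)] <- W[2:(k + 1), 1] <- 0.4
  expect_equal(inverse_participation(W)[1], 1 / k)
  W2 <- matrix(0, 3, 3); W2[1, 2] <- W2[2, 1] <- 0.8
  expect_equal(inverse_participation(W2)[1:3], c(1, 1, 0))
})

test_that("degree-conditional means average within degree classes", {
  cm <- conditional_means(toy_W())
  expect_equal(unname(cm$s_k), rep(1.0, 3))           # triangle: all degree 2
  expect_identical(cm$table$n_k, 3L)
  # all-distinct degrees: the conditional mean is the node's own value
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.5
  W[2, 4] <- W[4, 2] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.5
  # degrees: 1, 3, 2, 2
  cm2 <- conditional_means(W)
  expect_equal(cm2$s_k[1], node_strength(W)[1])
  expect_equal(cm2$s_k[2], node_strength(W)[2])
  expect_equal(cm2$s_k[3], mean(node_strength(W)[3:4]))
  # empty layer: everything 0
  cm0 <- conditional_means(matrix(0, 3, 3))
  expect_equal(cm0$s_k, rep(0, 3))
  expect_equal(cm0$y_k, rep(0, 3))
})

test_that("aggregate adjacency is the union of layer supports", {
  W1 <- matrix(0, 3, 3); W1[1, 2] <- W1[2, 1] <- 0.5
  W2 <- matrix(0, 3, 3); W2[1, 3] <- W2[3, 1] <- -0.4   # signed-mode edge
  mux <- multiplex(list(make_layer(W1), make_layer(W2)))
  agg <- aggregate_adjacency(mux)
  expect_equal(agg$A[1, 2], 1)
  expect_equal(agg$A[1, 3], 1)
  expect_equal(agg$A[2, 3], 0)
  expect_equal(agg$k_multi, c(2L, 1L, 1L))
  # single layer: support of W; repeated layers: unchanged
  m1 <- multiplex(list(make_layer(toy_W())))
  expect_equal(unname(aggregate_adjacency(m1)$A), unname((toy_W() != 0) * 1L))
  m5 <- multiplex(rep(list(make_layer(toy_W())), 5))
  expect_equal(aggregate_adjacency(m5)$A, aggregate_adjacency(m1)$A)
})

test_that("multiplex node features reduce correctly for a single layer", {
  l <- make_layer(toy_W())
  m1 <- multiplex(list(l))
  agg <- aggregate_adjacency(m1)
  mf <- multiplex_node_features(l, agg)
  expect_equal(unname(mf$ms), unname((2 / 2) * node_strength(toy_W())))
  expect_equal(unname(mf$my), unname(inverse_participation(toy_W())))
  # fully disconnected node: all four multiplex features 0
  W <- matrix(0, 4, 4); W[1, 2] <- W[2, 1] <- 0.9
  m <- multiplex(list(make_layer(W)))
  mfd <- multiplex_node_features(m$layers[[1]], aggregate_adjacency(m))
  expect_equal(mfd$ms[3:4], c(0, 0))
  expect_equal(mfd$ms_k[3:4], c(0, 0))
  expect_equal(mfd$my_k[3:4], c(0, 0))
})

test_that("the feature matrix has the documented shape and order", {
  mux <- multiplex(list(make_layer(toy_W(), "s1"), make_layer(toy_W() / 2, "s2")))
  F <- feature_matrix(mux)
  expect_identical(dim(F), c(2L, 24L))
  expect_identical(colnames(F)[1:3], c("strength_a", "strength_b", "strength_c"))
  expect_identical(rownames(F), c("s1", "s2"))
  expect_false(anyNA(F))
  # permuting subjects permutes rows only
  F2 <- feature_matrix(multiplex(list(make_layer(toy_W() / 2, "s2"),
                                      make_layer(toy_W(), "s1"))))
  expect_equal(F2[c("s1", "s2"), ], F[c("s1", "s2"), ])
})

test_that("all eight features match the brute-force loop oracles", {
  set.seed(31)
  for (rep in 1:25) {
    N <- sample(3:10, 1)
    M <- sample(1:5, 1)
    signed <- rep %% 2 == 0
    Ws <- lapply(seq_len(M), function(i) random_W(N, runif(1, 0.2, 0.9), signed))
    mux <- multiplex(lapply(Ws, make_layer))
    F <- feature_matrix(mux)
    oracle <- oracle_all_features(Ws)
    for (a in seq_len(M)) for (m in feature_metrics()) {
      got <- unname(F[a, paste(m, mux$node_ids, sep = "_")])
      expect_equal(got, oracle[[a]][[m]], tolerance = 1e-12,
                   label = sprintf("metric %s layer %d (rep %d)", m, a, rep))
    }
  }
})

test_that("abs-weight features respect their analytic bounds", {
  set.seed(32)
  for (rep in 1:10) {
    W <- random_W(8, density = 0.5)
    mux <- multiplex(list(make_layer(W)))
    s <- node_strength(W); Y <- inverse_participation(W); k <- node_degree(W)
    con <- k >= 1
    expect_true(all(Y[con] >= 1 / k[con] - 1e-12))
    expect_true(all(Y[con] <= 1 + 1e-12))
    mf <- multiplex_node_features(mux$layers[[1]], aggregate_adjacency(mux))
    expect_true(all(mf$ms >= -1e-12 & mf$ms <= s + 1e-12))
  }
})

test_that("held-out rows perturb only the aggregate bookkeeping", {
  set.seed(33)
  Ws <- lapply(1:3, function(i) random_W(6, 0.5))
  mux <- multiplex(lapply(Ws, make_layer))
  F <- feature_matrix(mux)
  # duplicate of a training layer: its row equals the training row
  row <- append_test_layer_features(mux, make_layer(Ws[[2]]))
  expect_equal(unname(row), unname(F[2, ]), tolerance = 1e-12)
  # empty new layer: all-zero row
  row0 <- append_test_layer_features(mux, make_layer(matrix(0, 6, 6)))
  expect_equal(unname(row0), rep(0, 48))
  # one novel edge raises exactly two aggregate degrees by one
  A_old <- aggregate_adjacency(mux)$A
  absent <- which(A_old == 0 & upper.tri(A_old), arr.ind = TRUE)[1, ]
  Wnew <- matrix(0, 6, 6)
  Wnew[absent[1], absent[2]] <- Wnew[absent[2], absent[1]] <- 0.9
  mux2 <- multiplex(c(mux$layers, list(make_layer(Wnew))))
  k_new <- aggregate_adjacency(mux2)$k_multi
  k_old <- aggregate_adjacency(mux)$k_multi
  expect_equal(sort(which(k_new != k_old)), sort(unname(absent)))
  expect_equal(sum(k_new - k_old), 2L)
  expect_error(append_test_layer_features(mux, make_layer(matrix(0, 5, 5))),
               "training grid")
})
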