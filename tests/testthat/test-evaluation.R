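test_that("classification metrics handle degenerate truth sets", {
  m <- classification_metrics(c("disease", "control", "disease"),
                              c("disease", "control", "control"))
  expect_equal(unname(m), c(2 / 3, 1, 1 / 2))
  one <- classification_metrics(rep("disease", 3), rep("disease", 3))
  expect_equal(one[["sensitivity"]], 1)
  expect_true(is.na(one[["specificity"]]))
})

test_that("the final model trains, predicts and guards its columns", {
  d <- separable_layers(n_per_class = 10L)
  F <- feature_matrix(multiplex(d$layers))
  sel <- c("strength_n01", "strength_n02", "mstrength_n01")
  model <- train_final(F, d$labels, sel, selection_config(n_trees = 200L), seed = 3)
  pred <- predict(model, F)
  expect_gte(mean(pred == d$labels), 0.95)
  model2 <- train_final(F, d$labels, sel, selection_config(n_trees = 200L), seed = 3)
  expect_identical(predict(model2, F), pred)
  expect_error(train_final(F, d$labels, character(0)), "empty selection")
  expect_error(train_final(F, d$labels, "no_such_feature"), "missing")
  expect_error(predict(model, F[, 1:5]), "feature columns")
})

test_that("held-out evaluation bootstraps with shrinking uncertainty", {
  d <- separable_layers(n_per_class = 12L, seed = 8L)
  tr <- c(1:9, 13:21); te <- c(10:12, 22:24)
  mux <- multiplex(d$layers[tr])
  F <- feature_matrix(mux)
  sel <- c("strength_n01", "mstrength_n01")
  model <- train_final(F, d$labels[tr], sel, selection_config(n_trees = 200L))
  rep1 <- evaluate_test(model, mux, d$layers[te], d$labels[te],
                        n_boot = 50L, seed = 1)
  expect_gte(rep1$accuracy, 0.9)
  expect_true(all(c(rep1$sensitivity, rep1$specificity) >= 0,
                  c(rep1$sensitivity, rep1$specificity) <= 1))
  # one-class test set: specificity missing, not zero
  one <- evaluate_test(model, mux, d$layers[22:24], d$labels[22:24],
                       n_boot = 20L, seed = 1)
  expect_true(is.na(one$specificity))
  expect_false(is.na(one$sensitivity))
  # bootstrap SE shrinks roughly like 1/sqrt(n_boot) on a fixed prediction set
  d2 <- separable_layers(n_per_class = 20L, seed = 9L)
  mux2 <- multiplex(d2$layers[c(1:10, 21:30)])
  F2 <- feature_matrix(mux2)
  model2 <- train_final(F2, d2$labels[c(1:10, 21:30)], sel,
                        selection_config(n_trees = 200L))
  te2 <- c(11:20, 31:40)
  # mislabel part of the truth so the bootstrap has genuine variance
  truth2 <- d2$labels[te2]
  truth2[c(1:3, 11:13)] <- truth2[c(11:13, 1:3)]
  se_small <- evaluate_test(model2, mux2, d2$layers[te2], truth2,
                            n_boot = 25L, seed = 2)$accuracy_se
  se_big <- evaluate_test(model2, mux2, d2$layers[te2], truth2,
                          n_boot = 1600L, seed = 2)$accuracy_se
  expect_gt(se_big, 0)
  expect_lt(abs(se_small / se_big - 1), 0.6)
})

test_that("voxel shuffling is the identity at zero and collapses correlations in full", {
  set.seed(41)
  P <- matrix(rnorm(200 * 6), 200, 6)
  expect_identical(mplexmorph:::shuffle_patch_matrix(P, 0L), P)
  # full shuffle on i.i.d. noise: mean |r| stays near zero while structured
  # patches lose their correlation
  base <- cbind(a = sin(1:200 / 10), b = sin(1:200 / 10) + rnorm(200, 0, 0.1))
  r_before <- abs(cor(base)[1, 2])
  r_after <- replicate(20, {
    S <- mplexmorph:::shuffle_patch_matrix(base, 200L)
    abs(cor(S)[1, 2])
  })
  expect_gt(r_before, 0.9)
  expect_lt(mean(r_after), 0.2)
})

test_that("the threshold sweep reports a monotone empty-network profile", {
  co <- small_cohort()
  mats <- lapply(co$volumes[c(1:4, 11:14)], patch_matrix, grid = small_grid())
  sw <- threshold_sweep(mats, co$labels[c(1:4, 11:14)],
                        taus = c(0, 0.3, 0.6, 0.9, 0.99), classify = FALSE)
  expect_true(all(diff(sw$empty_fraction) >= 0))
  # tau = 0 keeps every nonzero correlation
  R <- cor(mats[[1]])
  l0 <- build_layer(mats[[1]], config = correlation_config(threshold = 0))
  expect_equal(sum(l0$W != 0), sum(R[upper.tri(R)] != 0) * 2)
})

test_that("label permutation returns a calibrated null at toy scale", {
  d <- separable_layers(n_per_class = 6L, seed = 10L)
  cfg <- selection_config(n_rounds = 2L, n_trees = 60L, k_folds = 3L, seed = 1L)
  out <- label_permutation_test(d$layers, d$labels, cfg, n_perm = 6L, seed = 3L)
  expect_length(out$accuracies, 6L)
  expect_gt(out$observed, max(0.6, mean(out$accuracies)))
  expect_lte(out$p_empirical, 0.5)
  expect_error(label_permutation_test(d$layers, d$labels, cfg, n_perm = 0L),
               "n_perm")
})

test_that("hemisphere restrictions partition the feature columns", {
  g <- small_grid()
  rb <- retained_boxes(g)
  nL <- sum(rb$hemisphere == "L"); nR <- sum(rb$hemisphere == "R")
  expect_identical(nL + nR, n_nodes(g))
  # half multiplex on a symmetric mask keeps about half the nodes
  expect_equal(nL, n_nodes(g) / 2)
  co <- small_cohort()
  idx <- c(1:6, 11:16)
  layers <- small_layers()[idx]
  cfg <- selection_config(n_rounds = 2L, n_trees = 100L, k_folds = 3L, seed = 2L)
  res <- hemisphere_experiments(layers, co$labels[idx], g,
                                mode = "half_multiplex", sel_config = cfg)
  expect_identical(res$hemisphere, c("L", "R"))
  expect_identical(res$n_nodes, c(nL, nR))
  # lesions are left-only: the left half-multiplex must not underperform
  expect_gte(res$accuracy[1], res$accuracy[2])
})
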