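# a deterministic selection_result built from chosen counts
fake_selection <- function(counts, n_trials = 100L, alpha = 0.01) {
  occurrence_test(counts, n_trials, alpha)
}

test_that("patch/atlas overlap counts voxels per label", {
  atlas <- array(0L, dim = c(10L, 10L, 10L))
  atlas[1:10, 1:6, 1:10] <- 3L
  atlas[1:10, 7:10, 1:10] <- 7L
  box <- list(x0 = 1L, y0 = 2L, z0 = 1L, l1 = 5L, l2 = 9L, l3 = 4L)
  # hand count: y 2..10 inside label 3 for y 2..6 (5 planes), label 7 for 7..10
  ov <- patch_regions(box, atlas)
  expect_equal(ov[["3"]], 5L * 5L * 4L)
  expect_equal(ov[["7"]], 5L * 4L * 4L)
  # constant label: a single entry of the full box
  const <- array(1L, dim = c(10L, 10L, 10L))
  expect_equal(patch_regions(list(x0 = 2L, y0 = 2L, z0 = 2L, l1 = 3L, l2 = 3L,
                                  l3 = 3L), const)[["1"]], 27L)
  # background-only box: empty map
  expect_length(patch_regions(list(x0 = 1L, y0 = 1L, z0 = 1L, l1 = 1L, l2 = 1L,
                                   l3 = 1L), atlas * 0L), 0L)
  expect_error(patch_regions(list(x0 = 9L, y0 = 1L, z0 = 1L, l1 = 5L, l2 = 2L,
                                  l3 = 2L), atlas), "bounds")
})

test_that("node significance takes the minimum over selected direct features", {
  counts <- c(strength_L001 = 95L, ipr_L001 = 88L, mstrength_L002 = 92L,
              strength_L003 = 10L, strengthk_L004 = 96L,
              rep(c(x = 8L), 40))
  names(counts)[6:45] <- sprintf("ipr_R%03d", 1:40)
  res <- fake_selection(counts)
  ns <- node_significance(res)
  # L004 carries only a conditional feature: absent from the direct map
  expect_false("L004" %in% ns$node)
  expect_false("L003" %in% ns$node)   # not selected
  expect_true(all(c("L001", "L002") %in% ns$node))
  p1 <- res$p_value[res$feature == "strength_L001"]
  p2 <- res$p_value[res$feature == "ipr_L001"]
  expect_equal(ns$p_value[ns$node == "L001"], min(p1, p2))
})

test_that("conditional-feature patches match a loop-and-summation oracle", {
  set.seed(51)
  for (rep in 1:5) {
    N <- 8L; M <- 12L
    Ws <- lapply(1:M, function(i) random_W(N, runif(1, 0.2, 0.6)))
    mux <- multiplex(lapply(Ws, make_layer))
    feat <- paste0("strengthk_", mux$node_ids[3])
    got <- conditional_feature_patches(mux, feat, alpha = 0.05)
    # oracle: recount memberships by loops
    counts <- integer(N); fr <- numeric(M)
    for (a in 1:M) {
      k <- oracle_degree(Ws[[a]])
      members <- which(k == k[3])
      counts[members] <- counts[members] + 1L
      fr[a] <- length(members) / N
    }
    p0 <- mean(fr)
    for (i in 1:N) {
      expect_identical(got$count[i], counts[i])
      expect_equal(got$p_value[i], oracle_binom_tail(counts[i], M, p0),
                   tolerance = 1e-12)
    }
    expect_identical(got$kept, got$p_value < 0.05)
  }
  expect_error(conditional_feature_patches(
    multiplex(list(make_layer(random_W(4)))), "strength_n01"),
    "not a conditional-mean")
})

test_that("aggregate-degree conditional features use the multiplex degree", {
  W1 <- matrix(0, 4, 4); W1[1, 2] <- W1[2, 1] <- 0.5
  W2 <- matrix(0, 4, 4); W2[3, 4] <- W2[4, 3] <- 0.6
  mux <- multiplex(list(make_layer(W1), make_layer(W2)))
  got <- conditional_feature_patches(mux, "mstrengthk_1", alpha = 0.5)
  # aggregate degrees are all 1 -> every node is in the class in every layer
  expect_equal(got$count, rep(2L, 4))
})

test_that("the region report aggregates by minimum p with no orphan regions", {
  g <- small_grid()
  tpl <- small_template()
  co <- small_cohort()
  rb <- retained_boxes(g)
  # mark two direct features on known nodes (one per hemisphere)
  nodes <- c(rb$node_id[rb$hemisphere == "L"][1], rb$node_id[rb$hemisphere == "R"][1])
  counts <- stats::setNames(rep(3L, 2 + 50), c(paste0("strength_", nodes),
                                               sprintf("ipr_X%03d", 1:50)))
  counts[1:2] <- c(98L, 91L)
  res <- fake_selection(counts)
  rep <- region_report(res, NULL, g, co$atlas, co$atlas_names)
  expect_s3_class(rep, "region_report")
  expect_true(all(rep$region %in% co$atlas_names$name))
  expect_true(all(rep$n_patches >= 1L))
  expect_true(!is.unsorted(rep$p_value))
  expect_true(all(rep$hemisphere_l + rep$hemisphere_r >= 1L))
  # no significant features: empty report, not an error
  none <- fake_selection(stats::setNames(rep(3L, 40), sprintf("ipr_R%03d", 1:40)))
  rep0 <- region_report(none, NULL, g, co$atlas, co$atlas_names)
  expect_identical(nrow(rep0), 0L)
})
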