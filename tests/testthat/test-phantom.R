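test_that("template is mirror symmetric with sane mask coverage", {
  tpl <- generate_template(c(64L, 72L, 60L), seed = 3)
  X <- dim(tpl$volume)[1L]
  expect_identical(tpl$volume, tpl$volume[X:1, , ])
  expect_identical(tpl$mask, tpl$mask[X:1, , ])
  frac <- mean(tpl$mask)
  expect_gt(frac, 0.15)
  expect_lt(frac, 0.75)
  expect_gte(length(setdiff(unique(as.integer(tpl$atlas)), 0L)), 4L)
  expect_true(all(tpl$atlas[!tpl$mask] == 0L))
  expect_error(generate_template(c(8, 64, 64)), "too small")
})

test_that("template intensities sit on the three tissue tiers", {
  tpl <- small_template()
  v <- tpl$volume[tpl$mask]
  # every masked voxel is within texture range of a tier
  d <- pmin(abs(v - 0.2), abs(v - 0.5), abs(v - 0.8))
  expect_lte(max(d), 0.05)
})

test_that("cohort generation is deterministic and bookkeeping is exact", {
  cfg <- phantom_config(c(20L, 18L, 16L), n_per_class = 3L, effect_size = 0.4,
                        affected_boxes = data.frame(x0 = 3L, y0 = 5L, z0 = 5L,
                                                    l1 = 4L, l2 = 4L, l3 = 4L),
                        seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$volumes, b$volumes)
  expect_length(a$volumes, 6L)
  expect_identical(as.character(table(a$labels)), c("3", "3"))
  expect_identical(a$truth, cfg$affected_boxes)
})

test_that("degenerate configs reproduce the template or fail loudly", {
  tpl <- small_template()
  cfg0 <- phantom_config(SMALL_SHAPE, n_per_class = 1L, effect_size = 0,
                         noise_sd = 0, bias_scale = 0, seed = 5)
  set.seed(1)
  expect_identical(generate_subject(tpl, "control", cfg0), tpl$volume)
  # disease with zero effect is also the identity
  set.seed(1)
  expect_identical(generate_subject(tpl, "disease", cfg0), tpl$volume)
  # a box with no mask support is rejected
  bad <- phantom_config(SMALL_SHAPE, n_per_class = 1L,
                        affected_boxes = data.frame(x0 = 1L, y0 = 1L, z0 = 1L,
                                                    l1 = 2L, l2 = 2L, l3 = 2L),
                        seed = 5)
  expect_error(generate_cohort(bad), "mask support")
  expect_error(phantom_config(effect_size = 1.2), "effect_size")
  expect_error(phantom_config(affected_boxes = data.frame(
    x0 = 60L, y0 = 1L, z0 = 1L, l1 = 10L, l2 = 2L, l3 = 2L)), "within shape")
})

box_means <- function(cohort, boxes) {
  vapply(cohort$volumes, function(v) {
    mean(vapply(seq_len(nrow(boxes)), function(i) {
      b <- boxes[i, ]
      mean(v[b$x0:(b$x0 + b$l1 - 1L), b$y0:(b$y0 + b$l2 - 1L),
             b$z0:(b$z0 + b$l3 - 1L)])
    }, numeric(1)))
  }, numeric(1))
}

test_that("atrophy lowers affected-box intensity, monotonically in effect size", {
  boxes <- small_boxes(2L)
  gaps <- vapply(c(0, 0.25, 0.5, 1), function(es) {
    co <- generate_cohort(phantom_config(SMALL_SHAPE, n_per_class = 30L,
                                         effect_size = es,
                                         affected_boxes = boxes, seed = 99))
    m <- box_means(co, boxes)
    mean(m[co$labels == "control"]) - mean(m[co$labels == "disease"])
  }, numeric(1))
  expect_lt(abs(gaps[1L]), 0.01)          # zero effect: no class difference
  expect_true(all(diff(gaps) > 0))        # gap grows with effect size
  # two-sample oracle at effect 0.5, 50 per class
  co <- generate_cohort(phantom_config(SMALL_SHAPE, n_per_class = 50L,
                                       effect_size = 0.5,
                                       affected_boxes = boxes, seed = 7))
  m <- box_means(co, boxes)
  tt <- t.test(m[co$labels == "disease"], m[co$labels == "control"],
               alternative = "less")
  expect_lt(tt$p.value, 1e-6)
})

test_that("no signal leaks outside the affected boxes", {
  boxes <- small_boxes(1L)
  co <- generate_cohort(phantom_config(SMALL_SHAPE, n_per_class = 30L,
                                       effect_size = 1,
                                       affected_boxes = boxes, seed = 13))
  ctrl <- Reduce(`+`, co$volumes[co$labels == "control"]) / 30
  dis <- Reduce(`+`, co$volumes[co$labels == "disease"]) / 30
  diffmap <- abs(ctrl - dis)
  inside <- array(FALSE, dim = SMALL_SHAPE)
  b <- boxes[1L, ]
  inside[b$x0:(b$x0 + b$l1 - 1L), b$y0:(b$y0 + b$l2 - 1L),
         b$z0:(b$z0 + b$l3 - 1L)] <- TRUE
  expect_gt(mean(diffmap[inside & co$mask]), 10 * mean(diffmap[!inside & co$mask]))
})

test_that("a cohort round-trips through the on-disk layout", {
  co <- generate_cohort(phantom_config(c(20L, 18L, 16L), n_per_class = 2L,
                                       effect_size = 0, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("mask.nii.gz", "atlas.nii.gz", "atlas_labels.tsv", "manifest.tsv",
      "phantom_config.txt")))))
  man <- read.delim(file.path(dir, "manifest.tsv"))
  expect_identical(nrow(man), 4L)
  v <- RNifti::readNifti(file.path(dir, man$file[1L]))
  expect_equal(array(as.numeric(v), dim = dim(v)), co$volumes[[1L]],
               tolerance = 1e-6)
})
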