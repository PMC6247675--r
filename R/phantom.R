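#' Phantom cohort configuration
#'
#' Parameters of the synthetic atrophy phantom. The phantom emulates the
#' intensity mechanism of gray-matter atrophy: inside designated boxes a
#' fraction of gray-matter-tier voxels is replaced by the CSF tier
#' intensity, so atrophy reads as CSF expanding at the expense of gray
#' matter. It does not model geometric deformation, scanner effects or
#' registration error.
#'
#' @param shape Image extents (voxels), each at least 16.
#' @param n_per_class Subjects per class (control / disease).
#' @param effect_size Fraction in \[0, 1\] of gray-matter-tier voxels shifted
#'   to the CSF intensity inside each affected box.
#' @param noise_sd Standard deviation of additive Gaussian noise, in the
#'   same arbitrary intensity units as the tissue tiers (CSF 0.2, GM 0.5,
#'   WM 0.8).
#' @param bias_scale Amplitude of the smooth multiplicative bias field
#'   (separable low-order cosine surface; 0 disables it).
#' @param affected_boxes Data frame with columns `x0`, `y0`, `z0`, `l1`,
#'   `l2`, `l3` (1-based origins) of the lesioned boxes, or `NULL` for a
#'   lesion-free configuration.
#' @param seed Integer master seed; the same seed yields a bit-identical
#'   cohort.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64L, 72L, 60L), n_per_class = 30L,
                           effect_size = 0.6, noise_sd = 0.05,
                           bias_scale = 0.05, affected_boxes = NULL,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape must have 3 extents, each at least 16")
  if (effect_size < 0 || effect_size > 1) stop("effect_size must be in [0, 1]")
  if (noise_sd < 0 || bias_scale < 0) stop("noise_sd and bias_scale must be >= 0")
  if (n_per_class < 1L) stop("n_per_class must be at least 1")
  if (!is.null(affected_boxes)) {
    need <- c("x0", "y0", "z0", "l1", "l2", "l3")
    if (!all(need %in% names(affected_boxes)))
      stop("affected_boxes needs columns x0, y0, z0, l1, l2, l3")
    hi <- with(affected_boxes, cbind(x0 + l1, y0 + l2, z0 + l3) - 1L)
    lo <- with(affected_boxes, cbind(x0, y0, z0))
    if (any(lo < 1L) || any(t(hi) > shape))
      stop("affected_boxes must lie within shape")
  }
  structure(list(shape = shape, n_per_class = as.integer(n_per_class),
                 effect_size = effect_size, noise_sd = noise_sd,
                 bias_scale = bias_scale, affected_boxes = affected_boxes,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Tissue tiers in arbitrary units; only their relative order matters for
# correlation-based layers (Pearson is scale invariant).
PHANTOM_TIERS <- c(csf = 0.2, gm = 0.5, wm = 0.8)
GM_BAND <- 0.1  # half-width of the pre-noise intensity band that defines GM

#' Generate the phantom template
#'
#' Nested-ellipsoid tissue model: an outer ellipsoid (the brain mask) with a
#' CSF rim, a gray-matter shell, a white-matter core and a central
#' CSF-filled ventricle, plus a faint smooth seed-derived texture. The
#' template is mirror symmetric about the midsagittal plane. The atlas
#' partitions the mask into 8 contiguous octant regions around the
#' ellipsoid center.
#'
#' @param shape Integer vector of 3 extents, each at least 16.
#' @param seed Integer seed for the texture phases.
#' @return A list with `volume` (3D array), `mask` (logical 3D array),
#'   `atlas` (integer 3D array, 0 = background) and `atlas_names` (data
#'   frame `label`, `name`).
#' @export
generate_template <- function(shape = c(64L, 72L, 60L), seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("shape too small to contain the ellipsoid model (need >= 16 per axis)")
  ctr <- (shape + 1) / 2          # symmetric about x -> shape[1] + 1 - x
  semi <- 0.45 * shape
  x <- (seq_len(shape[1L]) - ctr[1L]) / semi[1L]
  y <- (seq_len(shape[2L]) - ctr[2L]) / semi[2L]
  z <- (seq_len(shape[3L]) - ctr[3L]) / semi[3L]
  rho2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  rho <- sqrt(rho2)
  mask <- rho <= 1
  vol <- array(0, dim = shape)
  vol[mask] <- PHANTOM_TIERS[["gm"]]
  vol[mask & rho > 0.88] <- PHANTOM_TIERS[["csf"]]        # sulcal/peripheral CSF rim
  vol[mask & rho <= 0.62] <- PHANTOM_TIERS[["wm"]]        # white-matter core
  vol[mask & rho <= 0.16] <- PHANTOM_TIERS[["csf"]]       # ventricle
  # faint smooth texture, even in x so mirror symmetry is preserved
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  ph <- stats::runif(2L, 0, 2 * pi)
  tex <- outer(outer(cos(pi * abs(x) * 2),
                     cos(2 * pi * (y + 1) / 2 * 2 + ph[1L]), "*"),
               cos(2 * pi * (z + 1) / 2 * 2 + ph[2L]), "*")
  vol[mask] <- vol[mask] + 0.03 * tex[mask]

  atlas <- array(0L, dim = shape)
  oct <- 1L + (outer(outer(as.integer(x > 0) * 4L, as.integer(y > 0) * 2L, "+"),
                     as.integer(z > 0), "+"))
  atlas[mask] <- oct[mask]
  atlas_names <- data.frame(
    label = 1:8,
    name = c("left_posterior_inferior", "left_posterior_superior",
             "left_anterior_inferior", "left_anterior_superior",
             "right_posterior_inferior", "right_posterior_superior",
             "right_anterior_inferior", "right_anterior_superior"),
    stringsAsFactors = FALSE)
  list(volume = vol, mask = mask, atlas = atlas, atlas_names = atlas_names)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# index vector of GM-tier voxels (pre-noise band around the GM tier) of the
# template inside one box
gm_tier_voxels <- function(template_volume, box) {
  xs <- box$x0:(box$x0 + box$l1 - 1L)
  ys <- box$y0:(box$y0 + box$l2 - 1L)
  zs <- box$z0:(box$z0 + box$l3 - 1L)
  idx <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  v <- template_volume[idx]
  idx[abs(v - PHANTOM_TIERS[["gm"]]) <= GM_BAND, , drop = FALSE]
}

#' Generate one phantom subject
#'
#' Applies, in order: class-specific lesioning (for the disease class, an
#' `effect_size` fraction of the gray-matter-tier voxels inside each
#' affected box is set to the CSF tier intensity; the lesioned voxels are
#' drawn at random per subject), a smooth multiplicative bias field with
#' subject-specific phases, and additive Gaussian noise. Gray-matter-tier
#' membership is decided on the noise-free template so the lesion model is
#' independent of the noise draw.
#'
#' @param template Output of [generate_template()].
#' @param class_label `"control"` or `"disease"`.
#' @param config A [phantom_config()].
#' @return 3D numeric array; consumes the current RNG stream.
#' @export
generate_subject <- function(template, class_label = c("control", "disease"),
                             config) {
  class_label <- match.arg(class_label)
  stopifnot(inherits(config, "phantom_config"))
  vol <- template$volume
  if (class_label == "disease" && config$effect_size > 0 &&
      !is.null(config$affected_boxes)) {
    for (i in seq_len(nrow(config$affected_boxes))) {
      gm <- gm_tier_voxels(template$volume, config$affected_boxes[i, ])
      n_hit <- floor(config$effect_size * nrow(gm))
      if (n_hit > 0L) {
        pick <- if (n_hit == nrow(gm)) seq_len(nrow(gm)) else
          sample.int(nrow(gm), n_hit)
        vol[gm[pick, , drop = FALSE]] <- PHANTOM_TIERS[["csf"]]
      }
    }
  }
  if (config$bias_scale > 0) {
    sh <- config$shape
    ph <- stats::runif(3L, 0, 2 * pi)
    bx <- cos(2 * pi * seq_len(sh[1L]) / sh[1L] + ph[1L])
    by <- cos(2 * pi * seq_len(sh[2L]) / sh[2L] + ph[2L])
    bz <- cos(2 * pi * seq_len(sh[3L]) / sh[3L] + ph[3L])
    bias <- 1 + config$bias_scale * outer(outer(bx, by, "*"), bz, "*")
    vol <- vol * bias
  }
  if (config$noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(config$shape), 0, config$noise_sd),
                       dim = config$shape)
  vol
}

#' Generate a phantom cohort
#'
#' Produces `n_per_class` control and `n_per_class` disease volumes from
#' one template, fully reproducible from the config seed.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_cohort`: a list with `volumes`
#'   (list of 3D arrays), `labels` (factor control/disease), `subject_ids`,
#'   `mask`, `atlas`, `atlas_names`, `truth` (the affected boxes) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  template <- generate_template(config$shape, config$seed)
  if (!is.null(config$affected_boxes)) {
    for (i in seq_len(nrow(config$affected_boxes))) {
      b <- config$affected_boxes[i, ]
      xs <- b$x0:(b$x0 + b$l1 - 1L); ys <- b$y0:(b$y0 + b$l2 - 1L)
      zs <- b$z0:(b$z0 + b$l3 - 1L)
      if (!any(template$mask[xs, ys, zs]))
        stop("affected box ", i, " lies outside the mask support")
    }
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  labels <- factor(rep(c("control", "disease"), each = config$n_per_class),
                   levels = c("control", "disease"))
  volumes <- lapply(as.character(labels), function(cl)
    generate_subject(template, cl, config))
  ids <- sprintf("%s%03d", ifelse(labels == "control", "C", "D"),
                 c(seq_len(config$n_per_class), seq_len(config$n_per_class)))
  structure(list(volumes = volumes, labels = labels, subject_ids = ids,
                 mask = template$mask, atlas = template$atlas,
                 atlas_names = template$atlas_names,
                 truth = config$affected_boxes, config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("phantom_cohort: %d subjects (%s), shape %s, %d affected boxes\n",
              length(x$volumes), paste(table(x$labels), collapse = " + "),
              paste(x$config$shape, collapse = "x"),
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

#' Pick lesion target boxes from a grid
#'
#' Deterministically selects retained grid boxes with the highest
#' gray-matter-tier content of the template, optionally restricted to one
#' hemisphere. Useful for placing phantom lesions on patch boundaries so
#' the injected truth aligns with network nodes.
#'
#' @param grid A `patch_grid` built on the template mask.
#' @param template Output of [generate_template()].
#' @param n Number of boxes.
#' @param hemisphere `"L"`, `"R"` or `"both"`.
#' @return Data frame of `n` boxes (`node_id`, `x0`, `y0`, `z0`, `l1`,
#'   `l2`, `l3`, `gm_fraction`).
#' @export
pick_affected_boxes <- function(grid, template, n = 5L,
                                hemisphere = c("L", "R", "both")) {
  hemisphere <- match.arg(hemisphere)
  rb <- retained_boxes(grid)
  if (hemisphere != "both") rb <- rb[rb$hemisphere == hemisphere, , drop = FALSE]
  gm <- vapply(seq_len(nrow(rb)), function(i)
    nrow(gm_tier_voxels(template$volume, rb[i, ])) / attr(grid, "spec")$D,
    numeric(1))
  rb$gm_fraction <- gm
  rb <- rb[order(-rb$gm_fraction, rb$node_id), , drop = FALSE]
  if (nrow(rb) < n) stop("not enough retained boxes to pick from")
  out <- rb[seq_len(n), c("node_id", "x0", "y0", "z0", "l1", "l2", "l3", "gm_fraction")]
  rownames(out) <- NULL
  out
}

#' Write a phantom cohort to disk
#'
#' Volumes, mask and atlas as NIfTI-1; a cohort manifest (subject id, class,
#' seed, truth boxes) as TSV; the config as a flat key-value text file.
#'
#' @param cohort A `phantom_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$volumes))
    RNifti::writeNifti(cohort$volumes[[i]],
                       file.path(dir, paste0(cohort$subject_ids[i], ".nii.gz")))
  RNifti::writeNifti(array(as.numeric(cohort$mask), dim = dim(cohort$mask)),
                     file.path(dir, "mask.nii.gz"))
  RNifti::writeNifti(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  utils::write.table(cohort$atlas_names, file.path(dir, "atlas_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(subject_id = cohort$subject_ids,
                         class = as.character(cohort$labels),
                         file = paste0(cohort$subject_ids, ".nii.gz"),
                         seed = cohort$config$seed)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.table(cohort$truth, file.path(dir, "truth_boxes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  keys <- c(shape = paste(cfg$shape, collapse = "x"),
            n_per_class = cfg$n_per_class, effect_size = cfg$effect_size,
            noise_sd = cfg$noise_sd, bias_scale = cfg$bias_scale,
            seed = cfg$seed)
  writeLines(paste0(names(keys), " = ", unname(keys)),
             file.path(dir, "phantom_config.txt"))
  invisible(dir)
}
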