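#' Pipeline run configuration
#'
#' Flat key-value configuration binding every stage. Defaults are the
#' method's reference values: 10 x 15 x 20 patches at 10% mask overlap,
#' correlation threshold 0.3, 1000 selection rounds of 5-fold CV with
#' 500-tree forests, alpha 0.01, 100 bootstrap replicates.
#'
#' @param input `"phantom"` (generate the synthetic cohort) or a directory
#'   holding a `manifest.tsv` (subject_id, class, file), `mask.nii.gz`,
#'   and optionally `atlas.nii.gz` + `atlas_labels.tsv`.
#' @param out_dir Output directory for stage artifacts.
#' @param l1,l2,l3 Patch edge lengths (voxels).
#' @param min_overlap Mask-overlap retention threshold.
#' @param threshold Correlation threshold tau.
#' @param use_abs_weights Edge-weight mode.
#' @param n_rounds,k_folds,n_trees,alpha Selection parameters.
#' @param n_boot Bootstrap replicates for test metrics.
#' @param test_fraction Fraction of subjects held out for testing.
#' @param seed Master seed.
#' @param phantom_shape,phantom_n_per_class,phantom_effect_size,
#'   phantom_noise_sd,phantom_bias_scale,phantom_n_affected Phantom
#'   parameters (used when `input = "phantom"`).
#' @return An object of class `run_config` (a flat named list).
#' @export
run_config <- function(input = "phantom", out_dir = tempfile("mplexrun"),
                       l1 = 10L, l2 = 15L, l3 = 20L, min_overlap = 0.10,
                       threshold = 0.3, use_abs_weights = TRUE,
                       n_rounds = 1000L, k_folds = 5L, n_trees = 500L,
                       alpha = 0.01, n_boot = 100L, test_fraction = 0.25,
                       seed = 1L,
                       phantom_shape = c(64L, 72L, 60L),
                       phantom_n_per_class = 30L,
                       phantom_effect_size = 0.6,
                       phantom_noise_sd = 0.05,
                       phantom_bias_scale = 0.05,
                       phantom_n_affected = 5L) {
  cfg <- list(input = input, out_dir = out_dir,
              l1 = as.integer(l1), l2 = as.integer(l2), l3 = as.integer(l3),
              min_overlap = min_overlap, threshold = threshold,
              use_abs_weights = isTRUE(use_abs_weights),
              n_rounds = as.integer(n_rounds), k_folds = as.integer(k_folds),
              n_trees = as.integer(n_trees), alpha = alpha,
              n_boot = as.integer(n_boot), test_fraction = test_fraction,
              seed = as.integer(seed),
              phantom_shape = as.integer(phantom_shape),
              phantom_n_per_class = as.integer(phantom_n_per_class),
              phantom_effect_size = phantom_effect_size,
              phantom_noise_sd = phantom_noise_sd,
              phantom_bias_scale = phantom_bias_scale,
              phantom_n_affected = as.integer(phantom_n_affected))
  structure(cfg, class = "run_config")
}

#' Hash of a run configuration
#'
#' MD5 of the canonical (key-sorted) serialization, stable under key
#' reordering. The output directory is excluded: the hash identifies the
#' scientific parameters of a run, not where its artifacts land.
#'
#' @param config A `run_config` (or any flat list).
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(vapply(names(cfg), function(k)
    paste0(k, "=", paste(format(cfg[[k]], digits = 15), collapse = ",")),
    character(1)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write / read a run configuration as flat key-value text
#' @param config A `run_config`.
#' @param path File path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  writeLines(vapply(names(cfg), function(k)
    paste0(k, " = ", paste(cfg[[k]], collapse = ",")), character(1)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(x)
    strsplit(x[2L], ",", fixed = TRUE)[[1L]]), vapply(kv, `[[`, "", 1L))
  base <- run_config()
  for (k in names(vals)) {
    if (!k %in% names(base)) next
    proto <- base[[k]]
    base[[k]] <- if (is.logical(proto)) as.logical(vals[[k]])
      else if (is.integer(proto)) as.integer(vals[[k]])
      else if (is.numeric(proto)) as.numeric(vals[[k]])
      else vals[[k]]
  }
  base
}

#' Validate pipeline inputs
#'
#' Checks that all volumes share one grid shape, that mask and atlas align
#' with it, and that every nonzero atlas label has a name. Violations are
#' reported, not thrown.
#'
#' @param volume_paths Character vector of NIfTI volume paths.
#' @param mask_path Path to the mask NIfTI (optional).
#' @param atlas_path Path to the atlas NIfTI (optional).
#' @param atlas_labels_path Path to the label TSV (optional; columns
#'   `label`, `name`).
#' @return Data frame with `check` and `message` (zero rows when all
#'   consistent).
#' @export
validate_inputs <- function(volume_paths, mask_path = NULL, atlas_path = NULL,
                            atlas_labels_path = NULL) {
  bad <- list()
  note <- function(check, msg)
    bad[[length(bad) + 1L]] <<- data.frame(check = check, message = msg)
  shapes <- lapply(volume_paths, function(p) {
    if (!file.exists(p)) { note("volume_exists", paste(p, "missing")); return(NULL) }
    dim(RNifti::readNifti(p))
  })
  shapes <- Filter(Negate(is.null), shapes)
  if (length(shapes) > 1L) {
    ref <- shapes[[1L]]
    for (i in seq_along(shapes)[-1L])
      if (!identical(shapes[[i]], ref))
        note("shared_grid", paste0(volume_paths[i], " shape ",
                                   paste(shapes[[i]], collapse = "x"),
                                   " != ", paste(ref, collapse = "x")))
  }
  ref <- if (length(shapes)) shapes[[1L]] else NULL
  atlas <- NULL
  for (nm in c("mask", "atlas")) {
    p <- if (nm == "mask") mask_path else atlas_path
    if (is.null(p)) next
    if (!file.exists(p)) { note(paste0(nm, "_exists"), paste(p, "missing")); next }
    v <- RNifti::readNifti(p)
    if (nm == "atlas") atlas <- v
    if (!is.null(ref) && !identical(dim(v), ref))
      note(paste0(nm, "_aligned"), paste0(nm, " shape ",
                                          paste(dim(v), collapse = "x"),
                                          " != ", paste(ref, collapse = "x")))
  }
  if (!is.null(atlas_labels_path) && !is.null(atlas)) {
    if (!file.exists(atlas_labels_path)) {
      note("labels_exist", paste(atlas_labels_path, "missing"))
    } else {
      tab <- utils::read.delim(atlas_labels_path)
      labs <- setdiff(unique(as.integer(atlas)), 0L)
      unnamed <- setdiff(labs, tab$label)
      if (length(unnamed))
        note("labels_complete", paste("atlas labels without a name:",
                                      paste(unnamed, collapse = ", ")))
    }
  }
  if (length(bad) == 0L)
    return(data.frame(check = character(0), message = character(0)))
  do.call(rbind, bad)
}

read_input_cohort <- function(dir) {
  man <- utils::read.delim(file.path(dir, "manifest.tsv"))
  vols <- lapply(file.path(dir, man$file), function(p)
    array(as.numeric(RNifti::readNifti(p)), dim = dim(RNifti::readNifti(p))))
  mask <- RNifti::readNifti(file.path(dir, "mask.nii.gz")) != 0
  atlas <- NULL; atlas_names <- NULL
  ap <- file.path(dir, "atlas.nii.gz")
  if (file.exists(ap)) {
    atlas <- array(as.integer(RNifti::readNifti(ap)), dim = dim(mask))
    lp <- file.path(dir, "atlas_labels.tsv")
    if (file.exists(lp)) atlas_names <- utils::read.delim(lp)
  }
  list(volumes = vols, labels = factor(man$class), subject_ids = man$subject_id,
       mask = mask, atlas = atlas, atlas_names = atlas_names, truth = NULL)
}

#' Run the full pipeline
#'
#' Orchestrates parcellation, layer construction, multiplex features,
#' selection, final training, held-out evaluation and (when an atlas is
#' available) the anatomical region report, writing every stage artifact
#' under `config$out_dir` plus a run manifest with the config hash, seeds
#' and per-stage counts. Stage failures abort with the failing stage
#' named; artifacts already written are preserved.
#'
#' @param config A [run_config()].
#' @return The run manifest (a list), invisibly; written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    out
  }

  spec <- patch_spec(config$l1, config$l2, config$l3)
  data <- stage("input", {
    if (identical(config$input, "phantom")) {
      tpl <- generate_template(config$phantom_shape, config$seed)
      grid0 <- build_patch_grid(config$phantom_shape, spec, tpl$mask,
                                config$min_overlap)
      boxes <- if (config$phantom_n_affected > 0L)
        pick_affected_boxes(grid0, tpl, config$phantom_n_affected, "L") else NULL
      pcfg <- phantom_config(config$phantom_shape, config$phantom_n_per_class,
                             config$phantom_effect_size, config$phantom_noise_sd,
                             config$phantom_bias_scale, boxes, config$seed)
      co <- generate_cohort(pcfg)
      co[c("volumes", "labels", "subject_ids", "mask", "atlas", "atlas_names",
           "truth")]
    } else read_input_cohort(config$input)
  })

  grid <- stage("parcellation", {
    g <- build_patch_grid(dim(data$volumes[[1L]]), spec, data$mask,
                          config$min_overlap)
    write_patch_grid(g, file.path(config$out_dir, "patch_grid.tsv"))
    g
  })

  cc <- correlation_config(config$threshold,
                           use_abs_weights = config$use_abs_weights)
  layers <- stage("layers", {
    lapply(seq_along(data$volumes), function(i)
      build_layer(data$volumes[[i]], grid, cc,
                  subject_id = as.character(data$subject_ids[i])))
  })

  split <- stage("split", {
    old <- get_rng_state()
    set.seed(config$seed)
    te <- unlist(lapply(split(seq_along(layers), data$labels), function(idx)
      sample(idx, max(1L, round(config$test_fraction * length(idx))))))
    restore_rng_state(old)
    list(train = setdiff(seq_along(layers), te), test = sort(te))
  })

  scfg <- selection_config(config$n_rounds, config$k_folds, config$n_trees,
                           alpha = config$alpha, seed = config$seed)
  sel <- stage("selection", {
    s <- select_features(layers[split$train], data$labels[split$train], scfg)
    write_selection_result(s, file.path(config$out_dir, "selection.tsv"))
    s
  })

  mux <- multiplex(layers[split$train])
  feats <- stage("features", {
    f <- feature_matrix(mux)
    write_feature_matrix(f, file.path(config$out_dir, "features_train.tsv"),
                         data$labels[split$train])
    f
  })

  model <- stage("train", {
    train_final(feats, data$labels[split$train], selected_features(sel),
                scfg, seed = config$seed)
  })

  report <- stage("evaluate", {
    r <- evaluate_test(model, mux, layers[split$test], data$labels[split$test],
                       config$n_boot, seed = config$seed)
    jsonlite::write_json(r[c("accuracy", "sensitivity", "specificity",
                             "accuracy_se", "sensitivity_se", "specificity_se",
                             "n_boot")],
                         file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    r
  })

  regions <- NULL
  if (!is.null(data$atlas)) {
    regions <- stage("anatomy", {
      rr <- region_report(sel, mux, grid, data$atlas, data$atlas_names)
      write_region_report(rr, file.path(config$out_dir, "region_report.tsv"))
      rr
    })
  }

  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   n_subjects = length(layers), n_train = length(split$train),
                   n_test = length(split$test), N = n_nodes(grid),
                   f = 8L * n_nodes(grid),
                   n_selected = sum(sel$selected),
                   cv_accuracy = attr(sel, "accuracy"),
                   test_accuracy = report$accuracy,
                   n_regions = if (is.null(regions)) NA else nrow(regions),
                   timings = timings,
                   total_seconds = as.numeric(difftime(Sys.time(), t0,
                                                       units = "secs")))
  write_run_config(config, file.path(config$out_dir, "run_config.txt"))
  # manifest written atomically at run end
  tmp <- file.path(config$out_dir, ".manifest.json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
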