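#' Classification metrics
#'
#' Accuracy, sensitivity (true-positive rate on the positive class, by
#' default the disease class) and specificity (true-negative rate on the
#' other class). With no positive (resp. negative) case in `truth`,
#' sensitivity (resp. specificity) is `NA`, not 0.
#'
#' @param pred,truth Factors or characters of equal length.
#' @param positive Name of the positive class (default `"disease"`).
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(pred, truth, positive = "disease") {
  pred <- as.character(pred); truth <- as.character(truth)
  pos <- truth == positive
  c(accuracy = mean(pred == truth),
    sensitivity = if (any(pos)) mean(pred[pos] == truth[pos]) else NA_real_,
    specificity = if (any(!pos)) mean(pred[!pos] == truth[!pos]) else NA_real_)
}

#' Train the final classifier on the selected features
#'
#' @param features Training feature matrix (`M x 8N`).
#' @param labels Class labels aligned to rows.
#' @param selected Character vector of selected feature names (nonempty).
#' @param config A [selection_config()] supplying `n_trees` and `mtry`.
#' @param seed Integer seed.
#' @return An object of class `mplex_model`: list with the ranger forest,
#'   the feature list, class levels and config.
#' @export
train_final <- function(features, labels, selected,
                        config = selection_config(), seed = config$seed) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (length(selected) == 0L)
    stop("empty selection; relax alpha or increase n_rounds")
  if (!all(selected %in% colnames(features)))
    stop("selected features missing from the feature matrix")
  rf <- ranger::ranger(x = features[, selected, drop = FALSE], y = labels,
                       num.trees = config$n_trees,
                       mtry = mtry_value(config, length(selected)),
                       num.threads = 1L, seed = seed)
  structure(list(forest = rf, features = selected, levels = levels(labels),
                 config = config),
            class = "mplex_model")
}

#' @export
print.mplex_model <- function(x, ...) {
  cat(sprintf("mplex_model: %d-tree forest on %d selected features (classes: %s)\n",
              x$config$n_trees, length(x$features), paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Predict classes from feature rows
#' @param object An `mplex_model`.
#' @param newdata Matrix with (at least) the model's feature columns.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.mplex_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, names(newdata)))
  if (!all(object$features %in% colnames(newdata)))
    stop("newdata lacks the model's feature columns")
  stats::predict(object$forest, data = newdata[, object$features, drop = FALSE],
                 num.threads = 1L)$predictions
}

#' Evaluate a model on held-out subjects with bootstrap uncertainty
#'
#' Each test subject's feature row is computed by adding its layer to the
#' training multiplex (training features fixed). Metrics are averaged over
#' `n_boot` bootstrap resamples of the test set; standard errors are the
#' bootstrap standard deviations.
#'
#' @param model An `mplex_model`.
#' @param train_mux The training `multiplex`.
#' @param test_layers List of held-out `layer_network`s on the training
#'   grid.
#' @param test_labels Labels aligned to `test_layers`.
#' @param n_boot Bootstrap replicates (default 100).
#' @param seed Integer seed for the resampling.
#' @param positive Positive class name (default `"disease"`).
#' @return An object of class `metrics_report`: list with `accuracy`,
#'   `sensitivity`, `specificity`, their `*_se`, `n_boot`, and the
#'   per-subject `predictions`.
#' @export
evaluate_test <- function(model, train_mux, test_layers, test_labels,
                          n_boot = 100L, seed = 1L, positive = "disease") {
  stopifnot(inherits(model, "mplex_model"), inherits(train_mux, "multiplex"))
  rows <- t(vapply(test_layers,
                   function(l) append_test_layer_features(train_mux, l),
                   numeric(8L * train_mux$N)))
  pred <- predict(model, rows)
  truth <- as.character(test_labels)
  point <- classification_metrics(pred, truth, positive)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  boot <- t(vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(truth), replace = TRUE)
    classification_metrics(pred[i], truth[i], positive)
  }, numeric(3)))
  se <- apply(boot, 2L, stats::sd, na.rm = TRUE)
  mn <- colMeans(boot, na.rm = TRUE)
  structure(list(accuracy = mn[["accuracy"]], sensitivity = mn[["sensitivity"]],
                 specificity = mn[["specificity"]],
                 accuracy_se = se[["accuracy"]], sensitivity_se = se[["sensitivity"]],
                 specificity_se = se[["specificity"]],
                 point = point, n_boot = n_boot, predictions = pred),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f +- %.3f | sensitivity %.3f +- %.3f | specificity %.3f +- %.3f (n_boot = %d)\n",
              x$accuracy, x$accuracy_se, x$sensitivity, x$sensitivity_se,
              x$specificity, x$specificity_se, x$n_boot))
  invisible(x)
}

#' Label-permutation test of the training pipeline
#'
#' Permutes the class labels before selection and training in each
#' replicate and records the cross-validated accuracy, yielding the null
#' accuracy distribution against which the unpermuted accuracy is scored
#' (empirical tail and, given the usually normal shape of the null, a
#' normal-fit tail).
#'
#' @param layers Training `layer_network`s.
#' @param labels True labels.
#' @param config A [selection_config()] (use few rounds for desk runs).
#' @param n_perm Number of permutations (reference default 1000).
#' @param seed Integer seed.
#' @param observed Optional precomputed unpermuted accuracy; computed if
#'   `NULL`.
#' @return List with `accuracies` (length `n_perm`), `observed`,
#'   `p_empirical`, `p_normal`.
#' @export
label_permutation_test <- function(layers, labels, config = selection_config(),
                                   n_perm = 1000L, seed = 1L, observed = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  labels <- factor(labels)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  if (is.null(observed))
    observed <- attr(select_features(layers, labels, config), "accuracy")
  accs <- vapply(seq_len(n_perm), function(p) {
    set.seed(seed + 131L * p)
    perm <- sample(labels)
    cfg <- config; cfg$seed <- (config$seed + 977L * p) %% .Machine$integer.max
    attr(select_features(layers, perm, cfg), "accuracy")
  }, numeric(1))
  p_emp <- (1 + sum(accs >= observed)) / (n_perm + 1)
  p_norm <- stats::pnorm(observed, mean(accs), stats::sd(accs),
                         lower.tail = FALSE)
  list(accuracies = accs, observed = observed, p_empirical = p_emp,
       p_normal = p_norm)
}

# permute `n_shuffled` voxel positions within each patch column,
# independently per patch (and caller loops per subject)
shuffle_patch_matrix <- function(P, n_shuffled) {
  D <- nrow(P)
  if (n_shuffled > D) stop("cannot shuffle more voxels than the patch holds")
  if (n_shuffled < 2L) return(P)
  for (j in seq_len(ncol(P))) {
    pos <- sample.int(D, n_shuffled)
    P[pos, j] <- P[sample(pos), j]
  }
  P
}

#' Voxel-shuffle robustness experiment
#'
#' Destroys voxel correspondence by permuting a growing number of voxel
#' positions within each patch (independently per patch and per subject,
#' fresh permutation per replicate) before the correlations are computed,
#' while keeping the patch decomposition fixed; records the cross-validated
#' accuracy at each shuffle level.
#'
#' @param patch_mats List of `D x N` patch matrices, one per subject.
#' @param labels Class labels.
#' @param levels Integer vector of shuffle sizes (0 .. D).
#' @param cor_config A [correlation_config()].
#' @param sel_config A [selection_config()].
#' @param n_reps Replicates per level.
#' @param seed Integer seed.
#' @return Data frame with `n_shuffled`, `rep`, `accuracy`.
#' @export
voxel_shuffle_experiment <- function(patch_mats, labels, levels,
                                     cor_config = correlation_config(),
                                     sel_config = selection_config(),
                                     n_reps = 1L, seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  out <- expand.grid(n_shuffled = as.integer(levels), rep = seq_len(n_reps),
                     KEEP.OUT.ATTRS = FALSE)
  out$accuracy <- NA_real_
  for (i in seq_len(nrow(out))) {
    set.seed(seed + 613L * i)
    mats <- lapply(patch_mats, shuffle_patch_matrix, n_shuffled = out$n_shuffled[i])
    layers <- lapply(seq_along(mats), function(s)
      build_layer(mats[[s]], config = cor_config,
                  subject_id = sprintf("S%03d", s)))
    cfg <- sel_config
    cfg$seed <- (sel_config$seed + 389L * i) %% .Machine$integer.max
    out$accuracy[i] <- attr(select_features(layers, labels, cfg), "accuracy")
  }
  out
}

#' Correlation-threshold sweep
#'
#' Rebuilds every subject's layer at each threshold (the pairwise
#' correlations are computed once), reporting the fraction of empty
#' networks and, optionally, the cross-validated accuracy of the selection
#' wrapper at each threshold.
#'
#' @param patch_mats List of `D x N` patch matrices.
#' @param labels Class labels.
#' @param taus Thresholds (default `seq(0, 0.8, 0.1)`).
#' @param sel_config A [selection_config()].
#' @param use_abs_weights Weight mode passed to the layers.
#' @param classify Run the selection wrapper per threshold (set `FALSE`
#'   to sweep only the network-emptiness profile).
#' @return Data frame with `tau`, `empty_fraction`, `accuracy`.
#' @export
threshold_sweep <- function(patch_mats, labels, taus = seq(0, 0.8, by = 0.1),
                            sel_config = selection_config(),
                            use_abs_weights = TRUE, classify = TRUE) {
  Rs <- lapply(patch_mats, function(P) {
    R <- suppressWarnings(stats::cor(P))
    R[!is.finite(R)] <- 0
    R
  })
  out <- data.frame(tau = taus, empty_fraction = NA_real_, accuracy = NA_real_)
  for (i in seq_along(taus)) {
    cfg <- correlation_config(threshold = taus[i],
                              use_abs_weights = use_abs_weights)
    layers <- lapply(seq_along(Rs), function(s) {
      W <- threshold_weight(Rs[[s]], taus[i], use_abs_weights)
      diag(W) <- 0
      structure(list(W = W, subject_id = sprintf("S%03d", s), N = ncol(W),
                     config = cfg),
                class = "layer_network")
    })
    out$empty_fraction[i] <- mean(vapply(layers, is_empty_layer, logical(1)))
    if (classify) {
      scfg <- sel_config
      scfg$seed <- (sel_config$seed + 211L * i) %% .Machine$integer.max
      out$accuracy[i] <- attr(select_features(layers, labels, scfg), "accuracy")
    }
  }
  out
}

#' Patch-size sweep
#'
#' Reruns the full pipeline (grid, layers, selection) for each patch
#' specification, recording the node count and cross-validated accuracy as
#' a function of the patch volume D.
#'
#' @param volumes List of 3D arrays.
#' @param mask Brain mask on the shared shape.
#' @param labels Class labels.
#' @param specs List of [patch_spec()]s.
#' @param min_overlap Mask-overlap retention threshold.
#' @param cor_config A [correlation_config()].
#' @param sel_config A [selection_config()].
#' @return Data frame with `l1`, `l2`, `l3`, `D`, `N`, `accuracy` (specs
#'   too large for a hemisphere are skipped with a warning).
#' @export
patch_size_sweep <- function(volumes, mask, labels, specs,
                             min_overlap = 0.10,
                             cor_config = correlation_config(),
                             sel_config = selection_config()) {
  shape <- dim(volumes[[1L]])
  rows <- lapply(specs, function(sp) {
    grid <- tryCatch(build_patch_grid(shape, sp, mask, min_overlap),
                     error = function(e) {
                       warning("spec ", sp$l1, "x", sp$l2, "x", sp$l3,
                               " skipped: ", conditionMessage(e))
                       NULL
                     })
    if (is.null(grid)) return(NULL)
    layers <- lapply(seq_along(volumes), function(s)
      build_layer(volumes[[s]], grid, cor_config,
                  subject_id = sprintf("S%03d", s)))
    acc <- attr(select_features(layers, labels, sel_config), "accuracy")
    data.frame(l1 = sp$l1, l2 = sp$l2, l3 = sp$l3, D = sp$D,
               N = n_nodes(grid), accuracy = acc)
  })
  do.call(rbind, rows)
}

#' Hemisphere experiments
#'
#' Quantifies the lateralization of the signal in two ways.
#' `feature_subset` keeps the full-brain multiplex but restricts the
#' feature columns to nodes of one hemisphere before selection;
#' `half_multiplex` rebuilds the layers from the nodes of one hemisphere
#' only, so every feature is genuinely intra-hemispheric.
#'
#' @param layers Full-brain `layer_network`s.
#' @param labels Class labels.
#' @param grid The `patch_grid` carrying hemisphere tags.
#' @param mode `"feature_subset"` or `"half_multiplex"`.
#' @param sel_config A [selection_config()].
#' @return Data frame with `hemisphere`, `n_nodes`, `accuracy`.
#' @export
hemisphere_experiments <- function(layers, labels, grid,
                                   mode = c("feature_subset", "half_multiplex"),
                                   sel_config = selection_config()) {
  mode <- match.arg(mode)
  rb <- retained_boxes(grid)
  rows <- lapply(c("L", "R"), function(h) {
    nodes <- rb$node_id[rb$hemisphere == h]
    if (mode == "feature_subset") {
      acc <- attr(select_features(layers, labels, sel_config, nodes = nodes),
                  "accuracy")
    } else {
      half <- lapply(layers, function(l) {
        W <- l$W[nodes, nodes, drop = FALSE]
        structure(list(W = W, subject_id = l$subject_id, N = ncol(W),
                       config = l$config),
                  class = "layer_network")
      })
      acc <- attr(select_features(half, labels, sel_config), "accuracy")
    }
    data.frame(hemisphere = h, n_nodes = length(nodes), accuracy = acc)
  })
  do.call(rbind, rows)
}
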