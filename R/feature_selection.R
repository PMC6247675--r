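#' Feature-selection configuration
#'
#' Parameters of the repeated cross-validated random-forest wrapper. Each
#' round draws stratified k folds; per fold a forest is grown on the
#' training-fold feature matrix, features whose Gini importance exceeds the
#' fold mean are kept, fold selections are unioned into the round's set,
#' and a second forest on the kept features predicts the validation fold.
#' Occurrence counts over rounds then enter an exact binomial test.
#'
#' @param n_rounds Number of cross-validation rounds (default 1000; desk
#'   runs use far fewer).
#' @param k_folds Folds per round (default 5).
#' @param n_trees Trees per forest (default 500).
#' @param mtry `"sqrt"` (default, sqrt(f) candidate features per split) or
#'   `"all"` (every feature at every split, pure bagging).
#' @param alpha Significance level of the occurrence test (default 0.01, no
#'   multiple-testing correction).
#' @param seed Master seed; round seeds are derived by counter.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_rounds = 1000L, k_folds = 5L, n_trees = 500L,
                             mtry = c("sqrt", "all"), alpha = 0.01,
                             seed = 1L) {
  mtry <- match.arg(mtry)
  if (n_rounds < 1L) stop("n_rounds must be >= 1")
  if (k_folds < 2L) stop("k_folds must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_rounds = as.integer(n_rounds), k_folds = as.integer(k_folds),
                 n_trees = as.integer(n_trees), mtry = mtry, alpha = alpha,
                 seed = as.integer(seed)),
            class = "selection_config")
}

mtry_value <- function(config, f) {
  switch(config$mtry, sqrt = max(1L, floor(sqrt(f))), all = f)
}

# stratified fold assignment; resamples until every fold holds both classes
stratified_folds <- function(labels, k) {
  cls <- levels(factor(labels))
  if (min(table(labels)) < 2L) stop("need at least 2 subjects per class")
  for (attempt in 1:100) {
    fold <- integer(length(labels))
    for (cl in cls) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
    ok <- all(vapply(seq_len(k), function(j)
      length(unique(labels[fold == j])) == length(cls), logical(1)))
    if (ok) return(fold)
  }
  stop("could not build stratified folds with both classes in every fold")
}

# Per-layer statistics that do not depend on which other layers are in the
# training fold: edge support, strength, IPR, layer degree and the
# degree-conditional means. Only the aggregate-degree (multiplex) features
# must be recomputed per fold.
layer_stats <- function(layer) {
  W <- layer$W
  s <- rowSums(W)
  Y <- inverse_participation(W)
  k <- as.integer(rowSums(W != 0))
  list(sup = (W != 0) * 1L, s = s, Y = Y, k = k,
       sk = cond_mean_by(s, k), yk = cond_mean_by(Y, k))
}

# 8N feature row from precomputed stats and aggregate degrees
row_from_stats <- function(st, km, N) {
  wgt <- km / (N - 1)
  c(st$s, st$Y, st$sk, st$yk, wgt * st$s, wgt * st$Y,
    cond_mean_by(st$s, km), cond_mean_by(st$Y, km))
}

fit_forest <- function(x, y, config, seed, importance = "none") {
  ranger::ranger(x = x, y = y, num.trees = config$n_trees,
                 mtry = mtry_value(config, ncol(x)),
                 importance = importance, num.threads = 1L, seed = seed)
}

#' One cross-validation round of the selection wrapper
#'
#' @param layers List of `layer_network` (one per training subject).
#' @param labels Factor of class labels aligned to `layers`.
#' @param config A [selection_config()].
#' @param round_seed Integer seed for this round's folds and forests.
#' @param nodes Optional node ids; when given, only feature columns of
#'   these nodes are visible to the round (hemisphere-restricted runs).
#' @param stats Optional precomputed per-layer statistics (internal reuse
#'   across rounds); computed from `layers` when `NULL`.
#' @return A list with `selected` (character feature names, union over
#'   folds) and `accuracy` (validation accuracy pooled over folds).
#' @export
cv_round <- function(layers, labels, config, round_seed = config$seed,
                     nodes = NULL, stats = NULL) {
  labels <- factor(labels)
  if (is.null(stats)) stats <- lapply(layers, layer_stats)
  N <- length(stats[[1L]]$s)
  ids <- colnames(layers[[1L]]$W)
  if (is.null(ids)) ids <- as.character(seq_len(N))
  universe <- paste(rep(feature_metrics(), each = N), rep(ids, times = 8L),
                    sep = "_")
  keep <- if (is.null(nodes)) seq_along(universe) else
    which(rep(ids, times = 8L) %in% nodes)
  S_all <- Reduce(`+`, lapply(stats, `[[`, "sup"))
  set.seed(round_seed)
  fold <- stratified_folds(labels, config$k_folds)
  selected <- character(0)
  n_ok <- 0L; n_tot <- 0L
  for (j in seq_len(config$k_folds)) {
    tr <- which(fold != j); va <- which(fold == j)
    S_tr <- S_all
    for (v in va) S_tr <- S_tr - stats[[v]]$sup
    A_tr <- S_tr > 0
    km <- as.integer(rowSums(A_tr))
    Ftr <- t(vapply(tr, function(i) row_from_stats(stats[[i]], km, N),
                    numeric(8L * N)))
    colnames(Ftr) <- universe
    Ftr <- Ftr[, keep, drop = FALSE]
    rf1 <- fit_forest(Ftr, labels[tr], config, round_seed + 7L * j,
                      importance = "impurity")
    imp <- rf1$variable.importance
    sel <- names(imp)[imp > mean(imp)]
    selected <- union(selected, sel)
    Fva <- t(vapply(va, function(v) {
      A_v <- (S_tr + stats[[v]]$sup) > 0
      row_from_stats(stats[[v]], as.integer(rowSums(A_v)), N)
    }, numeric(8L * N)))
    colnames(Fva) <- universe
    Fva <- Fva[, keep, drop = FALSE]
    if (length(sel) > 0L) {
      rf2 <- fit_forest(Ftr[, sel, drop = FALSE], labels[tr], config,
                        round_seed + 7L * j + 3L)
      pred <- stats::predict(rf2, data = Fva[, sel, drop = FALSE],
                             num.threads = 1L)$predictions
    } else {
      # degenerate: no informative split anywhere; fall back to majority
      maj <- names(which.max(table(labels[tr])))
      pred <- factor(rep(maj, length(va)), levels = levels(labels))
    }
    n_ok <- n_ok + sum(pred == labels[va]); n_tot <- n_tot + length(va)
  }
  list(selected = selected, accuracy = n_ok / n_tot)
}

#' Binomial occurrence test on selection counts
#'
#' Interprets how often each feature was selected across rounds as a
#' success count. The null success rate is estimated from the pooled
#' selection mass (`p0 = sum(counts) / (n_trials * f)`, the rate expected
#' if rounds picked features exchangeably), and each feature gets a
#' one-sided exact binomial tail `P(X >= c)`. No multiple-testing
#' correction is applied.
#'
#' @param counts Named integer vector of per-feature occurrence counts.
#' @param n_trials Number of rounds each feature was eligible in.
#' @param alpha Significance level; a feature is selected when `p < alpha`.
#' @return An object of class `selection_result`: a data frame with
#'   `feature`, `metric`, `node`, `count`, `n_trials`, `p_value`,
#'   `selected`; attributes `p0_hat` and `alpha`.
#' @export
occurrence_test <- function(counts, n_trials, alpha = 0.01) {
  if (n_trials < 1L) stop("n_trials must be >= 1")
  if (any(counts < 0) || any(counts > n_trials))
    stop("counts must lie in [0, n_trials]")
  f <- length(counts)
  p0 <- sum(counts) / (n_trials * f)
  p <- stats::pbinom(counts - 1L, size = n_trials, prob = p0,
                     lower.tail = FALSE)
  feat <- names(counts)
  if (is.null(feat)) feat <- as.character(seq_len(f))
  res <- data.frame(feature = feat,
                    metric = sub("_[^_]*$", "", feat),
                    node = sub(".*_", "", feat),
                    count = as.integer(counts),
                    n_trials = as.integer(n_trials),
                    p_value = p,
                    selected = p < alpha,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("selection_result", "data.frame"),
            p0_hat = p0, alpha = alpha)
}

#' Repeated-CV feature selection with occurrence testing
#'
#' Orchestrates `n_rounds` cross-validation rounds over the training
#' layers, accumulates per-feature occurrence counts and per-round
#' validation accuracies, and applies the binomial occurrence test.
#'
#' @param layers List of `layer_network`, one per subject.
#' @param labels Class labels aligned to `layers`.
#' @param config A [selection_config()].
#' @param nodes Optional node ids restricting the visible feature columns
#'   (hemisphere-restricted runs).
#' @return A `selection_result` (see [occurrence_test()]) with extra
#'   attributes `accuracy` (mean per-round validation accuracy),
#'   `accuracy_se` (standard error over rounds), `accuracies` (per round)
#'   and `config`.
#' @export
select_features <- function(layers, labels, config = selection_config(),
                            nodes = NULL) {
  stopifnot(inherits(config, "selection_config"))
  labels <- factor(labels)
  if (length(layers) < 2L * config$k_folds)
    stop("need at least 2 * k_folds subjects")
  ids <- colnames(layers[[1L]]$W)
  if (is.null(ids)) ids <- as.character(seq_len(layers[[1L]]$N))
  if (!is.null(nodes)) ids <- ids[ids %in% nodes]
  universe <- paste(rep(feature_metrics(), each = length(ids)),
                    rep(ids, times = 8L), sep = "_")
  counts <- stats::setNames(integer(length(universe)), universe)
  acc <- numeric(config$n_rounds)
  lstats <- lapply(layers, layer_stats)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  for (r in seq_len(config$n_rounds)) {
    rs <- (config$seed + 1009L * r) %% .Machine$integer.max
    out <- cv_round(layers, labels, config, round_seed = rs, nodes = nodes,
                    stats = lstats)
    counts[out$selected] <- counts[out$selected] + 1L
    acc[r] <- out$accuracy
  }
  res <- occurrence_test(counts, config$n_rounds, config$alpha)
  attr(res, "accuracy") <- mean(acc)
  attr(res, "accuracy_se") <- if (length(acc) > 1L)
    stats::sd(acc) / sqrt(length(acc)) else NA_real_
  attr(res, "accuracies") <- acc
  attr(res, "config") <- config
  res
}

#' Selected feature names of a selection result
#' @param result A `selection_result`.
#' @return Character vector of feature names with `selected == TRUE`.
#' @export
selected_features <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  result$feature[result$selected]
}

#' Write a selection result as TSV (plus JSON run metadata)
#' @param result A `selection_result`.
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_selection_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- attr(result, "config")
  meta <- list(p0_hat = attr(result, "p0_hat"), alpha = attr(result, "alpha"),
               accuracy = attr(result, "accuracy"),
               accuracy_se = attr(result, "accuracy_se"),
               config = if (is.null(cfg)) NULL else unclass(cfg))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
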