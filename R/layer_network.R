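#' Correlation-layer configuration
#'
#' @param threshold Correlation threshold tau in \[0, 1): pairwise patch
#'   correlations with `|r| <= tau` are set to zero (default 0.3, the
#'   moderate-correlation cut).
#' @param zero_variance One of `"zero"` (a constant patch correlates 0 with
#'   everything) or `"error"`.
#' @param use_abs_weights If `TRUE` (default) surviving edges carry `|r|`,
#'   keeping strengths nonnegative and the inverse participation ratio in
#'   \[1/k, 1\]; if `FALSE` the signed correlation is kept.
#' @return An object of class `correlation_config`.
#' @export
correlation_config <- function(threshold = 0.3,
                               zero_variance = c("zero", "error"),
                               use_abs_weights = TRUE) {
  zero_variance <- match.arg(zero_variance)
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  structure(list(threshold = threshold, zero_variance = zero_variance,
                 use_abs_weights = isTRUE(use_abs_weights)),
            class = "correlation_config")
}

#' Pearson correlation of two patch vectors
#'
#' Standard Pearson correlation: each patch centered on its own mean and
#' scaled by its own standard deviation, with voxel positions associated
#' pairwise.
#'
#' @param si,sj Numeric vectors of equal length `D >= 2`.
#' @param zero_variance Policy when a patch has zero variance: `"zero"`
#'   returns 0, `"error"` fails.
#' @return Correlation in \[-1, 1\].
#' @export
patch_pearson <- function(si, sj, zero_variance = c("zero", "error")) {
  zero_variance <- match.arg(zero_variance)
  if (length(si) != length(sj)) stop("patch vectors must have equal length")
  if (length(si) < 2L) stop("patch vectors must have length >= 2")
  if (stats::sd(si) == 0 || stats::sd(sj) == 0) {
    if (zero_variance == "error") stop("zero-variance patch")
    return(0)
  }
  stats::cor(si, sj)
}

#' Threshold a correlation into an edge weight
#'
#' `|r| <= tau` is discarded (the boundary included); otherwise the weight
#' is `r`, or `|r|` in absolute-weight mode.
#'
#' @param r Correlation value(s) in \[-1, 1\] (vectorized).
#' @param tau Threshold in \[0, 1).
#' @param use_abs_weights Keep `|r|` instead of `r`.
#' @return Thresholded weight(s).
#' @export
threshold_weight <- function(r, tau = 0.3, use_abs_weights = TRUE) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  w <- if (use_abs_weights) abs(r) else r
  w[abs(r) <= tau] <- 0
  w
}

#' Build one subject's correlation layer
#'
#' Evaluates all pairwise Pearson correlations between the retained patch
#' vectors of one volume and thresholds them into a symmetric weighted
#' adjacency matrix with a zero diagonal (one layer of the multiplex).
#'
#' @param volume 3D numeric array on the grid shape, or a precomputed
#'   `D x N` patch matrix from [patch_matrix()].
#' @param grid A `patch_grid` (ignored when `volume` is already a patch
#'   matrix).
#' @param config A [correlation_config()].
#' @param subject_id Optional identifier stored with the layer.
#' @return An object of class `layer_network`: a list with `W` (`N x N`
#'   symmetric matrix), `subject_id`, `N`, `config`.
#' @export
build_layer <- function(volume, grid = NULL, config = correlation_config(),
                        subject_id = NA_character_) {
  stopifnot(inherits(config, "correlation_config"))
  P <- if (is.matrix(volume)) volume else patch_matrix(volume, grid)
  if (ncol(P) == 0L) stop("layer has zero nodes")
  sds <- apply(P, 2L, stats::sd)
  if (any(sds == 0) && config$zero_variance == "error")
    stop("zero-variance patch encountered")
  R <- suppressWarnings(stats::cor(P))
  R[!is.finite(R)] <- 0       # zero-variance columns correlate 0
  W <- threshold_weight(R, config$threshold, config$use_abs_weights)
  diag(W) <- 0
  W <- (W + t(W)) / 2         # enforce exact symmetry against fp asymmetry
  structure(list(W = W, subject_id = subject_id, N = ncol(W), config = config),
            class = "layer_network")
}

#' @export
print.layer_network <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] != 0)
  cat(sprintf("layer_network: %d nodes, %d edges (tau = %g)%s\n", x$N, ne,
              x$config$threshold,
              if (ne == 0L) " [empty network]" else ""))
  invisible(x)
}

#' Is a layer empty?
#' @param layer A `layer_network`.
#' @return `TRUE` when the layer has no surviving edge.
#' @export
is_empty_layer <- function(layer) {
  stopifnot(inherits(layer, "layer_network"))
  all(layer$W == 0)
}

#' Write a layer as an edge-list TSV plus JSON sidecar
#' @param layer A `layer_network`.
#' @param path TSV output path (`<path>.json` gets the sidecar).
#' @return `path`, invisibly.
#' @export
write_layer <- function(layer, path) {
  ut <- upper.tri(layer$W)
  idx <- which(ut & layer$W != 0, arr.ind = TRUE)
  ids <- colnames(layer$W)
  if (is.null(ids)) ids <- as.character(seq_len(layer$N))
  edges <- data.frame(i = ids[idx[, 1L]], j = ids[idx[, 2L]],
                      w = layer$W[idx])
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(subject_id = layer$subject_id, threshold = layer$config$threshold,
               use_abs_weights = layer$config$use_abs_weights, N = layer$N,
               n_edges = nrow(edges))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
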