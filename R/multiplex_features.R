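#' Assemble per-subject layers into a multiplex
#'
#' A multiplex is a collection of layers (one per subject) sharing a common
#' node set and ordering; only the edge sets differ across layers.
#'
#' @param layers List of `layer_network` objects with identical `N` and
#'   node ordering.
#' @param labels Optional class labels, kept only for bookkeeping.
#' @return An object of class `multiplex`: list with `layers`, `M`, `N`,
#'   `node_ids`, `labels`.
#' @export
multiplex <- function(layers, labels = NULL) {
  if (length(layers) < 1L) stop("a multiplex needs at least one layer")
  stopifnot(all(vapply(layers, inherits, logical(1), "layer_network")))
  Ns <- vapply(layers, `[[`, integer(1), "N")
  if (length(unique(Ns)) != 1L) stop("all layers must share the same node count")
  ids <- colnames(layers[[1L]]$W)
  if (is.null(ids)) ids <- as.character(seq_len(Ns[1L]))
  structure(list(layers = layers, M = length(layers), N = Ns[1L],
                 node_ids = ids, labels = labels),
            class = "multiplex")
}

#' @export
print.multiplex <- function(x, ...) {
  cat(sprintf("multiplex: M = %d layers, N = %d nodes\n", x$M, x$N))
  invisible(x)
}

#' Node strength of a layer
#'
#' Row sums of the thresholded weight matrix: the total edge weight
#' attached to each node within one subject's network.
#'
#' @param layer A `layer_network` (or bare weight matrix).
#' @return Numeric vector of length N.
#' @export
node_strength <- function(layer) {
  W <- if (inherits(layer, "layer_network")) layer$W else layer
  rowSums(W)
}

#' Node degree of a layer
#' @param layer A `layer_network` (or bare weight matrix).
#' @return Integer vector: number of nonzero edges per node.
#' @export
node_degree <- function(layer) {
  W <- if (inherits(layer, "layer_network")) layer$W else layer
  as.integer(rowSums(W != 0))
}

#' Inverse participation ratio of a layer
#'
#' Per node, the sum of squared weights normalized by the node strength:
#' 1/k for k equal weights (maximally spread) up to 1 for a single edge
#' (maximally concentrated). Isolated nodes get 0 by convention.
#'
#' @param layer A `layer_network` (or bare weight matrix).
#' @return Numeric vector of length N.
#' @export
inverse_participation <- function(layer) {
  W <- if (inherits(layer, "layer_network")) layer$W else layer
  s <- rowSums(W)
  Y <- rowSums(sweep(W, 1L, ifelse(s == 0, 1, s), "/")^2)
  Y[s == 0] <- 0
  Y
}

# group mean of `values` over nodes sharing the same `groups` value; nodes
# with group 0 (isolated in the relevant sense) get 0 by convention
cond_mean_by <- function(values, groups) {
  out <- stats::ave(values, groups, FUN = mean)
  out[groups == 0] <- 0
  out
}

#' Degree-conditional means of strength and inverse participation
#'
#' For each degree k present in the layer, the mean strength (and mean
#' inverse participation) over the nodes of that degree; each node is then
#' assigned the conditional mean at its own degree. Degree-0 nodes get 0.
#'
#' @param layer A `layer_network` (or bare weight matrix).
#' @return A list with per-node vectors `s_k`, `y_k`, the per-node `degree`,
#'   and a summary data frame `table` (`k`, `n_k`, `s_k`, `y_k`).
#' @export
conditional_means <- function(layer) {
  W <- if (inherits(layer, "layer_network")) layer$W else layer
  k <- as.integer(rowSums(W != 0))
  s <- rowSums(W)
  Y <- inverse_participation(W)
  sk <- cond_mean_by(s, k)
  yk <- cond_mean_by(Y, k)
  tab <- do.call(rbind, lapply(sort(unique(k)), function(kk) {
    sel <- k == kk
    data.frame(k = kk, n_k = sum(sel), s_k = mean(s[sel]), y_k = mean(Y[sel]))
  }))
  list(s_k = sk, y_k = yk, degree = k, table = tab)
}

#' Aggregate adjacency of a multiplex
#'
#' Binary union of the edge supports over all layers: nodes i and j are
#' aggregate-adjacent when any layer carries a nonzero weight between them
#' (`|w| > 0`, so signed-mode negative edges count). Row sums are the
#' aggregate degrees.
#'
#' @param mux A `multiplex`.
#' @return An object of class `aggregate_adjacency`: list with `A` (binary
#'   `N x N` matrix) and `k_multi` (integer aggregate degrees).
#' @export
aggregate_adjacency <- function(mux) {
  stopifnot(inherits(mux, "multiplex"))
  S <- Reduce(`+`, lapply(mux$layers, function(l) abs(l$W) > 0))
  A <- (S > 0) * 1L
  diag(A) <- 0L
  structure(list(A = A, k_multi = as.integer(rowSums(A))),
            class = "aggregate_adjacency")
}

#' Multiplex node features of one layer
#'
#' Re-expresses a layer's strength and inverse participation in the context
#' of the whole multiplex: each is weighted by the node's normalized
#' aggregate degree `k_multi / (N - 1)`, and the degree-conditional means
#' are recomputed grouping nodes by aggregate degree instead of the layer
#' degree. Nodes with aggregate degree 0 get 0 throughout.
#'
#' @param layer A `layer_network`.
#' @param aggregate An `aggregate_adjacency` sharing the layer's N.
#' @return A list of per-node vectors `ms`, `my`, `ms_k`, `my_k`.
#' @export
multiplex_node_features <- function(layer, aggregate) {
  stopifnot(inherits(aggregate, "aggregate_adjacency"))
  W <- if (inherits(layer, "layer_network")) layer$W else layer
  N <- ncol(W)
  if (length(aggregate$k_multi) != N) stop("layer and aggregate disagree on N")
  s <- rowSums(W)
  Y <- inverse_participation(W)
  km <- aggregate$k_multi
  wgt <- km / (N - 1)
  msk <- cond_mean_by(s, km)
  myk <- cond_mean_by(Y, km)
  list(ms = wgt * s, my = wgt * Y, ms_k = msk, my_k = myk)
}

#' Feature metric names
#'
#' The eight node metrics, in the fixed column-block order of the feature
#' matrix: four single-layer (strength, inverse participation ratio, their
#' degree-conditional means) and four multiplex (aggregate-degree weighted
#' strength/IPR, conditional means grouped by aggregate degree).
#'
#' @return Character vector of length 8.
#' @export
feature_metrics <- function() {
  c("strength", "ipr", "strengthk", "iprk",
    "mstrength", "mipr", "mstrengthk", "miprk")
}

# 8N named feature row for one layer given the aggregate degrees
layer_feature_row <- function(layer, aggregate, node_ids) {
  W <- layer$W
  s <- rowSums(W)
  Y <- inverse_participation(W)
  cm <- conditional_means(W)
  mx <- multiplex_node_features(layer, aggregate)
  vals <- c(s, Y, cm$s_k, cm$y_k, mx$ms, mx$my, mx$ms_k, mx$my_k)
  names(vals) <- paste(rep(feature_metrics(), each = length(node_ids)),
                       rep(node_ids, times = 8L), sep = "_")
  vals
}

#' Subject-by-feature matrix of a multiplex
#'
#' One row per subject (layer), 8N named columns: the four single-layer and
#' four multiplex node metrics for every node, in deterministic
#' metric-major order (`<metric>_<node-id>`). Built blind to class labels.
#'
#' @param mux A `multiplex`.
#' @return `M x 8N` numeric matrix with subject ids as row names.
#' @export
feature_matrix <- function(mux) {
  stopifnot(inherits(mux, "multiplex"))
  agg <- aggregate_adjacency(mux)
  rows <- t(vapply(mux$layers, layer_feature_row, numeric(8L * mux$N),
                   aggregate = agg, node_ids = mux$node_ids))
  rn <- vapply(mux$layers, function(l) l$subject_id, character(1))
  if (all(!is.na(rn))) rownames(rows) <- rn
  rows
}

#' Feature row of a held-out subject
#'
#' Computes the 8N features of a new layer against a training multiplex:
#' single-layer features come from the new layer alone; the aggregate
#' adjacency is recomputed over the M + 1 layers (training plus the new
#' one), leaving the training feature rows untouched. The perturbation of
#' the aggregate by one added layer is small, which is what makes held-out
#' rows comparable with training rows.
#'
#' @param mux The training `multiplex`.
#' @param new_layer A `layer_network` on the same grid.
#' @return Named numeric vector of length 8N.
#' @export
append_test_layer_features <- function(mux, new_layer) {
  stopifnot(inherits(mux, "multiplex"), inherits(new_layer, "layer_network"))
  if (new_layer$N != mux$N) stop("new layer is not on the training grid")
  S <- Reduce(`+`, lapply(mux$layers, function(l) abs(l$W) > 0))
  A <- ((S + (abs(new_layer$W) > 0)) > 0) * 1L
  diag(A) <- 0L
  agg <- structure(list(A = A, k_multi = as.integer(rowSums(A))),
                   class = "aggregate_adjacency")
  layer_feature_row(new_layer, agg, mux$node_ids)
}

#' Write a feature matrix as TSV
#' @param features Matrix from [feature_matrix()].
#' @param path Output path.
#' @param labels Optional class labels prepended as a `class` column.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path, labels = NULL) {
  df <- data.frame(subject_id = if (is.null(rownames(features)))
    sprintf("S%03d", seq_len(nrow(features))) else rownames(features),
    check.names = FALSE)
  if (!is.null(labels)) df$class <- as.character(labels)
  df <- cbind(df, as.data.frame(features, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
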