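#' Atlas labels overlapped by one patch
#'
#' Counts, per nonzero atlas label, the voxels of the label falling inside
#' the box; one voxel is enough to qualify a region, so the same region can
#' be reached from several patches.
#'
#' @param box Single-row data frame (or list) with `x0`, `y0`, `z0`, `l1`,
#'   `l2`, `l3`.
#' @param atlas Integer-labeled 3D array (0 = background).
#' @return Named integer vector: voxel counts per label (empty when the
#'   box lies entirely in background).
#' @export
patch_regions <- function(box, atlas) {
  d <- dim(atlas)
  x1 <- box$x0 + box$l1 - 1L; y1 <- box$y0 + box$l2 - 1L; z1 <- box$z0 + box$l3 - 1L
  if (box$x0 < 1L || box$y0 < 1L || box$z0 < 1L ||
      x1 > d[1L] || y1 > d[2L] || z1 > d[3L])
    stop("box out of atlas bounds")
  v <- atlas[box$x0:x1, box$y0:y1, box$z0:z1]
  v <- v[v != 0]
  if (length(v) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-node significance from direct features
#'
#' Direct features (strength, inverse participation ratio and their
#' multiplex-weighted variants) attach to a single node; each node's p is
#' the minimum over its selected direct features. Nodes with no selected
#' direct feature are absent.
#'
#' @param result A `selection_result`.
#' @return Data frame with `node`, `p_value`, sorted ascending.
#' @export
node_significance <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  direct <- c("strength", "ipr", "mstrength", "mipr")
  sel <- result[result$selected & result$metric %in% direct, , drop = FALSE]
  if (nrow(sel) == 0L)
    return(data.frame(node = character(0), p_value = numeric(0)))
  p <- tapply(sel$p_value, sel$node, min)
  out <- data.frame(node = names(p), p_value = as.numeric(p))
  out <- out[order(out$p_value, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Patches behind a significant conditional-mean feature
#'
#' A degree-conditional feature summarizes every node sharing the
#' conditioning degree, so its anatomical support is recovered per subject:
#' the nodes whose degree (layer degree for `strengthk`/`iprk`, aggregate
#' degree for `mstrengthk`/`miprk`) equals the degree of the feature's node
#' in that subject. Occurrence counts over the M subjects are tested
#' against an empirical binomial null (null rate = mean fraction of nodes
#' per subject in the degree class); patches with `p < alpha` are kept.
#'
#' @param mux The training `multiplex`.
#' @param feature A conditional-mean feature name, e.g. `"strengthk_L012"`.
#' @param alpha Significance level (default 0.01).
#' @return Data frame with `node`, `count`, `p_value`, `kept`.
#' @export
conditional_feature_patches <- function(mux, feature, alpha = 0.01) {
  stopifnot(inherits(mux, "multiplex"))
  metric <- sub("_[^_]*$", "", feature)
  node <- sub(".*_", "", feature)
  if (!metric %in% c("strengthk", "iprk", "mstrengthk", "miprk"))
    stop("feature is not a conditional-mean column: ", feature)
  ni <- match(node, mux$node_ids)
  if (is.na(ni)) stop("unknown node: ", node)
  aggregate_mode <- metric %in% c("mstrengthk", "miprk")
  km <- if (aggregate_mode) aggregate_adjacency(mux)$k_multi else NULL
  counts <- stats::setNames(integer(mux$N), mux$node_ids)
  class_frac <- numeric(mux$M)
  for (a in seq_len(mux$M)) {
    k <- if (aggregate_mode) km else node_degree(mux$layers[[a]])
    members <- which(k == k[ni])
    counts[members] <- counts[members] + 1L
    class_frac[a] <- length(members) / mux$N
  }
  p0 <- mean(class_frac)
  p <- stats::pbinom(counts - 1L, size = mux$M, prob = p0, lower.tail = FALSE)
  out <- data.frame(node = mux$node_ids, count = as.integer(counts),
                    p_value = p, kept = p < alpha)
  rownames(out) <- NULL
  out
}

#' Region report of a selection result
#'
#' Maps all significant nodes — those carrying selected direct features,
#' plus the patches recovered behind selected conditional-mean features —
#' to atlas regions via voxel overlap, reporting each region once with its
#' minimum p over contributing patches, ordered by ascending p, with
#' hemisphere tallies. When occurrence counts saturate, p-values tie at
#' their floor; ties are then broken by the strength of the directly
#' localized evidence — the minimum p among the region's selected direct
#' features, then how many direct features sit at that minimum — because
#' direct features attach to a single patch while conditional-mean
#' features localize only through an occurrence heuristic. Overlap voxels
#' break any remaining ties.
#'
#' @param result A `selection_result`.
#' @param mux The training `multiplex` (needed to resolve conditional-mean
#'   features; may be `NULL` if none were selected).
#' @param grid The `patch_grid`.
#' @param atlas Integer-labeled 3D array on the grid shape.
#' @param atlas_names Data frame with `label`, `name`.
#' @param alpha Significance level for the conditional-patch test.
#' @return An object of class `region_report`: data frame with `region`,
#'   `p_value`, `n_patches`, `patches`, `hemisphere_l`, `hemisphere_r`,
#'   `overlap_voxels`; attribute `significant_nodes` (per-node table).
#' @export
region_report <- function(result, mux, grid, atlas, atlas_names,
                          alpha = attr(result, "alpha")) {
  stopifnot(inherits(result, "selection_result"), inherits(grid, "patch_grid"))
  if (is.null(alpha)) alpha <- 0.01
  nodes <- node_significance(result)
  direct <- result[result$selected &
                     result$metric %in% c("strength", "ipr", "mstrength", "mipr"),
                   , drop = FALSE]
  node_direct_min <- tapply(direct$p_value, direct$node, min)
  node_direct_nmin <- vapply(names(node_direct_min), function(nd)
    sum(direct$p_value[direct$node == nd] == node_direct_min[[nd]]), integer(1))
  cond <- result[result$selected &
                   result$metric %in% c("strengthk", "iprk", "mstrengthk", "miprk"),
                 , drop = FALSE]
  if (nrow(cond) > 0L) {
    if (is.null(mux)) stop("conditional-mean features selected; mux required")
    for (i in seq_len(nrow(cond))) {
      cp <- conditional_feature_patches(mux, cond$feature[i], alpha)
      kept <- cp[cp$kept, , drop = FALSE]
      if (nrow(kept) > 0L) {
        add <- data.frame(node = kept$node,
                          p_value = pmax(cond$p_value[i], kept$p_value))
        nodes <- rbind(nodes, add)
      }
    }
    if (nrow(nodes) > 0L) {
      p <- tapply(nodes$p_value, nodes$node, min)
      nodes <- data.frame(node = names(p), p_value = as.numeric(p))
    }
  }
  if (nrow(nodes) == 0L) {
    out <- data.frame(region = character(0), p_value = numeric(0),
                      n_patches = integer(0), patches = character(0),
                      hemisphere_l = integer(0), hemisphere_r = integer(0),
                      overlap_voxels = integer(0))
    return(structure(out, class = c("region_report", "data.frame"),
                     significant_nodes = nodes))
  }
  rb <- retained_boxes(grid)
  hits <- list()
  for (i in seq_len(nrow(nodes))) {
    b <- rb[rb$node_id == nodes$node[i], , drop = FALSE]
    if (nrow(b) == 0L) next
    ov <- patch_regions(b[1L, ], atlas)
    nd <- nodes$node[i]
    has_direct <- nd %in% names(node_direct_min)
    for (lab in names(ov)) {
      hits[[length(hits) + 1L]] <- data.frame(
        label = as.integer(lab), node = nd,
        hemisphere = b$hemisphere[1L], p_value = nodes$p_value[i],
        voxels = ov[[lab]],
        direct_p = if (has_direct) node_direct_min[[nd]] else Inf,
        direct_n = if (has_direct) node_direct_nmin[[nd]] else 0L)
    }
  }
  if (length(hits) == 0L) {
    out <- data.frame(region = character(0), p_value = numeric(0),
                      n_patches = integer(0), patches = character(0),
                      hemisphere_l = integer(0), hemisphere_r = integer(0),
                      overlap_voxels = integer(0))
    return(structure(out, class = c("region_report", "data.frame"),
                     significant_nodes = nodes))
  }
  hits <- do.call(rbind, hits)
  rows <- lapply(split(hits, hits$label), function(h) {
    u <- h[!duplicated(h$node), , drop = FALSE]
    dmin <- min(u$direct_p)
    data.frame(region = atlas_names$name[match(h$label[1L], atlas_names$label)],
               p_value = min(h$p_value),
               n_patches = nrow(u),
               direct_min_p = if (is.finite(dmin)) dmin else NA_real_,
               direct_at_min = if (is.finite(dmin))
                 sum(u$direct_n[u$direct_p == dmin]) else 0L,
               patches = paste(sort(u$node), collapse = ","),
               hemisphere_l = sum(u$hemisphere == "L"),
               hemisphere_r = sum(u$hemisphere == "R"),
               overlap_voxels = sum(h$voxels))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, ifelse(is.na(out$direct_min_p), Inf,
                                       out$direct_min_p),
                   -out$direct_at_min, -out$overlap_voxels, out$region),
             , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("region_report", "data.frame"),
            significant_nodes = nodes)
}

#' Write a region report as TSV and JSON
#' @param report A `region_report`.
#' @param path TSV output path (`<path>.json` written alongside).
#' @return `path`, invisibly.
#' @export
write_region_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.data.frame(report), paste0(path, ".json"),
                       digits = NA)
  invisible(path)
}
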