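#' Patch specification
#'
#' Edge lengths of the rectangular boxes used to tile each hemisphere.
#' `l1` runs along the left-right (x) axis, `l2` along y, `l3` along z;
#' `D = l1 * l2 * l3` is the number of voxels per patch.
#'
#' @param l1,l2,l3 Positive integer edge lengths in voxels.
#' @return An object of class `patch_spec`: a list with `l1`, `l2`, `l3`
#'   and the box volume `D`.
#' @examples
#' patch_spec(10, 15, 20)
#' @export
patch_spec <- function(l1, l2, l3) {
  l <- c(l1, l2, l3)
  if (length(l) != 3L || any(!is.finite(l)) || any(l < 1) || any(l != round(l)))
    stop("patch edge lengths must be positive integers")
  structure(list(l1 = as.integer(l1), l2 = as.integer(l2), l3 = as.integer(l3),
                 D = as.integer(l1) * as.integer(l2) * as.integer(l3)),
            class = "patch_spec")
}

#' @export
print.patch_spec <- function(x, ...) {
  cat(sprintf("patch_spec: %d x %d x %d voxels (D = %d)\n", x$l1, x$l2, x$l3, x$D))
  invisible(x)
}

#' Split a grid at the midsagittal plane
#'
#' Divides the x (left-right) extent of the image grid into a left and a
#' right hemisphere at the medial longitudinal fissure. For an even extent
#' the two halves meet at the middle; for an odd extent the central sagittal
#' plane belongs to neither hemisphere.
#'
#' @param shape Integer vector of 3 image extents (x, y, z).
#' @return A list with 1-based inclusive column ranges `left = c(lo, hi)`,
#'   `right = c(lo, hi)`, and `excluded` (the central plane index for odd
#'   extents, otherwise `NA`).
#' @examples
#' midsagittal_split(c(196, 233, 189))
#' midsagittal_split(c(197, 233, 189))
#' @export
midsagittal_split <- function(shape) {
  if (length(shape) != 3L || any(shape < 1)) stop("shape must have 3 positive extents")
  X <- as.integer(shape[1L])
  if (X < 2L) stop("x extent must be at least 2 to define two hemispheres")
  if (X %% 2L == 0L) {
    c <- X %/% 2L
    list(left = c(1L, c), right = c(c + 1L, X), excluded = NA_integer_)
  } else {
    c <- (X - 1L) %/% 2L
    list(left = c(1L, c), right = c(c + 2L, X), excluded = c + 1L)
  }
}

# 1-based origins of non-overlapping intervals of length l inside [lo, hi],
# under an anchoring convention. Partial intervals are discarded.
tile_1d <- function(lo, hi, l, anchor = c("start", "center", "end")) {
  anchor <- match.arg(anchor)
  w <- hi - lo + 1L
  n <- w %/% l
  if (n < 1L) return(integer(0))
  off <- switch(anchor, start = 0L, center = (w - n * l) %/% 2L, end = w - n * l)
  lo + off + l * (seq_len(n) - 1L)
}

#' Build the shared patch grid
#'
#' Tiles both hemispheres of a common image grid with non-overlapping
#' rectangular boxes and flags as retained the boxes whose overlap with the
#' brain mask reaches `min_overlap`. The retained boxes are the shared node
#' set of every subject's network; the grid depends only on the geometry and
#' the mask, never on subject intensities.
#'
#' Along x, tiling is by default anchored at the fissure and extends
#' outward, so partial boxes fall at the lateral edges and are discarded;
#' along y and z the tiling is centered by default. All three conventions
#' are configurable because the retained count is sensitive to them.
#'
#' @param shape Integer vector of 3 image extents.
#' @param spec A [patch_spec()].
#' @param mask Logical or 0/1 numeric 3D array on `shape`.
#' @param min_overlap Minimum fraction of box voxels inside the mask for a
#'   box to be retained (default 0.10).
#' @param anchor_x One of `"fissure"`, `"edge"`, `"center"`: x anchoring
#'   within each hemisphere.
#' @param anchor_y,anchor_z One of `"center"`, `"start"`, `"end"`.
#' @return An object of class `patch_grid`: a data frame with one row per
#'   candidate box (`node_id`, `hemisphere`, `x0`, `y0`, `z0` 1-based
#'   origins, `l1`, `l2`, `l3`, `overlap`, `retained`), ordered by
#'   hemisphere then origin. Attributes: `shape`, `spec`, `min_overlap`,
#'   `N` (number of retained boxes).
#' @export
build_patch_grid <- function(shape, spec, mask, min_overlap = 0.10,
                             anchor_x = c("fissure", "edge", "center"),
                             anchor_y = c("center", "start", "end"),
                             anchor_z = c("center", "start", "end")) {
  anchor_x <- match.arg(anchor_x)
  anchor_y <- match.arg(anchor_y)
  anchor_z <- match.arg(anchor_z)
  stopifnot(inherits(spec, "patch_spec"))
  shape <- as.integer(shape)
  if (!is.null(dim(mask)) && !identical(as.integer(dim(mask)), shape))
    stop("mask shape does not match image shape")
  if (min_overlap <= 0 || min_overlap > 1) stop("min_overlap must be in (0, 1]")
  hemi <- midsagittal_split(shape)
  hw <- c(diff(hemi$left), diff(hemi$right)) + 1L
  if (spec$l1 > min(hw) || spec$l2 > shape[2L] || spec$l3 > shape[3L])
    stop("patch spec does not fit inside a hemisphere")

  xs_hemi <- function(rng, side) {
    if (anchor_x == "fissure") {
      # anchored at the fissure, growing outward
      a <- if (side == "L") "end" else "start"
      tile_1d(rng[1L], rng[2L], spec$l1, a)
    } else if (anchor_x == "edge") {
      a <- if (side == "L") "start" else "end"
      tile_1d(rng[1L], rng[2L], spec$l1, a)
    } else tile_1d(rng[1L], rng[2L], spec$l1, "center")
  }
  ys <- tile_1d(1L, shape[2L], spec$l2, anchor_y)
  zs <- tile_1d(1L, shape[3L], spec$l3, anchor_z)

  rows <- lapply(c("L", "R"), function(side) {
    rng <- if (side == "L") hemi$left else hemi$right
    xs <- sort(xs_hemi(rng, side))
    if (!length(xs) || !length(ys) || !length(zs))
      return(NULL)
    g <- expand.grid(z0 = zs, y0 = ys, x0 = xs, KEEP.OUT.ATTRS = FALSE)
    data.frame(hemisphere = side, x0 = g$x0, y0 = g$y0, z0 = g$z0)
  })
  grid <- do.call(rbind, rows)
  if (is.null(grid)) stop("no candidate boxes fit the grid")
  grid <- grid[order(grid$hemisphere, grid$x0, grid$y0, grid$z0), , drop = FALSE]

  m <- array(as.numeric(mask != 0), dim = shape)
  grid$overlap <- vapply(seq_len(nrow(grid)), function(i) {
    b <- grid[i, ]
    sum(m[b$x0:(b$x0 + spec$l1 - 1L),
          b$y0:(b$y0 + spec$l2 - 1L),
          b$z0:(b$z0 + spec$l3 - 1L)]) / spec$D
  }, numeric(1))
  grid$l1 <- spec$l1; grid$l2 <- spec$l2; grid$l3 <- spec$l3
  grid$retained <- grid$overlap >= min_overlap
  ord <- c("hemisphere", "x0", "y0", "z0", "l1", "l2", "l3", "overlap", "retained")
  grid <- grid[, ord]
  n_hemi <- table(factor(grid$hemisphere, c("L", "R")))
  idx <- unlist(lapply(c("L", "R"), function(s) seq_len(n_hemi[[s]])))
  grid$node_id <- sprintf("%s%03d", grid$hemisphere, idx)
  grid <- grid[, c("node_id", ord)]
  rownames(grid) <- NULL
  N <- sum(grid$retained)
  if (N == 0L) warning("no box reaches min_overlap; grid has zero nodes")
  structure(grid, class = c("patch_grid", "data.frame"),
            shape = shape, spec = spec, min_overlap = min_overlap, N = N)
}

#' @export
print.patch_grid <- function(x, ...) {
  sp <- attr(x, "spec")
  cat(sprintf("patch_grid: %d retained of %d candidate %dx%dx%d boxes on a %s grid (min_overlap %g)\n",
              attr(x, "N"), nrow(x), sp$l1, sp$l2, sp$l3,
              paste(attr(x, "shape"), collapse = "x"), attr(x, "min_overlap")))
  invisible(x)
}

#' Number of retained patches of a grid
#' @param grid A `patch_grid`.
#' @return Integer count of retained boxes (the node count N).
#' @export
n_nodes <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  attr(grid, "N")
}

#' Retained boxes of a grid
#' @param grid A `patch_grid`.
#' @return The rows of `grid` with `retained == TRUE`, in node order.
#' @export
retained_boxes <- function(grid) {
  stopifnot(inherits(grid, "patch_grid"))
  grid[grid$retained, , drop = FALSE]
}

#' Extract one patch vector
#'
#' Reads the `D` voxel intensities of a box in a fixed raster order shared
#' by every patch and every subject: x slowest, then y, z fastest. Boxes in
#' the right hemisphere are read in the same order (no mirroring).
#'
#' @param volume 3D numeric array.
#' @param box A single-row data frame (or list) with `x0`, `y0`, `z0`,
#'   `l1`, `l2`, `l3` (1-based origins).
#' @return Numeric vector of length `D`.
#' @export
extract_patch_vector <- function(volume, box) {
  x1 <- box$x0 + box$l1 - 1L; y1 <- box$y0 + box$l2 - 1L; z1 <- box$z0 + box$l3 - 1L
  d <- dim(volume)
  if (box$x0 < 1L || box$y0 < 1L || box$z0 < 1L || x1 > d[1L] || y1 > d[2L] || z1 > d[3L])
    stop("box out of volume bounds")
  sub <- volume[box$x0:x1, box$y0:y1, box$z0:z1, drop = FALSE]
  as.vector(aperm(sub, c(3L, 2L, 1L)))
}

#' Patch matrix of one subject
#'
#' Stacks the patch vectors of all retained boxes into a `D x N` matrix,
#' one column per node in grid order; the unit consumed by the correlation
#' layer.
#'
#' @param volume 3D numeric array on the grid's image shape.
#' @param grid A `patch_grid`.
#' @return `D x N` numeric matrix with node ids as column names.
#' @export
patch_matrix <- function(volume, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  if (!identical(as.integer(dim(volume)), attr(grid, "shape")))
    stop("volume shape does not match grid shape")
  rb <- retained_boxes(grid)
  if (nrow(rb) == 0L) stop("grid has no retained boxes")
  out <- vapply(seq_len(nrow(rb)), function(i) extract_patch_vector(volume, rb[i, ]),
                numeric(attr(grid, "spec")$D))
  colnames(out) <- rb$node_id
  out
}

#' Write a patch grid as TSV
#' @param grid A `patch_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patch_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
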