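#' Cartesian grid specification
#'
#' Describes the regular grid on which level sets, velocity frames and
#' concentration volumes live. Voxel centers define the sample positions:
#' the grid is 0-based and `origin` is the world coordinate (mm) of the
#' center of voxel (0, 0, 0).
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 2).
#' @param spacing voxel edge length in mm; scalar (isotropic) or length 3.
#' @param origin world coordinates (mm) of the first voxel center.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(shape, spacing = 1, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L))
    stop("`shape` must be three integers, all >= 2")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("all spacings must be > 0")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

# upper voxel-center corner of the grid (mm)
grid_upper <- function(grid) grid$origin + (grid$shape - 1L) * grid$spacing

# world coordinates (mm) of all voxel centers, as an (nx*ny*nz) x 3 matrix
# in column-major (R array) order
grid_centers <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3]
  cbind(rep(xs, times = grid$shape[2] * grid$shape[3]),
        rep(rep(ys, each = grid$shape[1]), times = grid$shape[3]),
        rep(zs, each = grid$shape[1] * grid$shape[2]))
}

# nearest voxel (1-based triple index as linear index) for points (mm),
# clamped into the grid
grid_nearest_voxel <- function(grid, pts) {
  pts <- as_points(pts)
  idx <- matrix(0L, nrow(pts), 3L)
  for (a in 1:3) {
    v <- round((pts[, a] - grid$origin[a]) / grid$spacing[a])
    idx[, a] <- as.integer(pmin(pmax(v, 0), grid$shape[a] - 1L))
  }
  1L + idx[, 1] + grid$shape[1] * (idx[, 2] + grid$shape[2] * idx[, 3])
}

# coerce a length-3 vector or n x 3 matrix to an n x 3 matrix
as_points <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("points must have 3 columns")
    x
  } else {
    if (length(x) != 3L) stop("a point must have 3 coordinates")
    matrix(as.numeric(x), 1L, 3L)
  }
}

# trilinear interpolation of a scalar volume at arbitrary points
interp_trilinear <- function(values, grid, pts, outside_zero = FALSE) {
  cpp_trilinear(as.numeric(values), grid$shape, grid$spacing, grid$origin,
                as_points(pts), outside_zero)
}
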