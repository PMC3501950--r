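#' Level-set vessel geometry
#'
#' A scalar field phi sampled on a Cartesian grid with the convention
#' phi > 0 strictly inside the lumen and phi < 0 outside (approximately a
#' signed distance in mm), together with inlet/outlet disk annotations.
#'
#' @param grid a [grid_spec()].
#' @param phi numeric array with `dim == grid$shape`, mm.
#' @param inlet inlet disk: `list(center, normal, radius)` with `center` in
#'   mm, `normal` a unit vector pointing into the lumen, `radius` in mm.
#' @param outlets list of outlet disks in the same format.
#' @param meta optional list of analytic parameters kept by the phantom
#'   constructors (used by [analytic_tube_field()]).
#' @return An object of class `levelset_geometry`.
#' @seealso [make_tube_levelset()], [make_aneurysm_levelset()]
#' @export
levelset_geometry <- function(grid, phi, inlet = NULL, outlets = list(),
                              meta = list()) {
  stopifnot(inherits(grid, "grid_spec"))
  phi <- array(as.numeric(phi), dim = grid$shape)
  structure(list(grid = grid, phi = phi, inlet = inlet, outlets = outlets,
                 meta = meta, cache = new.env(parent = emptyenv())),
            class = "levelset_geometry")
}

#' @export
print.levelset_geometry <- function(x, ...) {
  cat("<levelset_geometry> ", sum(x$phi > 0), " inside voxels on ",
      paste(x$grid$shape, collapse = "x"), " grid",
      if (!is.null(x$meta$kind)) paste0(" (", x$meta$kind, " phantom)"),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate the level set at arbitrary points
#'
#' Trilinear interpolation of phi at world coordinates (mm). Points beyond
#' the voxel-center bounding box are treated as outside: the clamped value
#' minus the distance to the box is returned, so phi decreases smoothly
#' away from the grid.
#'
#' @param geom a [levelset_geometry()].
#' @param pts length-3 vector or n x 3 matrix of points, mm.
#' @return Numeric vector of phi values, mm.
#' @export
phi_eval <- function(geom, pts) {
  pts <- as_points(pts)
  g <- geom$grid
  lo <- matrix(g$origin, nrow(pts), 3L, byrow = TRUE)
  hi <- matrix(grid_upper(g), nrow(pts), 3L, byrow = TRUE)
  clamped <- pmin(pmax(pts, lo), hi)
  v <- interp_trilinear(geom$phi, g, clamped)
  excess <- sqrt(rowSums((pts - clamped)^2))
  v - excess
}

# numerical gradient of phi_eval by central differences with step h
# (defaults to half the smallest spacing); valid outside the grid box too
phi_gradient <- function(geom, pts, h = min(geom$grid$spacing) / 2) {
  pts <- as_points(pts)
  g <- matrix(0, nrow(pts), 3L)
  for (a in 1:3) {
    dp <- pts; dp[, a] <- dp[, a] + h
    dm <- pts; dm[, a] <- dm[, a] - h
    g[, a] <- (phi_eval(geom, dp) - phi_eval(geom, dm)) / (2 * h)
  }
  g
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

# orthonormal basis perpendicular to a unit vector
perp_basis <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(pracma_cross(n, ref))
  e2 <- pracma_cross(n, e1)
  list(e1 = e1, e2 = e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Capped-cylinder tube phantom
#'
#' Builds a straight-tube lumen as a level set: phi is the minimum of the
#' radial distance to the wall and the axial distance to the end caps, so
#' the tube is a finite capped cylinder centered in the grid (it must fit
#' with a margin of at least 2 voxels). Inlet and outlet disks are placed
#' just inside the two end caps.
#'
#' @param radius tube radius, mm (>= 3 voxel spacings).
#' @param length tube length, mm.
#' @param axis tube axis direction (normalized internally).
#' @param grid a [grid_spec()].
#' @param center tube center, mm; defaults to the grid center.
#' @return A `levelset_geometry` whose `meta` records the analytic tube
#'   parameters.
#' @export
make_tube_levelset <- function(radius, length, axis = c(0, 0, 1), grid,
                               center = NULL) {
  axis <- unit3(axis)
  if (radius < 3 * min(grid$spacing))
    stop("tube radius must be at least 3 voxel spacings")
  if (is.null(center)) center <- (grid$origin + grid_upper(grid)) / 2
  half <- length / 2
  ends <- rbind(center - half * axis, center + half * axis)
  margin <- 2 * grid$spacing
  lo <- grid$origin + margin
  hi <- grid_upper(grid) - margin
  box_r <- radius * sqrt(1 - axis^2)  # tube extent perpendicular to axis
  if (any(sweep(ends, 2, box_r, "-") < matrix(lo, 2, 3, byrow = TRUE)) ||
      any(sweep(ends, 2, box_r, "+") > matrix(hi, 2, 3, byrow = TRUE)))
    stop("tube exceeds grid bounds (needs a 2-voxel margin)")
  pts <- grid_centers(grid)
  phi <- tube_phi(pts, center, axis, radius, half)
  off <- 2 * max(grid$spacing)
  inlet <- list(center = center - (half - off) * axis, normal = axis,
                radius = 0.85 * radius)
  outlet <- list(center = center + (half - off) * axis, normal = -axis,
                 radius = 0.85 * radius)
  levelset_geometry(grid, phi, inlet = inlet, outlets = list(outlet),
                    meta = list(kind = "tube", center = center, axis = axis,
                                radius = radius, half_length = half))
}

tube_phi <- function(pts, center, axis, radius, half) {
  rel <- sweep(as_points(pts), 2, center)
  s <- rel %*% axis
  r2 <- rowSums(rel^2) - s^2
  r2[r2 < 0] <- 0
  pmin(radius - sqrt(r2), half - abs(s))
}

#' Tube-plus-sac aneurysm phantom
#'
#' Adds a spherical aneurysm sac to a tube phantom by the level-set union
#' `phi = max(phi_tube, sac_radius - |x - sac_center|)`. The sac must
#' overlap the tube lumen so that the fluid region stays connected.
#'
#' @inheritParams make_tube_levelset
#' @param sac_center sphere center, mm.
#' @param sac_radius sphere radius, mm.
#' @return A `levelset_geometry`; `meta` records tube and sac parameters.
#' @export
make_aneurysm_levelset <- function(radius, length, axis = c(0, 0, 1), grid,
                                   sac_center, sac_radius, center = NULL) {
  tube <- make_tube_levelset(radius, length, axis, grid, center)
  m <- tube$meta
  if (tube_phi(sac_center, m$center, m$axis, m$radius, m$half_length) +
      sac_radius <= 0)
    stop("sac does not overlap the tube lumen: geometry would be disconnected")
  hi <- grid_upper(grid) - 2 * grid$spacing
  lo <- grid$origin + 2 * grid$spacing
  if (any(sac_center - sac_radius < lo) || any(sac_center + sac_radius > hi))
    stop("sac exceeds grid bounds (needs a 2-voxel margin)")
  pts <- grid_centers(grid)
  phi_sac <- sac_radius - sqrt(rowSums(sweep(pts, 2, sac_center)^2))
  phi <- pmax(as.numeric(tube$phi), phi_sac)
  levelset_geometry(grid, phi, inlet = tube$inlet, outlets = tube$outlets,
                    meta = c(m[setdiff(names(m), "kind")],
                             list(kind = "aneurysm", sac_center = sac_center,
                                  sac_radius = sac_radius)))
}

#' Convert a binary lumen mask to a signed-distance level set
#'
#' Voxels where `mask` is TRUE are inside. The returned phi is the
#' Euclidean distance to the nearest voxel on the other side, offset by
#' half a voxel so the zero crossing sits between inside and outside
#' voxels; positive inside, negative outside.
#'
#' @param mask logical array.
#' @param grid a [grid_spec()] matching `dim(mask)`.
#' @inheritParams levelset_geometry
#' @return A `levelset_geometry`.
#' @export
mask_to_levelset <- function(mask, grid, inlet = NULL, outlets = list()) {
  stopifnot(all(dim(mask) == grid$shape))
  if (!any(mask)) stop("mask has no inside voxel")
  ctr <- grid_centers(grid)
  hs <- min(grid$spacing) / 2
  phi <- numeric(length(mask))
  near_out <- cpp_nearest_inside_map(!as.logical(mask), grid$shape,
                                     grid$spacing)
  d_out <- sqrt(rowSums((ctr - ctr[as.integer(near_out), , drop = FALSE])^2))
  near_in <- cpp_nearest_inside_map(as.logical(mask), grid$shape, grid$spacing)
  d_in <- sqrt(rowSums((ctr - ctr[as.integer(near_in), , drop = FALSE])^2))
  phi[mask] <- d_out[mask] - hs
  phi[!mask] <- -(d_in[!mask] - hs)
  levelset_geometry(grid, phi, inlet = inlet, outlets = outlets,
                    meta = list(kind = "mask"))
}

# cached nearest-inside-voxel map (1-based linear indices); inside means
# phi >= 0. Used for boundary extension and as reflection fallback.
geometry_nearest_map <- function(geom) {
  if (is.null(geom$cache$nearest_map)) {
    inside <- as.logical(geom$phi >= 0)
    if (!any(inside)) stop("geometry has no inside voxel")
    geom$cache$nearest_map <-
      as.integer(cpp_nearest_inside_map(inside, geom$grid$shape,
                                        geom$grid$spacing))
  }
  geom$cache$nearest_map
}
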