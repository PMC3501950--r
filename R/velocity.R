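#' Time-varying velocity field
#'
#' A velocity field evaluable at arbitrary (t, x): `eval(t, pts)` takes a
#' scalar time (s) and an n x 3 matrix of world points (mm) and returns an
#' n x 3 matrix of velocities in mm/s. `max_speed` (mm/s) backs the CFL
#' time-step check of the transport loop.
#'
#' @param eval function `(t, pts) -> n x 3 matrix`, mm/s.
#' @param max_speed upper bound on the field speed, mm/s.
#' @param period cardiac period for periodic fields, s, or NULL.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(eval, max_speed, period = NULL) {
  stopifnot(is.function(eval), max_speed >= 0)
  structure(list(eval = eval, max_speed = max_speed, period = period),
            class = "velocity_field")
}

#' Evaluate a velocity field
#'
#' @param field a [velocity_field()].
#' @param t time, s (scalar).
#' @param pts length-3 vector or n x 3 matrix of points, mm.
#' @return n x 3 matrix of velocities, mm/s.
#' @export
field_eval <- function(field, t, pts) {
  if (!is.finite(t)) stop("time must be finite")
  field$eval(t, as_points(pts))
}

#' Analytic pulsatile field on a phantom geometry
#'
#' Inside the tube lumen the velocity is axial with magnitude from the
#' inflow waveform: a plug profile `w(t)` or a Poiseuille profile
#' `2 w(t) (1 - (r/R)^2)` whose cross-section average equals `w(t)`.
#' Inside an aneurysm sac (outside the tube) an optional rigid rotation
#' about the sac center models recirculation. Outside the lumen the field
#' is zero and the query is flagged in the `"outside"` attribute.
#' Waveform velocities (m/s) are converted to mm/s here, at field
#' construction, the package's single unit-conversion point.
#'
#' @param geom a phantom [levelset_geometry()] built by
#'   [make_tube_levelset()] or [make_aneurysm_levelset()].
#' @param w an [inflow_waveform()], m/s.
#' @param profile `"plug"` or `"poiseuille"`.
#' @param sac_spin optional angular-velocity vector, rad/s, for rigid
#'   rotation inside the sac.
#' @return A [velocity_field()] (periodic with the waveform's period).
#' @export
analytic_tube_field <- function(geom, w, profile = c("plug", "poiseuille"),
                                sac_spin = NULL) {
  profile <- match.arg(profile)
  m <- geom$meta
  if (is.null(m$axis))
    stop("`geom` must be built by the phantom constructors")
  axis <- m$axis; center <- m$center; R <- m$radius; half <- m$half_length
  has_sac <- identical(m$kind, "aneurysm")
  sacc <- m$sac_center; sacr <- m$sac_radius
  peak <- if (profile == "poiseuille") 2 else 1
  max_speed <- 1000 * max(w$samples) * peak
  if (has_sac && !is.null(sac_spin))
    max_speed <- max(max_speed, sqrt(sum(sac_spin^2)) * sacr)
  evalf <- function(t, pts) {
    rel <- sweep(pts, 2, center)
    s <- as.numeric(rel %*% axis)
    r2 <- rowSums(rel^2) - s^2
    r2[r2 < 0] <- 0
    in_tube <- sqrt(r2) <= R & abs(s) <= half
    v <- matrix(0, nrow(pts), 3L)
    if (any(in_tube)) {
      mag <- 1000 * waveform_eval(w, t)
      mag <- if (profile == "plug") rep(mag, sum(in_tube))
             else 2 * mag * (1 - r2[in_tube] / R^2)
      v[in_tube, ] <- outer(mag, axis)
    }
    outside <- !in_tube
    if (has_sac) {
      drel <- sweep(pts, 2, sacc)
      in_sac <- rowSums(drel^2) <= sacr^2 & !in_tube
      if (!is.null(sac_spin) && any(in_sac)) {
        d <- drel[in_sac, , drop = FALSE]
        v[in_sac, ] <- cbind(sac_spin[2] * d[, 3] - sac_spin[3] * d[, 2],
                             sac_spin[3] * d[, 1] - sac_spin[1] * d[, 3],
                             sac_spin[1] * d[, 2] - sac_spin[2] * d[, 1])
      }
      outside <- outside & !in_sac
    }
    attr(v, "outside") <- outside
    v
  }
  velocity_field(evalf, max_speed = max_speed, period = w$period)
}

#' Gridded periodic velocity field
#'
#' Wraps one cardiac cycle of vector volumes (the interface to an external
#' CFD solver): trilinear interpolation in space and linear-periodic
#' interpolation in cycle phase, exact at frame nodes.
#'
#' @param frames list of 4D arrays `c(grid$shape, 3)`, mm/s, one per cycle
#'   phase.
#' @param phases cycle phases of the frames, s, ascending in `[0, period)`.
#' @param period cardiac period, s.
#' @param grid the [grid_spec()] the frames live on.
#' @return A [velocity_field()].
#' @export
gridded_velocity_field <- function(frames, phases, period, grid) {
  stopifnot(length(frames) == length(phases), length(frames) >= 1,
            period > 0, !is.unsorted(phases), all(phases >= 0),
            all(phases < period))
  comps <- lapply(frames, function(f) {
    stopifnot(all(dim(f) == c(grid$shape, 3L)))
    lapply(1:3, function(a) as.numeric(f[, , , a]))
  })
  max_speed <- max(vapply(frames, function(f) {
    sqrt(max(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2))
  }, numeric(1)))
  nf <- length(frames)
  lo <- grid$origin; hi <- grid_upper(grid)
  evalf <- function(t, pts) {
    if (!is.finite(t)) stop("time must be finite")
    if (any(sweep(pts, 2, lo) < -1e-9) || any(sweep(pts, 2, hi) > 1e-9))
      stop("interpolation error: point outside grid bounds")
    ph <- t %% period
    i1 <- findInterval(ph, phases)        # frame at or before ph
    if (i1 == 0L) i1 <- nf                # before first phase: wrap back
    i2 <- if (i1 == nf) 1L else i1 + 1L
    p1 <- phases[i1]
    gap <- (phases[min(i2, nf)] - p1) %% period
    if (i1 == nf) gap <- (phases[1] + period - p1) %% period
    if (gap <= 0) gap <- period
    f <- ((ph - p1) %% period) / gap
    v <- matrix(0, nrow(pts), 3L)
    for (a in 1:3) {
      v1 <- interp_trilinear(comps[[i1]][[a]], grid, pts)
      v2 <- if (nf == 1L) v1 else interp_trilinear(comps[[i2]][[a]], grid, pts)
      v[, a] <- v1 * (1 - f) + v2 * f
    }
    v
  }
  velocity_field(evalf, max_speed = max_speed, period = period)
}

#' Evaluate a gridded velocity field once
#'
#' Convenience wrapper: builds the periodic interpolant and evaluates it.
#'
#' @inheritParams gridded_velocity_field
#' @param t time, s.
#' @param x length-3 vector or n x 3 matrix of points, mm.
#' @return n x 3 matrix of velocities, mm/s.
#' @export
eval_gridded_field <- function(frames, phases, period, grid, t, x) {
  field_eval(gridded_velocity_field(frames, phases, period, grid), t, x)
}
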