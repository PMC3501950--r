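#' Set of massless contrast particles
#'
#' Particle positions in mm. Particles are mass- and dimensionless and do
#' not interact; the active count never decreases during a simulation
#' (particles bounce off walls instead of leaving).
#'
#' @param pos n x 3 matrix of positions, mm (0 rows allowed).
#' @return An object of class `particle_set`.
#' @export
particle_set <- function(pos = matrix(numeric(0), 0, 3)) {
  pos <- if (is.matrix(pos)) pos else as_points(pos)
  stopifnot(ncol(pos) == 3L)
  structure(list(pos = pos, n = nrow(pos)), class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat("<particle_set> ", x$n, " particles\n", sep = "")
  invisible(x)
}

#' Transport configuration
#'
#' Numerical parameters of the contrast-transport loop.
#'
#' @param dt time step, s; must satisfy the CFL bound
#'   `dt <= min(spacing) / max_speed` for the velocity field used.
#' @param D diffusivity coefficient of the gradient-drift diffusion model
#'   (dimensionless model coefficient; the drift is `-D * grad C`).
#' @param sigma smoothing parameter: the particle-smoothing Gaussian has
#'   covariance `sigma * I3` in voxel^2 units.
#' @param n_total total number of particles to inject.
#' @param seed random-generator seed (injection positions).
#' @param frame_rate output frame rate for concentration snapshots, fps.
#' @param trunc_sd truncation radius of the smoothing kernel, in standard
#'   deviations per axis.
#' @return An object of class `transport_config`.
#' @export
transport_config <- function(dt, D = 0.1, sigma = 1, n_total, seed = 1L,
                             frame_rate = 30, trunc_sd = 4) {
  stopifnot(dt > 0, sigma > 0, n_total >= 1, frame_rate > 0, trunc_sd > 0,
            D >= 0)
  structure(list(dt = dt, D = D, sigma = sigma,
                 n_total = as.integer(n_total), seed = as.integer(seed),
                 frame_rate = frame_rate, trunc_sd = trunc_sd),
            class = "transport_config")
}

#' Concentration volume
#'
#' Scalar contrast-agent concentration (particles per mm^3) on a grid.
#'
#' @param grid a [grid_spec()].
#' @param values numeric array with `dim == grid$shape`.
#' @return An object of class `concentration_volume`.
#' @export
concentration_volume <- function(grid, values) {
  values <- array(as.numeric(values), dim = grid$shape)
  structure(list(grid = grid, values = values),
            class = "concentration_volume")
}

#' Advance particles by one RK4 step
#'
#' Classical explicit fourth-order Runge-Kutta integration of
#' `d rho / dt = f(t, rho)` with stage weights (k1 + 2 k2 + 2 k3 + k4)/6
#' and stages evaluated at t, t + dt/2, t + dt/2 and t + dt.
#'
#' @param particles a [particle_set()].
#' @param field a [velocity_field()].
#' @param t step start time, s.
#' @param dt step size, s.
#' @return The advected [particle_set()].
#' @export
advect_rk4 <- function(particles, field, t, dt) {
  p <- particles$pos
  if (nrow(p) == 0L) return(particles)
  k1 <- dt * field_eval(field, t, p)
  k2 <- dt * field_eval(field, t + dt / 2, p + k1 / 2)
  k3 <- dt * field_eval(field, t + dt / 2, p + k2 / 2)
  k4 <- dt * field_eval(field, t + dt, p + k3)
  new <- p + (k1 + 2 * k2 + 2 * k3 + k4) / 6
  bad <- which(!is.finite(rowSums(new)))
  if (length(bad))
    stop("transport error: velocity evaluation failed for particle ", bad[1])
  particle_set(new)
}

#' Reflect positions back into the vessel
#'
#' Positions with phi >= 0 are returned unchanged. Outside positions are
#' mirrored across the zero level set, `x - 2 phi(x) grad phi / |grad phi|`,
#' re-applied up to 5 times; anything still outside (or with a degenerate
#' gradient) is clamped to the center of the nearest inside voxel.
#'
#' @param position length-3 vector or n x 3 matrix, mm.
#' @param geom a [levelset_geometry()].
#' @return Positions of the same shape as the input, all with phi >= 0
#'   (up to interpolation error at the wall).
#' @export
reflect_into_vessel <- function(position, geom) {
  single <- !is.matrix(position)
  pos <- as_points(position)
  out <- which(phi_eval(geom, pos) < 0)
  if (length(out)) {
    sub <- pos[out, , drop = FALSE]
    for (iter in 1:5) {
      phi <- phi_eval(geom, sub)
      open <- which(phi < 0)
      if (!length(open)) break
      g <- phi_gradient(geom, sub[open, , drop = FALSE])
      gn <- sqrt(rowSums(g^2))
      ok <- gn >= 1e-6
      if (any(ok)) {
        i <- open[ok]
        sub[i, ] <- sub[i, , drop = FALSE] -
          (2 * phi[open][ok] / gn[ok]) * g[ok, , drop = FALSE]
      }
      if (any(!ok)) {  # degenerate gradient: clamp immediately
        i <- open[!ok]
        sub[i, ] <- nearest_inside_center(geom, sub[i, , drop = FALSE])
      }
    }
    still <- which(phi_eval(geom, sub) < 0)
    if (length(still))
      sub[still, ] <- nearest_inside_center(geom, sub[still, , drop = FALSE])
    pos[out, ] <- sub
  }
  if (single) pos[1, ] else pos
}

nearest_inside_center <- function(geom, pts) {
  map <- geometry_nearest_map(geom)
  vox <- grid_nearest_voxel(geom$grid, pts)
  grid_centers(geom$grid)[map[vox], , drop = FALSE]
}

#' Smooth particles to a concentration volume
#'
#' Each particle deposits an isotropic Gaussian (covariance `sigma * I3`
#' in voxel^2 units) centered at its exact off-grid position, truncated at
#' `trunc_sd` standard deviations per axis. The result is the mixture
#' density sampled at the voxel centers of `grid`, in particles per mm^3,
#' so the grid integral approximates the particle count.
#'
#' @param particles a [particle_set()].
#' @param sigma smoothing parameter, voxel^2.
#' @param grid a [grid_spec()] (normally the velocity field's grid).
#' @param trunc_sd kernel truncation radius in standard deviations.
#' @return A [concentration_volume()].
#' @export
smooth_particles <- function(particles, sigma, grid, trunc_sd = 4) {
  stopifnot(sigma > 0)
  vals <- cpp_deposit_gaussian(particles$pos, sigma, trunc_sd, grid$shape,
                               grid$spacing, grid$origin)
  concentration_volume(grid, vals)
}

#' Extend concentration values over the vessel boundary
#'
#' Every voxel with phi < 0 receives the value of its nearest (Euclidean)
#' phi >= 0 voxel; inside voxels are unchanged. This zeroes the
#' concentration gradient across the wall so the diffusion drift does not
#' push particles into the boundary.
#'
#' @param conc a [concentration_volume()].
#' @param geom a [levelset_geometry()] on the same grid.
#' @return A [concentration_volume()].
#' @export
extend_over_boundary <- function(conc, geom) {
  stopifnot(all(conc$grid$shape == geom$grid$shape))
  map <- geometry_nearest_map(geom)
  concentration_volume(conc$grid, conc$values[map])
}

#' Gradient-drift diffusion step
#'
#' Implements the diffusive movement as a drift velocity
#' `v_Diff = -D * grad C` (Fick's-law direction): the gradient of the
#' boundary-extended concentration is taken by second-order central
#' differences (one-sided at grid faces, per mm), trilinearly interpolated
#' at each particle, and the particles are moved by `v_Diff * dt` and
#' reflected back into the vessel.
#'
#' @param particles a [particle_set()].
#' @param conc_extended a boundary-extended [concentration_volume()].
#' @param D diffusivity coefficient (model units).
#' @param dt time step, s.
#' @param geom the [levelset_geometry()].
#' @return The moved [particle_set()].
#' @export
diffusion_step <- function(particles, conc_extended, D, dt, geom) {
  if (particles$n == 0L || D == 0) return(particles)
  g <- conc_extended$grid
  grad <- cpp_gradient_interp(as.numeric(conc_extended$values), g$shape,
                              g$spacing, g$origin, particles$pos)
  particle_set(reflect_into_vessel(particles$pos - D * grad * dt, geom))
}

#' Injection schedule by largest-remainder apportionment
#'
#' Distributes `n_total` particles over the simulation steps proportionally
#' to a non-negative bolus profile, using largest-remainder rounding (ties
#' to the earlier step) so the counts sum to `n_total` exactly.
#'
#' @param profile non-negative per-step injection weights (one per
#'   simulated step); see [sample_bolus()].
#' @param n_total total particle count.
#' @return An object of class `injection_schedule` with integer `counts`.
#' @export
build_injection_schedule <- function(profile, n_total) {
  profile <- as.numeric(profile)
  if (any(profile < 0)) stop("profile values must be >= 0")
  s <- sum(profile)
  if (s <= 0) stop("profile must not be all zero")
  q <- profile / s * n_total
  counts <- floor(q)
  rem <- as.integer(round(n_total - sum(counts)))
  if (rem > 0) {
    frac <- q - counts
    top <- order(-frac, seq_along(frac))[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  structure(list(counts = as.integer(counts), n_total = as.integer(n_total)),
            class = "injection_schedule")
}

# uniform random positions on the inlet disk (area-uniform), pushed a tiny
# step along the inward normal is not needed since the disk lies inside
inject_particles <- function(inlet, k) {
  if (k == 0L) return(matrix(numeric(0), 0, 3))
  b <- perp_basis(unit3(inlet$normal))
  r <- inlet$radius * sqrt(runif(k))
  th <- runif(k, 0, 2 * pi)
  sweep(outer(r * cos(th), b$e1) + outer(r * sin(th), b$e2), 2,
        inlet$center, "+")
}

#' Simulate contrast transport
#'
#' Runs the transport loop: at every step the scheduled particles are
#' injected uniformly over the inlet disk, all particles are advected by
#' [advect_rk4()] and reflected at the wall, then (when `D > 0`) smoothed
#' to a concentration volume, boundary-extended, and moved by the
#' diffusion drift. Concentration snapshots (smoothed, not extended) are
#' emitted at the output frame times.
#'
#' @param geom a [levelset_geometry()] with an inlet disk.
#' @param field a [velocity_field()].
#' @param schedule an [build_injection_schedule()] result; its length sets
#'   the number of simulated steps.
#' @param config a [transport_config()].
#' @param keep_particles if TRUE, the particle positions at each frame time
#'   are kept (for path/streak visualization dumps).
#' @return An object of class `transport_result`: list with `snapshots`
#'   (list of [concentration_volume()]), `times` (s), `frame_rate`,
#'   `particles` (final [particle_set()]), `active_counts` (per step) and
#'   `config`.
#' @export
simulate_transport <- function(geom, field, schedule, config,
                               keep_particles = FALSE) {
  stopifnot(inherits(schedule, "injection_schedule"),
            inherits(config, "transport_config"))
  if (is.null(geom$inlet)) stop("geometry has no inlet disk")
  cfl <- min(geom$grid$spacing) / max(field$max_speed, 1e-12)
  if (config$dt > cfl * (1 + 1e-9))
    stop(sprintf("CFL violation: dt = %g s exceeds spacing/max_speed = %g s",
                 config$dt, cfl))
  n_steps <- length(schedule$counts)
  dt <- config$dt
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  frame_dt <- 1 / config$frame_rate
  next_frame <- frame_dt
  pos <- matrix(numeric(0), 0, 3)
  snapshots <- list(); times <- numeric(0); pdumps <- list()
  active <- integer(n_steps)
  geometry_nearest_map(geom)  # warm the cache before the loop
  for (i in seq_len(n_steps)) {
    t0 <- (i - 1) * dt
    if (schedule$counts[i] > 0L)
      pos <- rbind(pos, inject_particles(geom$inlet, schedule$counts[i]))
    if (nrow(pos)) {
      ps <- advect_rk4(particle_set(pos), field, t0, dt)
      pos <- reflect_into_vessel(ps$pos, geom)
      if (config$D > 0) {
        conc <- smooth_particles(particle_set(pos), config$sigma, geom$grid,
                                 config$trunc_sd)
        ext <- extend_over_boundary(conc, geom)
        pos <- diffusion_step(particle_set(pos), ext, config$D, dt, geom)$pos
      }
    }
    active[i] <- nrow(pos)
    while (next_frame <= i * dt + 1e-12) {
      conc <- smooth_particles(particle_set(pos), config$sigma, geom$grid,
                               config$trunc_sd)
      snapshots[[length(snapshots) + 1L]] <- conc
      times <- c(times, next_frame)
      if (keep_particles) pdumps[[length(pdumps) + 1L]] <- pos
      next_frame <- next_frame + frame_dt
    }
  }
  structure(list(snapshots = snapshots, times = times,
                 frame_rate = config$frame_rate,
                 particles = particle_set(pos), active_counts = active,
                 particle_frames = if (keep_particles) pdumps,
                 config = config),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat("<transport_result> ", length(x$snapshots), " frames at ",
      x$frame_rate, " fps, ", x$particles$n, " particles\n", sep = "")
  invisible(x)
}
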