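# shared fixtures, all built in code

# rigid rotation about the z axis through the origin, omega in rad/s
rotation_field <- function(omega, max_radius = 20) {
  velocity_field(function(t, pts) {
    cbind(-omega * pts[, 2], omega * pts[, 1], 0)
  }, max_speed = abs(omega) * max_radius)
}

constant_field <- function(v) {
  velocity_field(function(t, pts) {
    matrix(v, nrow(pts), 3, byrow = TRUE)
  }, max_speed = sqrt(sum(v^2)))
}

zero_field <- function() constant_field(c(0, 0, 0))

# small tube phantom used across transport tests
small_tube <- function(shape = c(32, 32, 48), spacing = 0.5, radius = 3,
                       length = 18) {
  make_tube_levelset(radius, length, c(0, 0, 1),
                     grid_spec(shape, spacing))
}

# planar-wall geometry: phi = x - x_wall (inside where x > x_wall)
plane_geometry <- function(x_wall = 8, shape = c(32, 16, 16), spacing = 1) {
  grid <- grid_spec(shape, spacing)
  xs <- grid$origin[1] + (seq_len(shape[1]) - 1) * spacing
  phi <- array(rep(xs - x_wall, times = shape[2] * shape[3]), dim = shape)
  levelset_geometry(grid, phi)
}

# independent R oracle: nearest inside voxel by chunked vectorized search;
# ties resolve to the lowest linear index (which.min)
nearest_inside_oracle <- function(inside, grid) {
  ctr <- virtangio:::grid_centers(grid)
  sites <- which(inside)
  out <- integer(length(inside))
  out[sites] <- sites
  outside <- which(!inside)
  sc <- ctr[sites, , drop = FALSE]
  for (chunk in split(outside, ceiling(seq_along(outside) / 512))) {
    d2 <- outer(ctr[chunk, 1], sc[, 1], "-")^2 +
      outer(ctr[chunk, 2], sc[, 2], "-")^2 +
      outer(ctr[chunk, 3], sc[, 3], "-")^2
    out[chunk] <- sites[apply(d2, 1, which.min)]
  }
  out
}

# 6-connected flood fill component count over a logical 3D array
flood_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  ncomp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      k <- (cur - 1) %/% (d[1] * d[2])
      r <- (cur - 1) %% (d[1] * d[2])
      j <- r %/% d[1]; i <- r %% d[1]
      for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
        ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[1] || jj >= d[2] ||
            kk >= d[3]) next
        nb <- 1L + ii + d[1] * (jj + d[2] * kk)
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- ncomp
          queue <- c(queue, nb)
        }
      }
    }
  }
  ncomp
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-12), tol)
}
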