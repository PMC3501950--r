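# level-set phantoms, inflow waveforms and velocity fields

test_that("tube level set matches the analytic capped cylinder", {
  grid <- grid_spec(c(49, 49, 49), 0.5)   # odd shape: center is a voxel center
  geom <- make_tube_levelset(5, 18, c(0, 0, 1), grid)
  ctr <- geom$meta$center
  expect_equal(phi_eval(geom, ctr), 5, tolerance = 1e-12)
  expect_equal(phi_eval(geom, ctr + c(5, 0, 0)), 0, tolerance = 1e-9)
  # voxel-counted volume vs analytic cylinder volume (grid not aligned with
  # the wall, so no voxel centers sit exactly on the zero crossing)
  g2 <- grid_spec(c(48, 48, 48), 0.5)
  t2 <- make_tube_levelset(5, 18, c(0, 0, 1), g2)
  vol <- sum(t2$phi > 0) * prod(g2$spacing)
  expect_rel_equal(vol, pi * 5^2 * 18, 0.02)
  # analytic inside/outside classification away from the surface
  set.seed(42)
  pts <- cbind(runif(1e4, 0.5, 23.5), runif(1e4, 0.5, 23.5),
               runif(1e4, 0.5, 23.5))
  phi_true <- virtangio:::tube_phi(pts, ctr, c(0, 0, 1), 5, 9)
  away <- abs(phi_true) > max(grid$spacing)   # beyond 1 voxel of the surface
  expect_equal(sum(sign(phi_eval(geom, pts[away, ])) !=
                     sign(phi_true[away])), 0)
  # near-unit gradient magnitude close to the zero crossing
  near <- which(abs(geom$phi) < 3 * 0.5 & abs(geom$phi) > 0.75)
  samp <- sample(near, 200)
  g <- virtangio:::phi_gradient(geom, virtangio:::grid_centers(grid)[samp, ])
  expect_true(all(sqrt(rowSums(g^2)) > 0.5 & sqrt(rowSums(g^2)) < 1.5))
})

test_that("tube outside the grid margin is rejected", {
  grid <- grid_spec(c(32, 32, 32), 0.5)
  expect_error(make_tube_levelset(5, 40, c(0, 0, 1), grid), "exceeds")
  expect_error(make_tube_levelset(1, 10, c(0, 0, 1), grid), "radius")
})

test_that("aneurysm level set is the absorbing union of tube and sac", {
  grid <- grid_spec(c(49, 49, 49), 0.5)
  sacc <- c(18, 12, 12)
  geom <- make_aneurysm_levelset(4, 16, c(0, 0, 1), grid,
                                 sac_center = sacc, sac_radius = 5)
  expect_equal(phi_eval(geom, sacc), 5, tolerance = 1e-9)
  # sac fully inside the tube leaves phi unchanged (max identity)
  tube <- make_tube_levelset(4, 16, c(0, 0, 1), grid)
  inner <- make_aneurysm_levelset(4, 16, c(0, 0, 1), grid,
                                  sac_center = tube$meta$center,
                                  sac_radius = 1.5)
  expect_equal(inner$phi, tube$phi)
  # the lumen is a single connected component (flood-fill oracle)
  expect_equal(flood_components(geom$phi > 0), 1L)
  # a detached sac is a geometry error
  expect_error(make_aneurysm_levelset(4, 16, c(0, 0, 1), grid,
                                      sac_center = c(21, 5, 12),
                                      sac_radius = 2),
               "disconnected")
})

test_that("mask-derived level set classifies inside and outside", {
  grid <- grid_spec(c(16, 16, 16), 1)
  tube <- make_tube_levelset(4, 10, c(0, 0, 1), grid)
  geom <- mask_to_levelset(tube$phi > 0, grid)
  expect_true(all(geom$phi[tube$phi > 0.6] > 0))
  expect_true(all(geom$phi[tube$phi < -0.6] < 0))
})

test_that("pulsatile waveform matches requested min, max and mean", {
  w <- make_pulsatile_waveform(0.31, 0.28, 0.37, 60 / 84)
  expect_rel_equal(min(w$samples), 0.28, 0.01)
  expect_rel_equal(max(w$samples), 0.37, 0.01)
  expect_rel_equal(mean(w$samples), 0.31, 0.01)
  expect_equal(w$period, 60 / 84)
  # degenerate pulsatility gives a constant waveform
  wc <- make_pulsatile_waveform(0.5, 0.5, 0.5, 1)
  expect_true(all(abs(wc$samples - 0.5) < 1e-12))
  expect_error(make_pulsatile_waveform(0.2, 0.3, 0.4, 1), "vmin")
  # time-average accuracy over random parameter triples (quadrature oracle)
  set.seed(7)
  for (i in 1:20) {
    v <- sort(runif(3, 0.1, 1))
    w <- make_pulsatile_waveform(v[2], v[1], v[3], 0.8)
    tq <- seq(0, 0.8, length.out = 4001)[-4001]
    expect_rel_equal(mean(waveform_eval(w, tq)), v[2], 0.01)
  }
})

test_that("waveform evaluation is periodic and phase shifting works", {
  w <- make_pulsatile_waveform(0.31, 0.28, 0.37, 0.7)
  t <- seq(0, 0.7, length.out = 101)
  expect_equal(waveform_eval(w, t), waveform_eval(w, t + 0.7),
               tolerance = 1e-12)
  expect_equal(shift_waveform_phase(w, 0)$samples, w$samples)
  expect_equal(shift_waveform_phase(w, 0.7)$samples, w$samples,
               tolerance = 1e-9)
  ws <- shift_waveform_phase(w, 0.35)
  expect_equal(ws$phase_of_min, (w$phase_of_min + 0.35) %% 0.7)
  expect_equal(waveform_eval(ws, t), waveform_eval(w, t - 0.35),
               tolerance = 1e-9)
  # min of the shifted waveform falls at phase_of_min
  tt <- seq(0, 0.7, length.out = 2048)[-2048]
  expect_lt(abs(tt[which.min(waveform_eval(ws, tt))] - ws$phase_of_min),
            0.7 / 512)
})

test_that("analytic tube field implements plug and poiseuille profiles", {
  geom <- small_tube()
  ctr <- geom$meta$center
  w <- make_pulsatile_waveform(0.31, 0.28, 0.37, 60 / 84)
  plug <- analytic_tube_field(geom, w, "plug")
  # on-axis speed is the waveform value, converted to mm/s
  for (t in c(0, 0.17, 0.44)) {
    v <- field_eval(plug, t, ctr)
    expect_equal(as.numeric(v), c(0, 0, 1000 * waveform_eval(w, t)),
                 tolerance = 1e-9)
  }
  poi <- analytic_tube_field(geom, w, "poiseuille")
  # no-slip at the wall
  expect_equal(as.numeric(field_eval(poi, 0.2, ctr + c(3, 0, 0))),
               c(0, 0, 0), tolerance = 1e-9)
  # cross-section average equals the waveform (quadrature oracle)
  rr <- seq(0.005, 2.995, by = 0.01)
  vz <- field_eval(poi, 0.3, cbind(ctr[1] + rr, ctr[2], ctr[3]))[, 3]
  avg <- sum(vz * 2 * pi * rr * 0.01) / (pi * 3^2)
  expect_rel_equal(avg, 1000 * waveform_eval(w, 0.3), 0.01)
  # outside queries return zero and are flagged
  v <- field_eval(plug, 0, rbind(ctr, ctr + c(10, 10, 0)))
  expect_equal(as.numeric(v[2, ]), c(0, 0, 0))
  expect_equal(as.logical(attr(v, "outside")), c(FALSE, TRUE))
  # periodicity to machine precision
  pts <- sweep(matrix(runif(30, -2, 2), 10, 3), 2, ctr, "+")
  expect_equal(field_eval(plug, 0.123, pts),
               field_eval(plug, 0.123 + w$period, pts), tolerance = 1e-12)
})

test_that("sac recirculation is a rigid rotation about the sac center", {
  grid <- grid_spec(c(48, 48, 48), 0.5)
  geom <- make_aneurysm_levelset(3, 16, c(0, 0, 1), grid,
                                 sac_center = grid$origin + 11.75 +
                                   c(5, 0, 0), sac_radius = 4)
  w <- make_pulsatile_waveform(0.3, 0.3, 0.3, 1)
  f <- analytic_tube_field(geom, w, "plug", sac_spin = c(0, 0, 2))
  p <- geom$meta$sac_center + c(2, 0, 0)
  expect_equal(as.numeric(field_eval(f, 0, p)), c(0, 4, 0),
               tolerance = 1e-9)
})

test_that("gridded field interpolation is exact at nodes and linear in time", {
  grid <- grid_spec(c(6, 5, 4), 2, origin = c(1, 1, 1))
  set.seed(3)
  f1 <- array(rnorm(prod(grid$shape) * 3), c(grid$shape, 3))
  f2 <- f1 + 0.5   # constant offset between the two frames
  fld <- gridded_velocity_field(list(f1, f2), phases = c(0, 0.4),
                                period = 0.8, grid = grid)
  # node / frame-time exactness
  expect_equal(as.numeric(field_eval(fld, 0, c(3, 5, 7))),
               as.numeric(f1[2, 3, 4, ]), tolerance = 1e-12)
  # midpoint between frames differing by a constant: the average
  expect_equal(as.numeric(field_eval(fld, 0.2, c(3, 5, 7))),
               as.numeric(f1[2, 3, 4, ] + 0.25), tolerance = 1e-12)
  # periodic wrap
  expect_equal(field_eval(fld, 0.1, c(4, 4, 4)),
               field_eval(fld, 0.9, c(4, 4, 4)), tolerance = 1e-12)
  # identical frames: time-independent
  fld2 <- gridded_velocity_field(list(f1, f1), c(0, 0.4), 0.8, grid)
  expect_equal(field_eval(fld2, 0.13, c(4, 4, 4)),
               field_eval(fld2, 0.57, c(4, 4, 4)), tolerance = 1e-12)
  # spatial interpolation between nodes is the mean of neighbors
  expect_equal(as.numeric(eval_gridded_field(list(f1, f2), c(0, 0.4), 0.8,
                                             grid, 0, c(4, 5, 7))),
               as.numeric((f1[2, 3, 4, ] + f1[3, 3, 4, ]) / 2),
               tolerance = 1e-12)
  expect_error(field_eval(fld, NA, c(3, 5, 7)), "finite")
  expect_error(field_eval(fld, 0, c(100, 5, 7)), "bounds")
})
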