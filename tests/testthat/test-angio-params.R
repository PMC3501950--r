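# TIC extraction, peak detection, heart rate/state, capacitor bolus model

make_const_seq <- function(value, nf = 40, size = 32, fps = 30) {
  image_sequence(array(value, c(size, size, nf)), fps)
}

test_that("TIC extraction integrates along LOIs and over ROIs", {
  seq1 <- make_const_seq(1)
  # 19-px segment is sampled at 20 unit-pixel steps
  tic <- extract_tic(seq1, loi_spec(rbind(c(2, 5), c(21, 5))))
  expect_true(all(tic$intensities == 20))
  expect_equal(tic$times, (0:39) / 30)
  # all-zero frames give an all-zero TIC
  tic0 <- extract_tic(make_const_seq(0), loi_spec(rbind(c(2, 5), c(21, 5))))
  expect_true(all(tic0$intensities == 0))
  # ROI mask sum
  mask <- matrix(FALSE, 32, 32); mask[10:12, 20:24] <- TRUE
  ticr <- extract_tic(seq1, roi_spec(mask))
  expect_true(all(ticr$intensities == 15))
  expect_error(extract_tic(seq1, loi_spec(rbind(c(2, 5), c(40, 5)))),
               "bounds")
})

test_that("TIC is proportional to the painted vessel intensity", {
  nf <- 120; fps <- 30
  t <- (0:(nf - 1)) / fps
  g <- capacitor_eval(bolus_params(0.5, 1.5, 0.2, 0.4, 7), t)
  frames <- array(0, c(16, 16, nf))
  for (i in seq_len(nf)) frames[5:12, 5:12, i] <- g[i]
  seq <- image_sequence(frames, fps)
  mask <- matrix(FALSE, 16, 16); mask[6:11, 6:11] <- TRUE
  tic <- extract_tic(seq, roi_spec(mask))
  expect_gt(cor(tic$intensities, g), 0.999)
})

test_that("peak detection finds cosine extrema at sub-frame precision", {
  fps <- 30
  t <- seq(0, 10, by = 1 / fps)
  tic <- tic_curve(t, cos(2 * pi * 1.4 * t))
  pk <- detect_peaks(tic)
  gaps <- diff(pk$times)
  expect_true(all(abs(gaps - 1 / 1.4) <= 0.5 / fps))
  # a monotone ramp has no peaks
  expect_length(detect_peaks(tic_curve(t, t))$times, 0)
})

test_that("pulsatile TIC at 84 bpm yields the right inter-peak spacing", {
  fps <- 30
  t <- seq(0, 10, by = 1 / fps)
  set.seed(31)
  y <- 10 * (1 + 0.3 * cos(2 * pi * 84 / 60 * t)) + rnorm(length(t), 0, 0.5)
  pk <- detect_peaks(tic_curve(t, y))
  expect_lt(abs(median(diff(pk$times)) - 60 / 84), 1 / fps)
})

test_that("heart period is the mean inter-peak interval", {
  expect_equal(estimate_heart_period(
    structure(list(times = c(1, 2, 3)), class = "peak_set")),
    list(period = 1, rate = 60))
  h <- estimate_heart_period(
    structure(list(times = c(0.5, 1.22, 1.93, 2.64)), class = "peak_set"))
  expect_equal(h$period, mean(diff(c(0.5, 1.22, 1.93, 2.64))))
  expect_equal(h$period, 0.71333, tolerance = 1e-4)
  expect_equal(h$rate, 84.1, tolerance = 1e-2)
  # telescoping mean: equally spaced peaks give the spacing exactly
  for (T in c(0.3, 0.71, 1.7)) {
    h <- estimate_heart_period(
      structure(list(times = T * (0:10)), class = "peak_set"))
    expect_equal(h$period, T)
  }
  expect_error(estimate_heart_period(
    structure(list(times = 1), class = "peak_set")), "insufficient")
})

test_that("heart-state synchronization aligns the velocity minimum", {
  w <- make_pulsatile_waveform(0.31, 0.28, 0.37, 0.714)
  # backward extrapolation of the earliest peak
  pk <- structure(list(times = 2.26), class = "peak_set")
  s <- synchronize_heart_state(pk, 0.714, w)
  expect_equal(s$t_star, 2.26 - 3 * 0.714, tolerance = 1e-12)
  expect_equal(s$waveform$phase_of_min, s$t_star, tolerance = 1e-9)
  # waveform minimum already at t*: zero shift (mod period)
  w0 <- shift_waveform_phase(w, 0.118 - w$phase_of_min)
  s0 <- synchronize_heart_state(structure(list(times = 0.118 + 2 * 0.714),
                                          class = "peak_set"), 0.714, w0)
  expect_lt(min(s0$shift %% 0.714, 0.714 - s0$shift %% 0.714), 1e-9)
  # randomized property: min of the synced waveform falls on t* mod period
  set.seed(12)
  for (i in 1:20) {
    T <- runif(1, 0.5, 1.2)
    wi <- make_pulsatile_waveform(0.3, 0.25, 0.4, T)
    p1 <- runif(1, 1, 6)
    si <- synchronize_heart_state(structure(list(times = p1),
                                            class = "peak_set"), T, wi)
    tt <- seq(0, T, length.out = 4096)[-4096]
    tmin <- tt[which.min(waveform_eval(si$waveform, tt))]
    dd <- abs(tmin - si$t_star %% T)
    expect_lt(min(dd, T - dd), 1 / 60)   # half a frame at 30 fps
  }
  # no peaks: unsynchronized signal, waveform passed through
  expect_warning(sn <- synchronize_heart_state(
    structure(list(times = numeric(0)), class = "peak_set"), 0.7, w),
    "unsynchronized")
  expect_false(sn$synchronized)
  expect_equal(sn$waveform$samples, w$samples)
})

test_that("capacitor curve follows the charge/discharge branches", {
  p <- bolus_params(1, 3, 0.2, 0.5, 10)
  expect_equal(capacitor_eval(p, 0.5), 0)
  # continuity at the plateau end
  expect_equal(capacitor_eval(p, 4 - 1e-9), capacitor_eval(p, 4 + 1e-9),
               tolerance = 1e-6)
  expect_equal(capacitor_eval(p, 4.5), 10 * (1 - exp(-15)) * exp(-1),
               tolerance = 1e-12)
  expect_equal(capacitor_eval(p, 4.5), 3.6788, tolerance = 1e-4)
  # continuity everywhere on a fine grid
  tt <- seq(0, 8, by = 1e-3)
  v <- capacitor_eval(p, tt)
  expect_true(all(abs(diff(v)) < 0.1))
  expect_true(all(v >= 0))
  expect_error(bolus_params(-1, 3, 0.2, 0.5, 10), "p1")
})

test_that("bolus fit recovers known parameters from noiseless samples", {
  t <- seq(0, 12, by = 1 / 30)
  truth <- bolus_params(1, 3, 0.2, 0.5, 10)
  fit <- fit_bolus_profile(tic_curve(t, capacitor_eval(truth, t)))
  expect_true(all(abs(fit$params - truth) / truth < 0.01))
  expect_lt(fit$residual, 1e-4)
})

test_that("bolus fit is robust to noise and pulsatile modulation", {
  t <- seq(0, 12, by = 1 / 30)
  truth <- bolus_params(1, 3, 0.2, 0.5, 10)
  clean <- capacitor_eval(truth, t)
  set.seed(77)
  errs <- replicate(10, {
    y <- clean + rnorm(length(t), 0, 10 / 20)   # SNR 20
    fit <- fit_bolus_profile(tic_curve(t, y))
    abs(as.numeric(fit$params) - as.numeric(truth)) / as.numeric(truth)
  })
  med <- apply(errs, 1, median)
  expect_lt(med[5], 0.05)                       # amplitude within 5%
  expect_lt(med[3], 0.15); expect_lt(med[4], 0.15)
  # pulsatile ripple is absent from the fitted model family
  yp <- clean * (1 - 0.2 * (1 - cos(2 * pi * 1.4 * t)) / 2)
  fit <- fit_bolus_profile(tic_curve(t, yp))
  smooth_fit <- capacitor_eval(fit$params, t)
  ripple <- diff(smooth_fit[t > fit$params[1] + 0.5 &
                              t < fit$params[1] + fit$params[2]])
  expect_true(all(ripple >= -1e-9))             # monotone plateau, no ripple
})

test_that("bolus fit is affine-equivariant in amplitude", {
  t <- seq(0, 12, by = 1 / 30)
  truth <- bolus_params(0.8, 2.5, 0.25, 0.6, 4)
  y <- capacitor_eval(truth, t)
  f1 <- fit_bolus_profile(tic_curve(t, y))
  f2 <- fit_bolus_profile(tic_curve(t, 3.5 * y))
  expect_equal(as.numeric(f2$params[1:4]), as.numeric(f1$params[1:4]),
               tolerance = 1e-3)
  expect_equal(as.numeric(f2$params[5]), 3.5 * as.numeric(f1$params[5]),
               tolerance = 1e-3)
})

test_that("resampled bolus profiles are normalized and refine consistently", {
  p <- bolus_params(0.3, 2, 0.2, 0.4, 5)
  prof <- sample_bolus(p, 200, 0.02)
  expect_equal(sum(prof), 1, tolerance = 1e-12)
  # near-rectangular limit for tiny time constants: flat plateau, sharp off
  pr <- sample_bolus(bolus_params(0.5, 1, 0.005, 0.005, 1), 100, 0.025)
  tt <- (seq_len(100) - 0.5) * 0.025
  plateau <- tt > 0.5 + 2 * 0.025 & tt < 1.5 - 2 * 0.025
  expect_true(all(abs(pr[plateau] - max(pr)) < 0.01 * max(pr)))
  expect_true(all(pr[tt < 0.5 | tt > 1.5 + 2 * 0.025] < 0.01 * max(pr)))
  # doubling the resolution preserves the cumulative shape
  p2 <- sample_bolus(p, 400, 0.01)
  cum1 <- cumsum(prof)
  cum2 <- cumsum(p2)[seq(2, 400, by = 2)]
  expect_lt(max(abs(cum1 - cum2)), 1 / 200)
  expect_error(sample_bolus(bolus_params(50, 1, 0.1, 0.1, 1), 10, 0.01),
               "zero")
})
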