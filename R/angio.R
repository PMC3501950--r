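#' DSA image sequence
#'
#' A stack of 2D scalar frames at a fixed frame rate. Frames are stored as
#' an array `[row (y), col (x), frame]`; pixel coordinates are 1-based at
#' pixel centers with x along columns and y along rows.
#'
#' @param frames 3D numeric array `[ny, nx, n_frames]` (n_frames >= 2).
#' @param frame_rate frames per second.
#' @param pixel_spacing detector pixel spacing, mm/px.
#' @param source `"real"` or `"virtual"` provenance tag.
#' @return An object of class `image_sequence`.
#' @export
image_sequence <- function(frames, frame_rate, pixel_spacing = 1,
                           source = "real") {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3] >= 2L, frame_rate > 0)
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_spacing = pixel_spacing, source = source),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_sequence> %d frames of %dx%d px at %g fps (%s)\n",
              d[3], d[1], d[2], x$frame_rate, x$source))
  invisible(x)
}

#' Line / region of interest
#'
#' @param points for a LOI: 2 x 2 matrix of endpoints `(x, y)` in pixel
#'   coordinates (length >= 2 px).
#' @param mask for an ROI: logical matrix of the frame size (non-empty).
#' @return An object of class `roi_spec` with `type` `"loi"` or `"roi"`.
#' @export
loi_spec <- function(points) {
  points <- matrix(as.numeric(points), 2L, 2L)
  if (sqrt(sum((points[2, ] - points[1, ])^2)) < 2)
    stop("LOI must be at least 2 px long")
  structure(list(type = "loi", points = points), class = "roi_spec")
}

#' @rdname loi_spec
#' @export
roi_spec <- function(mask) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(type = "roi", mask = mask), class = "roi_spec")
}

#' Time-intensity curve
#'
#' Scalar opacification versus time over an ROI/LOI, at uniform spacing.
#'
#' @param times sample times, s, strictly increasing and uniform.
#' @param intensities intensities, arbitrary units.
#' @param source `"real"` or `"virtual"`.
#' @return An object of class `tic_curve`.
#' @export
tic_curve <- function(times, intensities, source = "real") {
  stopifnot(length(times) == length(intensities), length(times) >= 2,
            all(diff(times) > 0))
  structure(list(times = as.numeric(times),
                 intensities = as.numeric(intensities), source = source),
            class = "tic_curve")
}

tic_frame_rate <- function(tic) 1 / mean(diff(tic$times))

# bilinear sampling of one frame stack at pixel coordinates; returns the
# per-frame sum over the sample points
sample_stack <- function(frames, x, y) {
  d <- dim(frames)
  ny <- d[1]; nx <- d[2]
  if (any(x < 1 - 1e-9) || any(x > nx + 1e-9) ||
      any(y < 1 - 1e-9) || any(y > ny + 1e-9))
    stop("geometry error: ROI/LOI outside frame bounds")
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1); y0 <- pmin(floor(y), ny - 1)
  fx <- x - x0; fy <- y - y0
  m <- matrix(frames, ny * nx, d[3])
  li <- function(xx, yy) yy + (xx - 1) * ny
  w <- cbind((1 - fx) * (1 - fy), (1 - fx) * fy, fx * (1 - fy), fx * fy)
  idx <- cbind(li(x0, y0), li(x0, y0 + 1), li(x0 + 1, y0), li(x0 + 1, y0 + 1))
  out <- numeric(d[3])
  for (c in 1:4)
    out <- out + colSums(m[idx[, c], , drop = FALSE] * w[, c])
  out
}

#' Extract a time-intensity curve
#'
#' For a LOI the image intensities are bilinearly sampled at unit-pixel
#' arc-length steps along the segment and summed per frame; for an ROI the
#' mask pixels are summed per frame.
#'
#' @param seq an [image_sequence()].
#' @param roi a [loi_spec()] or [roi_spec()].
#' @return A [tic_curve()] (times from the frame rate, starting at 0).
#' @export
extract_tic <- function(seq, roi) {
  stopifnot(inherits(seq, "image_sequence"), inherits(roi, "roi_spec"))
  nf <- dim(seq$frames)[3]
  if (roi$type == "loi") {
    a <- roi$points[1, ]; b <- roi$points[2, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(2L, ceiling(len) + 1L)
    s <- seq(0, 1, length.out = n)
    vals <- sample_stack(seq$frames, a[1] + s * (b[1] - a[1]),
                         a[2] + s * (b[2] - a[2]))
  } else {
    if (!all(dim(roi$mask) == dim(seq$frames)[1:2]))
      stop("geometry error: ROI mask does not match frame size")
    m <- matrix(seq$frames, prod(dim(seq$frames)[1:2]), nf)
    vals <- colSums(m[as.vector(roi$mask), , drop = FALSE])
  }
  tic_curve((seq_len(nf) - 1) / seq$frame_rate, vals, source = seq$source)
}

#' Detect intensity peaks in a TIC
#'
#' Local maxima of the moving-average-smoothed curve with prominence of at
#' least `min_prominence` times the smoothed dynamic range and pairwise
#' separation of at least `min_separation`. Peak times are refined to
#' sub-frame precision by a parabolic fit through the three samples around
#' each maximum.
#'
#' Before the maxima are located, the slow bolus envelope is removed with
#' a long moving average (`detrend_window`): cardiac intensity ripples
#' ride on the steep wash-in/wash-out flanks of the bolus passage, and
#' peaks of the raw product curve are dragged along the envelope slope,
#' while peaks of the detrended pulsatile component stay put. The
#' prominence threshold still refers to the dynamic range of the
#' undetrended (smoothed) curve, so a featureless curve yields no peaks.
#'
#' @param tic a [tic_curve()] with at least 5 samples.
#' @param min_separation minimum spacing between returned peaks, s (the
#'   default 0.3 s caps the detectable heart rate at 200 bpm).
#' @param min_prominence prominence threshold as a fraction of the dynamic
#'   range.
#' @param smooth_window moving-average window, s.
#' @param detrend_window envelope-removal moving-average window, s
#'   (longer than any plausible cardiac period); 0 disables detrending.
#' @return An object of class `peak_set`: ascending peak times, s.
#' @export
detect_peaks <- function(tic, min_separation = 0.3, min_prominence = 0.05,
                         smooth_window = 0.15, detrend_window = 1.0) {
  y0 <- tic$intensities
  n <- length(y0)
  if (n < 5) stop("TIC too short for peak detection")
  fps <- tic_frame_rate(tic)
  moving_avg <- function(v, w) {
    if (w %% 2 == 0) w <- w + 1L
    if (w <= 1) return(v)
    pad <- (w - 1L) %/% 2L
    vp <- c(rep(v[1], pad), v, rep(v[n], pad))
    as.numeric(stats::filter(vp, rep(1 / w, w), sides = 2))[pad + seq_len(n)]
  }
  ys <- moving_avg(y0, max(1L, round(smooth_window * fps)))
  rng <- diff(range(ys))   # prominence scale: the full smoothed curve
  y <- if (detrend_window > 0)
    ys - moving_avg(ys, max(3L, round(detrend_window * fps))) else ys
  cand <- which(diff(sign(diff(y))) < 0) + 1L   # strict local maxima
  if (!length(cand))
    return(structure(list(times = numeric(0)), class = "peak_set"))
  prom <- vapply(cand, function(i) {
    lmin <- y[i]; j <- i
    while (j > 1 && y[j] <= y[i]) { j <- j - 1; lmin <- min(lmin, y[j]) }
    rmin <- y[i]; j <- i
    while (j < n && y[j] <= y[i]) { j <- j + 1; rmin <- min(rmin, y[j]) }
    y[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence * rng]
  if (!length(keep))
    return(structure(list(times = numeric(0)), class = "peak_set"))
  # greedy separation filter, highest peaks first
  keep <- keep[order(-y[keep])]
  sel <- integer(0)
  for (i in keep)
    if (!length(sel) || all(abs(i - sel) >= min_separation * fps))
      sel <- c(sel, i)
  sel <- sort(sel)
  pk <- vapply(sel, function(i) {
    if (i == 1L || i == n) return(tic$times[i])
    den <- y[i - 1] - 2 * y[i] + y[i + 1]
    off <- if (abs(den) < 1e-12) 0 else 0.5 * (y[i - 1] - y[i + 1]) / den
    tic$times[i] + max(min(off, 0.5), -0.5) / fps
  }, numeric(1))
  structure(list(times = pk), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> ", length(x$times), " peaks\n", sep = "")
  invisible(x)
}

#' Heart period and rate from intensity peaks
#'
#' The period is the mean of successive peak differences,
#' `(1/(n-1)) * sum(p_i - p_(i-1))`, and the rate is 60 / period in bpm.
#'
#' @param peaks a `peak_set` with at least 2 peaks.
#' @return List with `period` (s) and `rate` (bpm).
#' @export
estimate_heart_period <- function(peaks) {
  p <- peaks$times
  if (length(p) < 2) stop("insufficient peaks: need at least 2")
  period <- mean(diff(p))
  list(period = period, rate = 60 / period)
}

#' Synchronize the inflow waveform with the heart state
#'
#' The detected intensity peaks are reduced to a single cardiac phase (the
#' circular mean of the peak times modulo the period, which suppresses the
#' residual per-peak bias on the bolus flanks), extrapolated backward by
#' whole periods to the first peak time `t* >= t0`, and the inflow
#' waveform is phase-shifted so that its velocity minimum falls at `t*`
#' (low inlet velocity corresponds to high contrast intensity).
#'
#' @param peaks a `peak_set`.
#' @param period cardiac period, s.
#' @param waveform an [inflow_waveform()].
#' @param t0 start time of the sequence, s.
#' @return List with `waveform` (shifted, or the input when no peaks are
#'   available), `shift` (s), `t_star` (s) and `synchronized` (logical).
#' @export
synchronize_heart_state <- function(peaks, period, waveform, t0 = 0) {
  if (!length(peaks$times)) {
    warning("no intensity peaks: heart state left unsynchronized")
    return(list(waveform = waveform, shift = NA_real_, t_star = NA_real_,
                synchronized = FALSE))
  }
  stopifnot(period > 0)
  ang <- 2 * pi * (peaks$times %% period) / period
  phase <- atan2(mean(sin(ang)), mean(cos(ang))) * period / (2 * pi)
  t_star <- t0 + (phase - t0) %% period
  shift <- (t_star - waveform$phase_of_min) %% period
  list(waveform = shift_waveform_phase(waveform, shift), shift = shift,
       t_star = t_star, synchronized = TRUE)
}

#' Cardiac parameters from a TIC by envelope normalization
#'
#' Composite estimator for heart rate and heart state: the capacitor bolus
#' model is fitted to the TIC (the fit family carries no cardiac ripple,
#' so the fitted curve is the pulsatility-free envelope), the TIC is
#' divided by the fitted envelope over its well-supported span, and the
#' intensity peaks of the normalized modulation are detected with
#' [detect_peaks()]. Because the envelope division removes the bolus
#' wash-in/wash-out slopes, the peak times are unbiased even on the
#' flanks, which a direct detection on the raw curve cannot guarantee.
#' Peaks falling close to the envelope's model corners (the injection
#' onset, the plateau-to-decay break, and the edges of the supported
#' span), where the normalization is only as good as the local fit, are
#' excluded from the period and phase estimates. Falls back to direct
#' detection when the envelope fit fails.
#'
#' @param tic a [tic_curve()].
#' @param support_frac envelope support threshold: samples where the
#'   fitted envelope falls below this fraction of its maximum are excluded
#'   from the normalized curve.
#' @param corner_margin exclusion half-width around envelope corners, s.
#' @param ... passed to [detect_peaks()].
#' @return List with `peaks` (the `peak_set` driving the rate estimate),
#'   `period` (s) and `rate` (bpm) from [estimate_heart_period()],
#'   `phase_peaks` (a single-peak `peak_set` at the lock-in-refined
#'   modulation maximum, the preferred input to
#'   [synchronize_heart_state()]), `refined_period` (s, from the lock-in
#'   frequency search), `bolus_fit` (from [fit_bolus_profile()], or NULL)
#'   and `method` (`"envelope-normalized"` or `"direct"`). `period`/`rate`
#'   are NA when fewer than two peaks are found.
#' @export
extract_cardiac_params <- function(tic, support_frac = 0.15, ...) {
  fit <- tryCatch(fit_bolus_profile(tic), error = function(e) NULL)
  method <- "direct"
  pk <- phase_pk <- NULL
  refined_period <- NA_real_
  if (!is.null(fit)) {
    env <- capacitor_eval(fit$params, tic$times)
    sup <- which(env > support_frac * max(env))
    # contiguous well-supported span only
    if (length(sup) >= 10 && all(diff(sup) == 1)) {
      ts <- tic$times[sup]
      ratio <- tic$intensities[sup] / env[sup]
      # the ratio is already trend-free, so no detrending (whose edge
      # padding would bias peaks within half a window of the span ends)
      pk <- detect_peaks(tic_curve(ts, ratio, tic$source),
                         detrend_window = 0, ...)
      # the first and last peaks sit where residual envelope misfit is
      # largest; drop them from the period average when enough remain
      nt <- length(pk$times)
      if (nt >= 4)
        pk <- structure(list(times = pk$times[2:(nt - 1)]),
                        class = "peak_set")
      if (nt >= 2) {
        lk <- lockin_phase(ts, ratio, env[sup], mean(diff(pk$times)))
        refined_period <- lk$period
        phase_pk <- structure(list(times = lk$t_max), class = "peak_set")
        # joint envelope-times-modulation refinement: re-fit the full
        # generative model to the raw TIC, then re-detect peaks on the
        # curve normalized by the refined envelope
        jt <- joint_modulation_fit(tic, fit$params, lk)
        if (!is.null(jt)) {
          env2 <- capacitor_eval(jt$bolus, tic$times)
          sup2 <- which(env2 > support_frac * max(env2))
          if (length(sup2) >= 10 && all(diff(sup2) == 1)) {
            pk2 <- detect_peaks(
              tic_curve(tic$times[sup2],
                        tic$intensities[sup2] / env2[sup2], tic$source),
              detrend_window = 0, ...)
            if (length(pk2$times) >= 2) pk <- pk2
            refined_period <- jt$period
            phase_pk <- structure(list(times = jt$t_max),
                                  class = "peak_set")
            fit <- list(params = jt$bolus, residual = jt$residual)
          }
        }
      }
      method <- "envelope-normalized"
    }
  }
  if (is.null(pk)) pk <- detect_peaks(tic, ...)
  if (is.null(phase_pk)) phase_pk <- pk
  h <- if (length(pk$times) >= 2) estimate_heart_period(pk)
    else list(period = NA_real_, rate = NA_real_)
  list(peaks = pk, period = h$period, rate = h$rate,
       phase_peaks = phase_pk, refined_period = refined_period,
       bolus_fit = fit, method = method)
}

# lock-in estimation of the cardiac modulation: weighted least-squares fit
# of a + b cos(w t) + c sin(w t) to the envelope-normalized curve, with
# the frequency refined around 1/period0 by maximizing the fitted
# modulation power. Returns the refined period and the time of the
# modulation maximum nearest the (weighted) span center.
lockin_phase <- function(ts, ratio, env, period0) {
  wt <- (env / max(env))^2   # ratio noise scales with 1 / envelope
  amp2 <- function(f) {
    cw <- cos(2 * pi * f * ts); sw <- sin(2 * pi * f * ts)
    X <- cbind(1, cw, sw)
    b <- tryCatch(solve(crossprod(X, wt * X), crossprod(X, wt * ratio)),
                  error = function(e) c(0, 0, 0))
    list(power = b[2]^2 + b[3]^2, b = b)
  }
  f0 <- 1 / period0
  opt <- optimize(function(f) -amp2(f)$power, c(0.9 * f0, 1.1 * f0),
                  tol = 1e-6)
  f <- opt$minimum
  b <- amp2(f)$b
  theta <- atan2(b[3], b[2])          # maximum of b2 cos + b3 sin
  t_ref <- sum(wt * ts) / sum(wt)
  t_max <- (theta / (2 * pi * f)) +
    round((t_ref - theta / (2 * pi * f)) * f) / f
  list(period = 1 / f, t_max = t_max, depth = sqrt(b[2]^2 + b[3]^2))
}

# Levenberg-Marquardt fit of the full TIC model
# capacitor(p, t) * (1 + d cos(2 pi f t - theta))
# initialized from the capacitor-only fit and the lock-in estimates.
# Returns NULL when the fit fails or finds no meaningful modulation.
joint_modulation_fit <- function(tic, bolus0, lk) {
  t <- tic$times; y <- tic$intensities
  f0 <- 1 / lk$period
  theta0 <- 2 * pi * f0 * lk$t_max
  par0 <- c(as.numeric(bolus0), min(lk$depth, 0.9), f0, theta0)
  lower <- c(0, 1e-3, 1e-3, 1e-3, 1e-6, 0, 0.85 * f0, theta0 - pi)
  upper <- c(max(t), 2 * max(t), max(t), max(t), 10 * max(y), 0.95,
             1.15 * f0, theta0 + pi)
  fn <- function(p) {
    capacitor_eval(p[1:5], t) *
      (1 + p[6] * cos(2 * pi * p[7] * t - p[8])) - y
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = pmin(pmax(par0, lower), upper), fn = fn,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$par[6] < 0.02) return(NULL)
  p <- fit$par
  t_ref <- lk$t_max
  t_max <- p[8] / (2 * pi * p[7]) +
    round((t_ref - p[8] / (2 * pi * p[7])) * p[7]) / p[7]
  list(bolus = bolus_params(p[1], max(p[2], 1e-3), max(p[3], 1e-3),
                            max(p[4], 1e-3), max(p[5], 1e-6)),
       depth = p[6], period = 1 / p[7], t_max = t_max,
       residual = sqrt(fit$deviance / length(t)))
}

#' Capacitor bolus parameters
#'
#' The five parameters of the capacitor-style injection-bolus model:
#' onset delay `p1` (s), injection duration `p2` (s), charging and
#' discharging time constants `p3`, `p4` (s) and amplitude `p5` (a.u.).
#'
#' @param p1,p2,p3,p4,p5 see above; `p1 >= 0`, the rest `> 0`.
#' @return An object of class `bolus_params` (numeric vector of length 5).
#' @export
bolus_params <- function(p1, p2, p3, p4, p5) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5)
  if (p[1] < 0 || any(p[2:5] <= 0))
    stop("need p1 >= 0 and p2..p5 > 0")
  structure(p, class = "bolus_params")
}

#' Evaluate the capacitor bolus model
#'
#' Piecewise charge/discharge curve: 0 before onset;
#' `p5 (1 - exp(-(t - p1)/p3))` during the injection; exponential decay
#' with time constant `p4` from the plateau-end value afterwards (the
#' decay branch is anchored at `p5 (1 - exp(-p2/p3))` so the curve is
#' continuous).
#'
#' @param p a [bolus_params()] or numeric vector (p1..p5).
#' @param t times, s (vectorized).
#' @return Intensities, a.u.
#' @export
capacitor_eval <- function(p, t) {
  p <- as.numeric(p)
  out <- numeric(length(t))
  rise <- t >= p[1] & t < p[1] + p[2]
  out[rise] <- p[5] * (1 - exp(-(t[rise] - p[1]) / p[3]))
  fall <- t >= p[1] + p[2]
  out[fall] <- p[5] * (1 - exp(-p[2] / p[3])) *
    exp(-(t[fall] - (p[1] + p[2])) / p[4])
  out
}

#' Fit the capacitor bolus model to a TIC
#'
#' Levenberg-Marquardt least squares (via \code{minpack.lm}) of
#' [capacitor_eval()] against the measured curve, with multi-start
#' initialization (onset from the 10%-rise time, duration from the FWHM,
#' charge/discharge constants seeded at 0.3 s, amplitude at the maximum)
#' and bounds enforcing the parameter invariants. The capacitor family
#' contains no oscillatory term, so the fit removes the cardiac
#' pulsatility and background noise from the measured bolus.
#'
#' @param tic a [tic_curve()] with at least 20 samples and positive
#'   dynamic range.
#' @param n_starts number of multi-start initializations.
#' @return List with `params` (a [bolus_params()]) and `residual` (RMS
#'   residual, a.u.).
#' @export
fit_bolus_profile <- function(tic, n_starts = 5) {
  t <- tic$times; y <- tic$intensities
  if (length(t) < 20) stop("TIC too short for bolus fitting")
  rng <- diff(range(y))
  if (rng <= 0) stop("TIC has no dynamic range")
  ymax <- max(y); imax <- which.max(y)
  lvl10 <- min(y) + 0.1 * rng
  i10 <- which(y >= lvl10)[1]
  t10 <- t[max(i10, 1)]
  above <- which(y >= min(y) + 0.5 * rng)
  fwhm0 <- max(t[above[length(above)]] - t[above[1]], 3 * (t[2] - t[1]))
  span <- diff(range(t))
  starts <- list(
    c(t10, fwhm0, 0.3, 0.3, ymax),
    c(max(t10 - fwhm0 / 4, 0), fwhm0, 0.15, 0.5, ymax),
    c(t10, 1.5 * fwhm0, 0.3, 0.3, ymax),
    c(max(t10 / 2, 0.01), 0.75 * fwhm0, 0.5, 0.2, ymax),
    c(t10, fwhm0, 0.1, 0.1, ymax * 1.1)
  )[seq_len(n_starts)]
  lower <- c(0, 1e-3, 1e-3, 1e-3, 1e-6)
  upper <- c(max(span, 1), 2 * span, span, span, 10 * ymax)
  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s,
                         fn = function(par) capacitor_eval(par, t) - y,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("bolus fit failed to converge from all starts")
  p <- best$par
  list(params = bolus_params(p[1], max(p[2], 1e-3), max(p[3], 1e-3),
                             max(p[4], 1e-3), max(p[5], 1e-6)),
       residual = sqrt(best$deviance / length(t)))
}

#' Resample a bolus curve as a normalized injection profile
#'
#' Evaluates the capacitor curve at the step midpoints and normalizes the
#' samples to sum to 1, ready for [build_injection_schedule()].
#'
#' @param p a [bolus_params()].
#' @param n_steps number of simulation steps.
#' @param dt step size, s.
#' @return Numeric vector of length `n_steps` summing to 1.
#' @export
sample_bolus <- function(p, n_steps, dt) {
  stopifnot(n_steps >= 1)
  v <- capacitor_eval(p, (seq_len(n_steps) - 0.5) * dt)
  s <- sum(v)
  if (s <= 0) stop("bolus profile is all zero over the simulated span")
  v / s
}
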