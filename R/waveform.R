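#' Inflow waveform over one cardiac cycle
#'
#' Velocity magnitude (m/s) sampled over one cardiac period, evaluated
#' periodically by linear interpolation. `phase_of_min` records where in
#' the cycle the velocity minimum falls; it is the anchor used by
#' [synchronize_heart_state()].
#'
#' @param samples velocity magnitude samples over one cycle, m/s (all > 0);
#'   sample i corresponds to phase (i-1)/length(samples) of the cycle.
#' @param period cardiac period, s.
#' @param phase_of_min time of the velocity minimum within the cycle, s.
#' @return An object of class `inflow_waveform`.
#' @export
inflow_waveform <- function(samples, period, phase_of_min = NULL) {
  samples <- as.numeric(samples)
  if (any(samples <= 0)) stop("all waveform samples must be > 0")
  if (period <= 0) stop("period must be > 0")
  if (is.null(phase_of_min))
    phase_of_min <- (which.min(samples) - 1) / length(samples) * period
  structure(list(samples = samples, period = period,
                 phase_of_min = phase_of_min %% period),
            class = "inflow_waveform")
}

#' @export
print.inflow_waveform <- function(x, ...) {
  cat(sprintf(
    "<inflow_waveform> %.3f-%.3f m/s (mean %.3f), period %.4f s (%.1f bpm)\n",
    min(x$samples), max(x$samples), mean(x$samples), x$period, 60 / x$period))
  invisible(x)
}

#' Evaluate an inflow waveform
#'
#' Periodic evaluation `v(t) = v(t + period)` by linear interpolation of
#' the cycle samples.
#'
#' @param w an [inflow_waveform()].
#' @param t times, s (any real values).
#' @return Velocity magnitudes, m/s.
#' @export
waveform_eval <- function(w, t) {
  m <- length(w$samples)
  u <- (t / w$period) %% 1
  x <- u * m          # in [0, m); sample i at x = i - 1
  i0 <- floor(x)
  f <- x - i0
  s <- c(w$samples, w$samples[1])   # wrap
  s[i0 + 1] * (1 - f) + s[i0 + 2] * f
}

#' Pulsatile inflow waveform from min/mean/max velocities
#'
#' Builds a smooth one-cycle waveform from a raised-cosine-plus-systolic-
#' peak template,
#' `v(u) = vmin + (vmax - vmin) * (alpha * c(u) + (1 - alpha) * c(u)^gamma)`
#' with `c(u) = (1 + cos(2*pi*u)) / 2`: the raised-cosine term keeps the
#' velocity varying throughout diastole (as physiological carotid
#' waveforms do — a template that is flat between systolic peaks would
#' carry almost no cardiac-frequency information), while the power term
#' sharpens the systolic peak. The exponent gamma is solved so that the
#' cycle average matches `mean`. The systolic peak sits at phase 0 and
#' the minimum at half the cycle.
#'
#' @param mean,vmin,vmax cycle average, minimum and maximum velocity, m/s
#'   (`0 < vmin <= mean <= vmax`).
#' @param period cardiac period, s.
#' @param n_samples number of cycle samples (even, so the minimum is an
#'   exact sample).
#' @param alpha weight of the raised-cosine base component (reduced
#'   automatically when the requested mean is too extreme for it).
#' @return An [inflow_waveform()] whose min, max and time average match the
#'   inputs to well within 1%.
#' @export
make_pulsatile_waveform <- function(mean, vmin, vmax, period,
                                    n_samples = 1024L, alpha = 0.35) {
  if (!(vmin <= mean && mean <= vmax) || vmin <= 0)
    stop("need 0 < vmin <= mean <= vmax")
  u <- (seq_len(n_samples) - 1) / n_samples
  cu <- (1 + cos(2 * pi * u)) / 2
  if (vmax - vmin < 1e-12) {
    samples <- rep(mean, n_samples)
  } else {
    target <- (mean - vmin) / (vmax - vmin)
    target <- min(max(target, 1e-6), 1 - 1e-6)
    # the cosine part contributes alpha/2 to the template mean and the
    # power part spans (0, 1 - alpha); shrink alpha for extreme targets
    alpha <- max(0, min(alpha, 1.8 * target, 1.8 * (1 - target)))
    f <- function(lg)
      alpha / 2 + (1 - alpha) * base::mean(cu^exp(lg)) - target
    lg <- uniroot(f, c(log(1e-4), log(1e4)), tol = 1e-12)$root
    samples <- vmin + (vmax - vmin) *
      (alpha * cu + (1 - alpha) * cu^exp(lg))
  }
  inflow_waveform(samples, period, phase_of_min = period / 2)
}

#' Shift an inflow waveform in phase
#'
#' Returns the waveform `v'(t) = v(t - shift)` with the same period.
#' Shifting by a whole period is the identity (up to interpolation).
#'
#' @param w an [inflow_waveform()].
#' @param shift time shift, s (any sign).
#' @return An [inflow_waveform()].
#' @export
shift_waveform_phase <- function(w, shift) {
  m <- length(w$samples)
  t_new <- (seq_len(m) - 1) / m * w$period
  inflow_waveform(waveform_eval(w, t_new - shift), w$period,
                  phase_of_min = (w$phase_of_min + shift) %% w$period)
}
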