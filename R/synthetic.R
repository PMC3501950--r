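#' Specification for a synthetic DSA sequence
#'
#' Defines a DSA-like sequence with known ground truth: a capacitor bolus
#' envelope multiplied by a cardiac pulsatility modulation, painted into a
#' vessel mask with optional per-region transit delays, plus additive
#' Gaussian noise. Intensity maxima coincide with inflow-velocity minima,
#' the correspondence heart-state synchronization relies on.
#'
#' Defaults model a high-frame-rate cerebral acquisition: 30 fps for 12 s,
#' 84 bpm, a 3 s injection with capacitor constants 0.2/0.5 s, 20%
#' pulsatile modulation and additive noise at 1/20 of the bolus amplitude.
#'
#' @param heart_rate heart rate, bpm.
#' @param phase_offset cardiac phase: time of the first intensity-
#'   modulation maximum, s.
#' @param bolus a [bolus_params()].
#' @param pulsatility_depth peak-to-mean intensity modulation fraction in
#'   `[0, 1)`.
#' @param noise_sigma per-pixel additive Gaussian noise sd, a.u.; default
#'   `p5 / 20`.
#' @param frame_rate fps.
#' @param duration sequence duration, s (`duration * frame_rate >= 10`).
#' @param vessel_mask logical matrix; default a centered disk in 32 x 32.
#' @param transit_delays optional list of `list(mask, delay)` regions
#'   whose pixels see the bolus delayed by `delay` seconds.
#' @param seed generator seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(heart_rate = 84, phase_offset = 0.15,
                       bolus = bolus_params(1, 3, 0.2, 0.5, 10),
                       pulsatility_depth = 0.2, noise_sigma = NULL,
                       frame_rate = 30, duration = 12, vessel_mask = NULL,
                       transit_delays = NULL, seed = 1L) {
  if (pulsatility_depth < 0 || pulsatility_depth >= 1)
    stop("pulsatility_depth must be in [0, 1)")
  if (duration * frame_rate < 10) stop("need at least 10 frames")
  if (is.null(noise_sigma)) noise_sigma <- as.numeric(bolus[5]) / 20
  if (is.null(vessel_mask)) {
    xy <- expand.grid(x = 1:32, y = 1:32)
    vessel_mask <- matrix((xy$x - 16.5)^2 + (xy$y - 16.5)^2 <= 10^2, 32, 32)
  }
  if (!any(vessel_mask)) stop("vessel mask is empty")
  structure(list(heart_rate = heart_rate, phase_offset = phase_offset,
                 bolus = bolus, pulsatility_depth = pulsatility_depth,
                 noise_sigma = noise_sigma, frame_rate = frame_rate,
                 duration = duration, vessel_mask = vessel_mask,
                 transit_delays = transit_delays, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic DSA sequence with known ground truth
#'
#' Per-pixel intensity inside the mask:
#' `I(x, t) = bolus(t - delay(x)) * (1 - depth * m(t)) + noise`, where
#' `m(t) = -cos(2 pi (t - phase_offset) / T)` is a unit-amplitude,
#' zero-mean cardiac modulation at the configured heart rate: intensity
#' maxima fall at `phase_offset + k T` and the cycle-averaged envelope
#' equals the bolus curve (`depth` is a peak-to-mean fraction), so the
#' fitted bolus amplitude is an unbiased estimate of `p5`.
#'
#' @param spec a [synth_spec()].
#' @return List with `seq` (an [image_sequence()]) and `truth` (the
#'   generating values, including the cardiac period).
#' @export
make_synthetic_dsa <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  nf <- round(spec$duration * spec$frame_rate)
  t <- (seq_len(nf) - 1) / spec$frame_rate
  period <- 60 / spec$heart_rate
  m <- -cos(2 * pi * (t - spec$phase_offset) / period)
  mod <- 1 - spec$pulsatility_depth * m
  d <- dim(spec$vessel_mask)
  delay <- matrix(0, d[1], d[2])
  for (td in spec$transit_delays)
    delay[td$mask] <- td$delay
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  frames <- array(0, c(d[1], d[2], nf))
  udel <- unique(delay[spec$vessel_mask])
  for (dl in udel) {
    env <- capacitor_eval(spec$bolus, t - dl) * mod
    pix <- spec$vessel_mask & delay == dl
    frames[outer(which(pix), (seq_len(nf) - 1) * d[1] * d[2], "+")] <-
      rep(env, each = sum(pix))
  }
  if (spec$noise_sigma > 0)
    frames <- frames + array(rnorm(length(frames), 0, spec$noise_sigma),
                             dim(frames))
  list(seq = image_sequence(frames, spec$frame_rate, source = "real"),
       truth = list(heart_rate = spec$heart_rate, period = period,
                    phase_offset = spec$phase_offset, bolus = spec$bolus,
                    pulsatility_depth = spec$pulsatility_depth,
                    noise_sigma = spec$noise_sigma, delays = udel,
                    seed = spec$seed))
}
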