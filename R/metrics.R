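#' Quantitative TIC metrics
#'
#' Computes the standard bolus-passage features of a time-intensity curve
#' on its 0-100 normalized scale (all metrics are therefore invariant to
#' affine intensity rescaling):
#' \itemize{
#' \item FWHM: duration between the first upward and last downward
#'   crossing of half maximum, located by linear interpolation.
#' \item TTP: duration from the first upward 10%-of-maximum crossing to
#'   the intensity maximum.
#' \item average wash-in/wash-out: `atan(slope)` with the intensity change
#'   on the 0-100 scale and the duration counted in frames at
#'   `frame_rate` (or in seconds with `time_base = "seconds"`); wash-out
#'   is negative.
#' }
#'
#' @param tic a [tic_curve()].
#' @param frame_rate frame rate used for the slope time base, fps;
#'   defaults to the curve's sampling rate.
#' @param time_base `"frames"` or `"seconds"` for the wash-in/out slopes.
#' @return An object of class `tic_metrics`: list with `fwhm` (s, NA if a
#'   half-max flank is missing), `ttp` (s), `washin` (rad), `washout`
#'   (rad), `fmax` (a.u., original scale), `t_fmax` (s) and `time_base`.
#' @export
compute_tic_metrics <- function(tic, frame_rate = NULL,
                                time_base = c("frames", "seconds")) {
  time_base <- match.arg(time_base)
  if (is.null(frame_rate)) frame_rate <- tic_frame_rate(tic)
  t <- tic$times; y0 <- tic$intensities
  rng <- diff(range(y0))
  if (rng <= 0) stop("TIC has no dynamic range")
  y <- 100 * (y0 - min(y0)) / rng
  imax <- which.max(y)
  t_fmax <- t[imax]
  scale_dt <- if (time_base == "frames") frame_rate else 1
  t10_up <- first_up_crossing(t, y, 10)
  t10_down <- last_down_crossing(t, y, 10)
  t50_up <- first_up_crossing(t, y, 50)
  t50_down <- last_down_crossing(t, y, 50)
  fwhm <- if (is.na(t50_up) || is.na(t50_down) || t50_down <= t50_up)
    NA_real_ else t50_down - t50_up
  ttp <- if (is.na(t10_up)) NA_real_ else t_fmax - t10_up
  washin <- if (is.na(t10_up) || t_fmax <= t10_up) NA_real_
    else atan(90 / ((t_fmax - t10_up) * scale_dt))
  washout <- if (is.na(t10_down) || t10_down <= t_fmax) NA_real_
    else atan(-90 / ((t10_down - t_fmax) * scale_dt))
  structure(list(fwhm = fwhm, ttp = ttp, washin = washin, washout = washout,
                 fmax = max(y0), t_fmax = t_fmax, time_base = time_base),
            class = "tic_metrics")
}

# first upward crossing of level L (linear interpolation); NA if none
first_up_crossing <- function(t, y, L) {
  i <- which(y[-length(y)] < L & y[-1] >= L)
  if (!length(i)) return(if (y[1] >= L) t[1] else NA_real_)
  i <- i[1]
  t[i] + (L - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i])
}

# last downward crossing of level L; NA if the curve ends above L
last_down_crossing <- function(t, y, L) {
  i <- which(y[-length(y)] >= L & y[-1] < L)
  if (!length(i)) return(NA_real_)
  i <- i[length(i)]
  t[i] + (y[i] - L) / (y[i] - y[i + 1]) * (t[i + 1] - t[i])
}

#' Crop a TIC to the arterial phase
#'
#' Keeps the samples inside the inclusive window, preserving their times.
#' Used to exclude venous overlay from curve-based comparisons.
#'
#' @param tic a [tic_curve()].
#' @param window `c(t_start, t_end)`, s, within the curve span.
#' @return The cropped [tic_curve()].
#' @export
crop_arterial <- function(tic, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  keep <- tic$times >= window[1] - 1e-9 & tic$times <= window[2] + 1e-9
  if (sum(keep) < 2) stop("arterial window selects fewer than 2 samples")
  tic_curve(tic$times[keep], tic$intensities[keep], tic$source)
}

#' Shift/scale-aligned relative RMSE between TICs
#'
#' The real TIC is min-max normalized to 0-100; the virtual TIC is shifted
#' (integer frames, exhaustively over a bounded window) and scaled (the
#' closed-form least-squares factor per shift) to minimize the rRMSE
#' `sqrt(mean(((P - a T) / Tm)^2)) * 100`, with `Tm` the mean of the
#' normalized real curve. A positive shift means the virtual curve lags
#' the real one.
#'
#' @param real,virtual [tic_curve()]s; the virtual curve is resampled to
#'   the real frame rate when the rates differ.
#' @param max_shift half-width of the shift search window, s.
#' @return List with `rrmse` (percent), `shift` (s), `shift_frames` and
#'   `scale`.
#' @export
rrmse_aligned <- function(real, virtual, max_shift = 1.0) {
  fps <- tic_frame_rate(real)
  Tv <- virtual$intensities
  if (abs(tic_frame_rate(virtual) - fps) > 1e-6 * fps)
    Tv <- approx(virtual$times, Tv,
                 xout = seq(min(virtual$times), max(virtual$times),
                            by = 1 / fps), rule = 2)$y
  P <- real$intensities
  rng <- diff(range(P))
  if (rng <= 0) stop("normalization error: real TIC is constant")
  P <- 100 * (P - min(P)) / rng
  Tm <- mean(P)
  nP <- length(P); nT <- length(Tv)
  kmax <- max(0L, round(max_shift * fps))
  best <- NULL
  for (s in (-kmax):kmax) {
    # compare P[i] with scale * Tv[i + s] on the overlap
    i <- seq_len(nP)
    j <- i + s
    ok <- j >= 1 & j <= nT
    if (sum(ok) < 3) next
    Pi <- P[i[ok]]; Ti <- Tv[j[ok]]
    a <- if (sum(Ti^2) > 0) sum(Pi * Ti) / sum(Ti^2) else 0
    r <- sqrt(mean(((Pi - a * Ti) / Tm)^2)) * 100
    if (is.null(best) || r < best$rrmse)
      best <- list(rrmse = r, shift = s / fps, shift_frames = s, scale = a)
  }
  if (is.null(best)) stop("no overlapping support within the shift window")
  best
}

#' Compare real and virtual angiograms over paired ROIs
#'
#' For each ROI pair: extract both TICs, optionally crop to an arterial
#' window, compute [compute_tic_metrics()] for each and the
#' shift/scale-aligned rRMSE between them. The report table follows the
#' FWHM / average wash-in (rad) / average wash-out (rad) / TTP / rRMSE
#' layout.
#'
#' @param real_seq,virt_seq [image_sequence()]s.
#' @param rois list of ROI pairs; each element either a single
#'   [roi_spec()]/[loi_spec()] used in both sequences, or
#'   `list(real = ..., virtual = ...)`.
#' @param windows optional arterial crop windows: one `c(t0, t1)` or a
#'   list, one per ROI.
#' @param max_shift rRMSE alignment window half-width, s.
#' @return An object of class `comparison_report`: list with `table` (one
#'   row per ROI and source) and `alignment` (per-ROI shift/scale), plus
#'   per-ROI flags for failed entries.
#' @export
compare_rois <- function(real_seq, virt_seq, rois, windows = NULL,
                         max_shift = 1.0) {
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  nm <- names(rois)
  if (is.null(nm)) nm <- paste0("ROI", seq_along(rois) - 1)
  rows <- list(); align <- list(); flags <- character(0)
  for (k in seq_along(rois)) {
    rk <- rois[[k]]
    pair <- if (!is.null(rk$real)) rk else list(real = rk, virtual = rk)
    win <- if (is.null(windows)) NULL
      else if (is.list(windows)) windows[[k]] else windows
    res <- tryCatch({
      tr <- extract_tic(real_seq, pair$real)
      tv <- extract_tic(virt_seq, pair$virtual)
      if (!is.null(win)) {
        tr <- crop_arterial(tr, win)
        tv <- crop_arterial(tv, win)
      }
      mr <- compute_tic_metrics(tr, real_seq$frame_rate)
      mv <- compute_tic_metrics(tv, virt_seq$frame_rate)
      al <- rrmse_aligned(tr, tv, max_shift = max_shift)
      list(mr = mr, mv = mv, al = al)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      flags <- c(flags, paste0(nm[k], ": ", conditionMessage(res)))
      next
    }
    for (src in c("real", "virtual")) {
      m <- if (src == "real") res$mr else res$mv
      rows[[length(rows) + 1L]] <- data.frame(
        roi = nm[k], source = src, fwhm_s = m$fwhm, washin_rad = m$washin,
        washout_rad = m$washout, ttp_s = m$ttp, rrmse_pct = res$al$rrmse,
        stringsAsFactors = FALSE)
    }
    align[[nm[k]]] <- c(res$al,
                        list(crop = if (is.null(win)) NA else win))
  }
  structure(list(table = do.call(rbind, rows), alignment = align,
                 flags = flags),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Dominant spectral peak of a TIC, in bpm
#'
#' Locates the dominant periodicity of the pulsatile component of a TIC.
#' When a capacitor bolus envelope fits the curve (see
#' [fit_bolus_profile()]), the TIC is divided by it and the peak is found
#' by a weighted least-squares periodogram (sinusoid regression over a
#' frequency scan): samples are weighted by the squared envelope (ratio
#' noise scales inversely with the envelope) and samples near the
#' envelope's model corners — where the normalization is only as reliable
#' as the local fit — are excluded. The raw-curve transients and corner
#' misfit otherwise leak phase-coherent power into the cardiac band and
#' displace a plain periodogram peak by several bpm on short records.
#' Without a usable envelope fit the curve is moving-average detrended,
#' Hann-windowed, zero-padded, and the FFT periodogram maximum above
#' `min_hz` is refined by parabolic interpolation. Used to verify that
#' distal TICs carry the configured cardiac frequency.
#'
#' @param tic a [tic_curve()].
#' @param min_hz lower band edge excluding the DC/bolus envelope band, Hz.
#' @param max_hz upper band edge, Hz; the default 3.4 Hz (204 bpm)
#'   matches the fastest heart rate the peak-detection defaults resolve.
#' @param detrend_window moving-average detrend window, s (fallback path).
#' @param normalize_envelope attempt the capacitor-envelope division.
#' @param corner_margin exclusion half-width around envelope corners, s.
#' @return Peak frequency expressed in beats per minute.
#' @export
spectral_peak_bpm <- function(tic, min_hz = 0.6, max_hz = 3.4,
                              detrend_window = 1.0,
                              normalize_envelope = TRUE,
                              corner_margin = 0.3) {
  y <- tic$intensities
  n <- length(y)
  fps <- tic_frame_rate(tic)
  if (normalize_envelope) {
    fit <- tryCatch(fit_bolus_profile(tic), error = function(e) NULL)
    if (!is.null(fit)) {
      env <- capacitor_eval(fit$params, tic$times)
      sup <- which(env > 0.1 * max(env))
      if (length(sup) >= 10 && all(diff(sup) == 1)) {
        p <- as.numeric(fit$params)
        ts <- tic$times[sup]
        r <- y[sup] / env[sup]
        wt <- (env[sup] / max(env))^2
        for (cn in c(p[1], p[1] + p[2]))
          wt[abs(ts - cn) < corner_margin] <- 0
        if (sum(wt > 0) > 10) {
          power <- function(f) {
            X <- cbind(1, cos(2 * pi * f * ts), sin(2 * pi * f * ts))
            b <- tryCatch(solve(crossprod(X, wt * X),
                                crossprod(X, wt * r)),
                          error = function(e) c(0, 0, 0))
            b[2]^2 + b[3]^2
          }
          fs <- seq(min_hz, min(max_hz, 0.95 * fps / 2), by = 0.005)
          pw <- vapply(fs, power, numeric(1))
          f0 <- fs[which.max(pw)]
          opt <- optimize(function(f) -power(f),
                          c(f0 - 0.01, f0 + 0.01), tol = 1e-7)
          return(60 * opt$minimum)
        }
      }
    }
  }
  w <- max(3L, round(detrend_window * fps))
  if (w %% 2 == 0) w <- w + 1L
  pad <- (w - 1L) %/% 2L
  yp <- c(rep(y[1], pad), y, rep(y[n], pad))
  trend <- as.numeric(stats::filter(yp, rep(1 / w, w),
                                    sides = 2))[pad + seq_len(n)]
  d <- (y - trend) * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  nfft <- 2^ceiling(log2(n * 16))
  sp <- Mod(fft(c(d, numeric(nfft - n))))^2
  freqs <- (seq_len(nfft) - 1) * fps / nfft
  band <- which(freqs >= min_hz & freqs <= min(max_hz, fps / 2))
  if (!length(band)) stop("no spectral band above min_hz")
  i <- band[which.max(sp[band])]
  f <- freqs[i]
  if (i > 1 && i < nfft / 2) {
    den <- sp[i - 1] - 2 * sp[i] + sp[i + 1]
    if (abs(den) > 0)
      f <- f + 0.5 * (sp[i - 1] - sp[i + 1]) / den * (fps / nfft)
  }
  60 * f
}
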