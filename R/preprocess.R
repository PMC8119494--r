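#' Zero-phase first-order Butterworth low-pass filter
#'
#' Applies a first-order Butterworth low-pass filter forward and backward
#' (zero-phase), so event timings in the filtered signal are not shifted.
#' The design cutoff is pre-compensated for the dual pass in the warped
#' (tangent) frequency domain, so the *combined* response is still -3 dB
#' (gain 1/sqrt(2)) at the requested cutoff frequency.
#'
#' @param x numeric signal sampled at `fs` Hz.
#' @param cutoff -3 dB cutoff frequency in Hz, in `(0, fs/2)`.
#' @param fs sampling rate in Hz (default 100).
#' @return the filtered signal, same length as `x`.
#' @export
butterworth_lowpass <- function(x, cutoff, fs = 100) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff))
    stop("`cutoff` must be a single finite number")
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop(sprintf("`cutoff` must lie in (0, %g) Hz", fs / 2))
  if (length(x) < 7) stop("signal too short to filter")
  # dual-pass gain of an order-1 Butterworth at normalized frequency w is
  # 1 / (1 + (tan(pi w/2)/tan(pi wc/2))^2); requiring 1/sqrt(2) at the
  # nominal cutoff gives tan(pi wc/2) = tan(pi w/2) / sqrt(sqrt(2) - 1)
  w_nom <- cutoff / (fs / 2)
  w_adj <- (2 / pi) * atan(tan(pi * w_nom / 2) / sqrt(sqrt(2) - 1))
  bf <- signal::butter(1, w_adj, type = "low")
  # reflective padding keeps the filter in steady state at the signal
  # edges (filtfilt alone starts from a zero state)
  n <- length(x)
  L <- min(n - 1, max(20, ceiling(3 * fs / cutoff)))
  xp <- c(2 * x[1] - x[(L + 1):2], x, 2 * x[n] - x[(n - 1):(n - L)])
  yp <- as.numeric(signal::filtfilt(bf, xp))
  yp[(L + 1):(L + n)]
}

#' Estimate a low-pass cutoff from the FFT power spectrum
#'
#' Returns the lowest frequency at which the cumulative one-sided power
#' spectrum (DC excluded) reaches the given fraction of the total signal
#' power.  Used to choose the Butterworth cutoff adaptively per channel.
#'
#' @param x numeric signal sampled at `fs` Hz, length >= 64.
#' @param fraction cumulative-power fraction in `(0, 1]` (default 0.99).
#' @param fs sampling rate in Hz (default 100).
#' @return estimated cutoff frequency in Hz.
#' @export
estimate_cutoff_fft <- function(x, fraction = 0.99, fs = 100) {
  if (length(x) < 64) stop("need at least 64 samples for a stable spectrum")
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  x <- x - mean(x)
  if (all(abs(x) < .Machine$double.eps * 10))
    stop("signal has no spectral content (constant or all zero)")
  n <- length(x)
  pw <- Mod(stats::fft(x))^2
  half <- pw[2:(floor(n / 2) + 1)]  # one-sided, DC excluded
  freqs <- (1:floor(n / 2)) * fs / n
  cum <- cumsum(half) / sum(half)
  freqs[which(cum >= fraction - 1e-12)[1]]
}

#' Partition a trial into a single gait cycle
#'
#' Slices all channels of a raw trial between two boundary gait events,
#' inclusive of both boundary samples.  Event times inside the slice are
#' re-expressed relative to the slice start.
#'
#' @param trial a `gait_trial` (or any list with the same fields).
#' @param mode `"IC_to_NIC"` (initial contact to next initial contact,
#'   stance-first; default) or `"ITO_to_NTO"` (toe off to next toe off,
#'   swing-first).
#' @return a `gait_slice`: channels restricted to the cycle plus the
#'   within-slice event sample indexes.
#' @export
partition_cycle <- function(trial, mode = c("IC_to_NIC", "ITO_to_NTO")) {
  mode <- match.arg(mode)
  ev <- trial$events
  bounds <- if (mode == "IC_to_NIC") c("t_IC", "t_NIC") else c("t_ITO", "t_NTO")
  if (!all(bounds %in% names(ev)) || any(is.na(ev[bounds])))
    stop(sprintf("trial lacks boundary events %s", paste(bounds, collapse = ", ")))
  from <- ev[[bounds[1]]]
  to <- ev[[bounds[2]]]
  if (to <= from) stop("boundary events must be strictly ordered")
  if (to - from < 10) stop("degenerate cycle: boundary events too close")
  keep <- from:to
  inside <- ev[ev >= from & ev <= to]
  slice <- list(
    time = trial$time[keep],
    vgrf_left = trial$vgrf_left[keep],
    vgrf_right = trial$vgrf_right[keep],
    theta_a = trial$theta_a[keep],
    theta_k = trial$theta_k[keep],
    theta_h = trial$theta_h[keep],
    events = inside - from + 1L,
    mode = mode,
    subject_id = trial$subject_id,
    trial_id = trial$trial_id
  )
  class(slice) <- "gait_slice"
  slice
}

#' Normalize a gait-cycle slice to the 0--100% phase grid
#'
#' Linearly resamples every channel of a single-cycle slice onto the
#' 101-point phase grid (0, 1, ..., 100% of the cycle) and maps event
#' sample indexes to percent indexes; the boundary events map exactly to
#' 0% and 100%.
#'
#' @param slice a `gait_slice` from [partition_cycle()].
#' @return a `gait_cycle` record: `phase` (0:100), stance-leg vGRF `f`,
#'   opposite-leg vGRF `f_prime`, angle channels `theta_a`, `theta_k`,
#'   `theta_h` (all length 101), and `events` in percent.
#' @export
normalize_cycle <- function(slice) {
  n <- length(slice$time)
  if (n < 2) stop("slice must contain at least 2 samples")
  if (any(diff(slice$time) <= 0)) stop("time vector must be strictly increasing")
  pos <- (seq_len(n) - 1) / (n - 1) * 100
  grid <- 0:100
  resample <- function(ch) stats::approx(pos, ch, xout = grid)$y
  events_pct <- (slice$events - 1) / (n - 1) * 100
  cyc <- list(
    phase = grid,
    f = resample(slice$vgrf_left),
    f_prime = resample(slice$vgrf_right),
    theta_a = resample(slice$theta_a),
    theta_k = resample(slice$theta_k),
    theta_h = resample(slice$theta_h),
    events = events_pct,
    mode = slice$mode,
    subject_id = slice$subject_id,
    trial_id = slice$trial_id
  )
  class(cyc) <- "gait_cycle"
  cyc
}

#' Filter, partition and normalize a cohort of raw trials
#'
#' Convenience wrapper running the full preprocessing chain on every
#' trial: zero-phase Butterworth low-pass filtering of all force and
#' angle channels (cutoff estimated per channel from the FFT spectrum
#' unless given), partition into one gait cycle, and normalization to the
#' 0--100% grid.
#'
#' @param cohort a `gait_cohort` or list of `gait_trial`s.
#' @param cutoff fixed cutoff in Hz, or `NULL` to estimate per channel
#'   with [estimate_cutoff_fft()].
#' @param filter if `FALSE`, skip filtering (useful for noiseless data).
#' @param mode cycle convention passed to [partition_cycle()].
#' @return list of `gait_cycle` records.
#' @export
preprocess_cohort <- function(cohort, cutoff = NULL, filter = TRUE,
                              mode = "IC_to_NIC") {
  lapply(cohort, function(trial) {
    if (filter) {
      for (ch in c("vgrf_left", "vgrf_right", "theta_a", "theta_k", "theta_h")) {
        co <- if (is.null(cutoff)) {
          # a first-order response is shallow: clamp the spectral estimate
          # so gait harmonics survive while high-frequency noise is cut
          min(max(estimate_cutoff_fft(trial[[ch]], fs = trial$fs), 10), 20)
        } else cutoff
        raw <- trial[[ch]]
        trial[[ch]] <- butterworth_lowpass(raw, co, fs = trial$fs)
        if (ch %in% c("vgrf_left", "vgrf_right")) {
          # the foot-off-ground constraint survives filtering: samples
          # with zero measured force stay exactly zero
          trial[[ch]][raw == 0] <- 0
          trial[[ch]] <- pmax(trial[[ch]], 0)
        }
      }
    }
    normalize_cycle(partition_cycle(trial, mode = mode))
  })
}
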