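#' Default parameters of the synthetic vGRF waveform
#'
#' The stance-phase vertical ground reaction force is modelled as the
#' classic double-bump ("M") shape: a loading-response peak near 13% of
#' the gait cycle and a push-off peak near 48%, riding on a mid-stance
#' plateau, tapered smoothly to zero at initial contact and toe-off.
#' Forces are expressed in body-weight (BW) units so no anthropometric
#' information is needed.
#'
#' @param peak1,peak2 heights of the loading and push-off peaks (BW).
#' @param t_peak1,t_peak2 peak locations (% of gait cycle).
#' @param width1,width2 Gaussian widths of the two bumps (% of cycle).
#' @param baseline mid-stance plateau level (BW).
#' @param toe_off stance-to-swing transition (% of cycle); force is exactly
#'   zero at and beyond this phase.
#' @param ramp length of the smooth taper at the edges of stance (%).
#' @return a named list of waveform parameters.
#' @export
vgrf_params <- function(peak1 = 1.10, peak2 = 1.15, t_peak1 = 13,
                        t_peak2 = 48, width1 = 6, width2 = 6,
                        baseline = 0.75, toe_off = 60, ramp = 6) {
  stopifnot(peak1 > 0, peak2 > 0, baseline > 0,
            toe_off > t_peak2, t_peak1 < t_peak2, ramp > 0)
  list(peak1 = peak1, peak2 = peak2, t_peak1 = t_peak1, t_peak2 = t_peak2,
       width1 = width1, width2 = width2, baseline = baseline,
       toe_off = toe_off, ramp = ramp)
}

#' Synthetic stance-phase vGRF waveform
#'
#' Evaluates the closed-form double-bump stance curve at the given gait
#' phase.  The force is exactly zero for phases at or beyond toe-off
#' (swing) and at phase 0 (contact onset), and continuous everywhere.
#'
#' @param phase gait phase in percent of the cycle, in `[0, 100]`;
#'   vectorized.
#' @param params waveform parameters from [vgrf_params()].
#' @return force in body-weight units, same length as `phase`.
#' @export
vgrf_waveform <- function(phase, params = vgrf_params()) {
  if (any(!is.finite(phase)) || any(phase < 0 | phase > 100))
    stop("`phase` must lie within [0, 100]")
  p <- params
  core <- p$baseline +
    (p$peak1 - p$baseline) * exp(-(phase - p$t_peak1)^2 / (2 * p$width1^2)) +
    (p$peak2 - p$baseline) * exp(-(phase - p$t_peak2)^2 / (2 * p$width2^2))
  # smooth taper: sin^2 ramps at both ends of stance, hard zero in swing
  w <- rep(1, length(phase))
  lo <- phase < p$ramp
  w[lo] <- sin(pi / 2 * pmax(phase[lo], 0) / p$ramp)^2
  hi <- phase > p$toe_off - p$ramp
  w[hi] <- sin(pi / 2 * pmax(p$toe_off - phase[hi], 0) / p$ramp)^2
  w[phase >= p$toe_off | phase <= 0] <- 0
  core * w
}

# Order-4 Fourier coefficients (period 100%) of the normative sagittal
# angle curves: constant, then cos/sin pairs for harmonics 1..4.  The
# curves are periodic by construction and stay well inside the published
# normative 95% CI envelopes (ankle [-24.8, 16.1], knee [-4.9, 72.4],
# hip [-24.1, 33.2] degrees).
.angle_fourier <- list(
  ankle = c(-0.486647, 0.194662, 5.880028, 0.273428, -6.638012,
            -1.525532, 0.265061, 1.303195, -0.508339),
  knee = c(20.342910, 1.876853, -19.315635, -15.907503, 4.326141,
           0.186749, 4.546432, -0.619150, -0.905811),
  hip = c(11.648685, 17.262501, -2.054609, -2.960497, -1.800372,
          0.172444, 0.444370, -0.179134, -0.042096)
)

#' Normative sagittal joint-angle template
#'
#' Smooth periodic template of the ankle, knee or hip sagittal angle over
#' the normalized gait cycle, built from a truncated (order-4) Fourier
#' series.  Dorsiflexion/flexion is positive.  Each template lies inside
#' the normative 95% confidence envelope for that joint.
#'
#' @param joint one of `"ankle"`, `"knee"`, `"hip"`.
#' @param phase gait phase in percent, in `[0, 100]`; vectorized.
#' @return angle in degrees, same length as `phase`.
#' @export
normative_angle_template <- function(joint, phase) {
  joint <- match.arg(joint, c("ankle", "knee", "hip"))
  if (any(!is.finite(phase)) || any(phase < 0 | phase > 100))
    stop("`phase` must lie within [0, 100]")
  cf <- .angle_fourier[[joint]]
  v <- rep(cf[1], length(phase))
  for (h in 1:4) {
    v <- v + cf[2 * h] * cos(2 * pi * h * phase / 100) +
      cf[2 * h + 1] * sin(2 * pi * h * phase / 100)
  }
  v
}

# draw one subject's latent gait parameters; the single latent force
# amplitude drives both the vGRF peaks and the angle excursions so that a
# deterministic vGRF -> angle mapping exists across the cohort
.draw_subject <- function(subject_id, base_params) {
  a_force <- min(max(rnorm(1, 1, 0.04), 0.90), 1.10)
  list(
    subject_id = subject_id,
    cadence_scale = runif(1, 0.9, 1.1),
    force_scale = a_force,
    # angle excursion scale coupled to the force amplitude (plus a small
    # idiosyncratic term), kept within the normative envelope
    angle_scales = vapply(c("ankle", "knee", "hip"), function(j) {
      min(max(0.55 + 0.45 * a_force + rnorm(1, 0, 0.02), 0.85), 1.10)
    }, numeric(1)),
    # subject-level timing shifts (% of cycle), |shift| <= 3
    toe_off_offset = min(max(rnorm(1, 0, 1), -3), 3),
    phase_offset = min(max(rnorm(1, 0, 0.8), -3), 3)
  )
}

.synthesize_trial <- function(subject, trial_id, noise_sd, trial_jitter,
                              base_params, fs = 100, angle_noise_ratio = 10) {
  base_len <- 110  # samples per cycle at cadence_scale 1 (1.1 s at 100 Hz)
  jit <- if (trial_jitter > 0) rnorm(1, 0, trial_jitter / 100) else 0
  cycle_len <- max(60, round_half_up(base_len * subject$cadence_scale * (1 + jit)))
  toe_jit <- if (trial_jitter > 0) rnorm(1, 0, trial_jitter) else 0
  toe_off <- min(max(60 + subject$toe_off_offset + toe_jit, 55), 65)

  pars <- base_params
  pars$peak1 <- pars$peak1 * subject$force_scale
  pars$peak2 <- pars$peak2 * subject$force_scale
  pars$toe_off <- toe_off

  pad <- 8L
  t_ic <- pad + 1L
  t_nic <- t_ic + cycle_len
  n <- t_nic + pad
  idx <- seq_len(n)
  ph <- (idx - t_ic) / cycle_len * 100
  ph_mod <- ph %% 100

  f_ipsi <- vgrf_waveform(ph_mod, pars)
  f_contra <- vgrf_waveform((ph_mod + 50) %% 100, pars)

  shift <- subject$phase_offset
  ang <- lapply(c(ankle = "ankle", knee = "knee", hip = "hip"), function(j) {
    tmpl <- normative_angle_template(j, (ph_mod - shift) %% 100)
    c0 <- .angle_fourier[[j]][1]
    c0 + subject$angle_scales[[j]] * (tmpl - c0)
  })

  if (noise_sd > 0) {
    add_force_noise <- function(f) {
      on_ground <- f > 0
      f[on_ground] <- pmax(f[on_ground] + rnorm(sum(on_ground), 0, noise_sd),
                           1e-6)
      f
    }
    f_ipsi <- add_force_noise(f_ipsi)
    f_contra <- add_force_noise(f_contra)
    ang <- lapply(ang, function(a) a + rnorm(n, 0, noise_sd * angle_noise_ratio))
  }

  t_ito <- t_ic + round_half_up(toe_off / 100 * cycle_len)
  trial <- list(
    subject_id = subject$subject_id,
    trial_id = trial_id,
    fs = fs,
    time = (idx - 1) / fs,
    vgrf_left = f_ipsi,
    vgrf_right = f_contra,
    theta_a = ang$ankle,
    theta_k = ang$knee,
    theta_h = ang$hip,
    events = c(t_IC = t_ic, t_ITO = t_ito, t_NTO = t_ito + 1L, t_NIC = t_nic),
    toe_off_pct = toe_off
  )
  class(trial) <- "gait_trial"
  trial
}

#' Generate a synthetic cohort of paired kinetic/kinematic gait trials
#'
#' Simulates `n_subjects * trials_per_subject` walking trials sampled at
#' 100 Hz.  Each subject draws latent gait parameters (cadence, force
#' amplitude, angle excursion, timing offsets); the same latent amplitude
#' shapes both the vGRF peaks and the joint-angle excursions, so a
#' learnable vGRF-to-angle mapping exists across the cohort.  Trials of
#' the same subject differ by timing jitter (controlled by
#' `trial_jitter`) and additive measurement noise (`noise_sd`).  Noise is
#' applied to the vGRF only where the foot is on the ground, so swing
#' samples remain exactly zero.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param trials_per_subject walking trials per subject (>= 1).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param noise_sd standard deviation of vGRF measurement noise in
#'   body-weight units; angle noise is `10 * noise_sd` degrees.
#' @param trial_jitter trial-level timing jitter (% of cycle); set to 0
#'   to make repeat trials of a subject identical when `noise_sd = 0`.
#' @param params base vGRF waveform parameters, see [vgrf_params()].
#' @return an object of class `gait_cohort`: a list of `gait_trial`
#'   objects with `seed` and `params` attributes.
#' @export
generate_cohort <- function(n_subjects, trials_per_subject, seed,
                            noise_sd = 0.02, trial_jitter = 0.5,
                            params = vgrf_params()) {
  stopifnot(n_subjects >= 1, trials_per_subject >= 1, is.finite(seed))
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (trial_jitter < 0) stop("`trial_jitter` must be non-negative")
  trials <- with_seed(seed, {
    out <- vector("list", n_subjects * trials_per_subject)
    k <- 1L
    for (s in seq_len(n_subjects)) {
      subject <- .draw_subject(s, params)
      for (tr in seq_len(trials_per_subject)) {
        out[[k]] <- .synthesize_trial(subject, tr, noise_sd, trial_jitter,
                                      params)
        k <- k + 1L
      }
    }
    out
  })
  structure(trials, class = "gait_cohort", seed = seed, params = params,
            noise_sd = noise_sd, trial_jitter = trial_jitter)
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials (%d subjects), seed %s\n",
              length(x), length(unique(vapply(x, `[[`, 1, "subject_id"))),
              format(attr(x, "seed"))))
  invisible(x)
}

#' Validate the structural invariants of a raw gait trial
#'
#' Checks that the trial is sampled at 100 Hz, that event times are
#' strictly increasing, and that the stance-leg vGRF is exactly zero
#' throughout the swing interval and positive in the interior of stance.
#'
#' @param trial a `gait_trial` object.
#' @return `TRUE` invisibly; errors describe any violated invariant.
#' @export
validate_trial <- function(trial) {
  stopifnot(inherits(trial, "gait_trial"))
  if (trial$fs != 100) stop("sampling rate must be exactly 100 Hz")
  ev <- trial$events
  if (any(diff(ev) <= 0)) stop("event times must be strictly increasing")
  n_chan <- lengths(trial[c("time", "vgrf_left", "vgrf_right",
                            "theta_a", "theta_k", "theta_h")])
  if (length(unique(n_chan)) != 1L) stop("channel lengths differ")
  cyc <- ev[["t_NIC"]] - ev[["t_IC"]]
  ph <- (seq_along(trial$time) - ev[["t_IC"]]) / cyc * 100
  swing <- ph %% 100 >= trial$toe_off_pct
  if (any(trial$vgrf_left[swing] != 0))
    stop("stance-leg vGRF must be exactly zero during swing")
  stance_int <- ph %% 100 > 1 & ph %% 100 < trial$toe_off_pct - 1
  if (any(trial$vgrf_left[stance_int] <= 0))
    stop("stance-leg vGRF must be positive during stance")
  invisible(TRUE)
}
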