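#' Default pre-defined primary gait event indexes
#'
#' Percent-of-cycle indexes for the five primary gait events that are not
#' measured directly: Opposite Toe Off (OTO), Heel Rise (HR), Opposite
#' Initial Contact (OIC), Feet Adjustment (FA), and Tibia Vertical (TV).
#' Defaults follow standard normative gait-phase boundaries and are
#' configurable per cohort.
#'
#' @return named numeric vector of percent indexes.
#' @export
default_predefined_events <- function() {
  c(OTO = 10, HR = 30, OIC = 50, FA = 73, TV = 87)
}

# the seven sub-phases hosting the 13 intermediate events, bounded by
# consecutive primary events; n = number of intermediate events inside
.subphases <- data.frame(
  i = 1:7,
  label = c("LR", "MST", "TST", "PSW", "ISW", "MSW", "TSW"),
  start = c("IC", "OTO", "HR", "OIC", "NTO", "FA", "TV"),
  end = c("OTO", "HR", "OIC", "ITO", "FA", "TV", "NIC"),
  n = c(1L, 2L, 2L, 1L, 2L, 3L, 2L),
  stringsAsFactors = FALSE
)

# feature slots: primary events occupy m in {1,3,6,9,11,12,15,19,22};
# intermediate events fill the remaining 13 slots in cycle order
.main_slots <- c(IC = 1L, OTO = 3L, HR = 6L, OIC = 9L, ITO = 11L,
                 NTO = 12L, FA = 15L, TV = 19L, NIC = 22L)
.intermediate_slots <- list(
  LR = 2L, MST = c(4L, 5L), TST = c(7L, 8L), PSW = 10L,
  ISW = c(13L, 14L), MSW = c(16L, 17L, 18L), TSW = c(20L, 21L)
)

#' Sub-phase definitions of the gait-intervals scheme
#'
#' @return data frame of the seven sub-phases (Loading Response, Mid and
#'   Terminal Stance, Pre/Initial/Mid/Terminal Swing) with their bounding
#'   primary events and intermediate-event counts (total 13).
#' @export
subphase_specs <- function() .subphases

#' Split a common gait event into pre and post events
#'
#' When a cycle begins and ends on the same foot, the stance-to-swing
#' transition hosts two coincident events (initial and next toe off, or
#' initial and next contact for swing-first cycles).  The shared index is
#' shifted by one percent in each direction to yield two distinct
#' neighbouring events.
#'
#' @param t_common percent index of the shared event, in `[1, 99]`.
#' @return numeric vector `c(pre = t - 1, post = t + 1)`.
#' @export
split_common_event <- function(t_common) {
  if (length(t_common) != 1 || !is.finite(t_common))
    stop("`t_common` must be a single finite index")
  if (t_common < 1 || t_common > 99)
    stop("common event at the grid boundary cannot be split")
  c(pre = t_common - 1, post = t_common + 1)
}

#' Step size between intermediate events of a sub-phase
#'
#' The interval between the bounding primary events is divided into
#' `n + 1` equal steps; intermediate events sit at multiples of this step
#' from the sub-phase start.
#'
#' @param t_start,t_end percent indexes of the bounding primary events.
#' @param n number of intermediate events in the sub-phase (>= 1).
#' @return the step size in percent of the gait cycle.
#' @export
intermediate_step_size <- function(t_start, t_end, n) {
  if (n < 1) stop("`n` must be at least 1")
  if (t_end <= t_start) stop("sub-phase must have positive width")
  (t_end - t_start) / (n + 1)
}

#' Resolve intermediate event indexes within a sub-phase
#'
#' Places the k-th intermediate event at `t_start + k * b` (with `b` the
#' step size), snapped to the nearest integer grid index (ties round up)
#' inside the one-percent buffer around the exact position.
#'
#' @inheritParams intermediate_step_size
#' @return integer vector of `n` percent indexes.
#' @export
resolve_intermediate_events <- function(t_start, t_end, n) {
  b <- intermediate_step_size(t_start, t_end, n)
  raw <- t_start + seq_len(n) * b
  snapped <- round_half_up(raw)
  # nearest-integer snapping always lands inside the +/- 1 buffer
  pmin(pmax(snapped, ceiling(raw - 1)), floor(raw + 1))
}

#' Resolve the nine primary gait events of a cycle
#'
#' IC, ITO, NTO and NIC come from the cycle's measured event indexes;
#' OTO, HR, OIC, FA and TV come from the pre-defined map, snapped to the
#' integer grid within their one-percent buffer.  If the measured initial
#' and next toe off coincide (or sit on adjacent raw frames), the shared
#' toe-off instant is split into pre/post events via
#' [split_common_event()].
#'
#' @param cycle a `gait_cycle` record.
#' @param predefined named percent map covering OTO, HR, OIC, FA, TV.
#' @return data frame with columns `label`, `t` (integer percent) and
#'   `source`, ordered by `t`.
#' @export
resolve_main_events <- function(cycle, predefined = default_predefined_events()) {
  need <- c("OTO", "HR", "OIC", "FA", "TV")
  if (!all(need %in% names(predefined)))
    stop(sprintf("predefined map must cover %s", paste(need, collapse = ", ")))
  ev <- cycle$events
  if (!all(c("t_IC", "t_ITO", "t_NTO", "t_NIC") %in% names(ev)))
    stop("cycle lacks measured events t_IC, t_ITO, t_NTO, t_NIC")
  t_ic <- round_half_up(ev[["t_IC"]])
  t_nic <- round_half_up(ev[["t_NIC"]])
  t_ito <- ev[["t_ITO"]]
  t_nto <- ev[["t_NTO"]]
  if (round_half_up(t_nto) - round_half_up(t_ito) < 2) {
    # coincident toe-off: one physical event shared by stance and swing
    tc <- round_half_up((t_ito + t_nto) / 2)
    pp <- split_common_event(tc)
    t_ito <- pp[["pre"]]
    t_nto <- pp[["post"]]
  } else {
    t_ito <- round_half_up(t_ito)
    t_nto <- round_half_up(t_nto)
  }
  out <- data.frame(
    label = c("IC", "OTO", "HR", "OIC", "ITO", "NTO", "FA", "TV", "NIC"),
    t = c(t_ic, round_half_up(predefined[["OTO"]]),
          round_half_up(predefined[["HR"]]), round_half_up(predefined[["OIC"]]),
          t_ito, t_nto, round_half_up(predefined[["FA"]]),
          round_half_up(predefined[["TV"]]), t_nic),
    source = c("measured", "predefined", "predefined", "predefined",
               "measured", "measured", "predefined", "predefined", "measured"),
    stringsAsFactors = FALSE
  )
  out[order(out$t), , drop = FALSE]
}

#' Shift duplicate schedule indexes until all are unique
#'
#' Scanning in ascending feature number, any index equal to an earlier
#' one is shifted by +1 percent repeatedly until it no longer collides.
#' Errors if a shift would leave the 0--100 grid or break the strictly
#' increasing order of the schedule.
#'
#' @param schedule a `gi_schedule` data frame (may contain duplicates).
#' @return the deduplicated schedule.
#' @export
dedupe_indexes <- function(schedule) {
  t <- schedule$t
  for (m in seq_along(t)) {
    while (m > 1 && t[m] %in% t[seq_len(m - 1)]) {
      t[m] <- t[m] + 1L
      if (t[m] > 100) stop("duplicate shift escaped the 0-100 grid")
    }
  }
  schedule$t <- t
  if (any(diff(schedule$t) <= 0))
    stop("deduplication broke the event ordering; cycle unresolvable")
  schedule
}

#' Build the full 22-event schedule of a normalized gait cycle
#'
#' Resolves the nine primary events (measured + pre-defined), splits the
#' shared toe-off event, fills the seven sub-phases with their 13
#' intermediate events, and removes duplicate indexes.  The result is 22
#' strictly increasing, unique percent indexes: stance-leg features for
#' feature numbers 1--11 and swing-leg features for 12--22.
#'
#' @inheritParams resolve_main_events
#' @return a `gi_schedule` data frame with columns `m` (feature number),
#'   `label`, `t` (percent index), `kind` (`main`/`intermediate`) and
#'   `leg` (`stance`/`swing`).
#' @export
build_event_schedule <- function(cycle,
                                 predefined = default_predefined_events()) {
  if (!is.null(cycle$mode) && cycle$mode != "IC_to_NIC")
    stop("schedules are built on IC-origin cycles; rotate swing-first cycles first")
  main <- resolve_main_events(cycle, predefined)
  tm <- stats::setNames(main$t, main$label)
  entries <- data.frame(m = unname(.main_slots),
                        label = names(.main_slots),
                        t = unname(tm[names(.main_slots)]),
                        kind = "main", stringsAsFactors = FALSE)
  for (r in seq_len(nrow(.subphases))) {
    sp <- .subphases[r, ]
    ts <- resolve_intermediate_events(tm[[sp$start]], tm[[sp$end]], sp$n)
    labs <- if (sp$n == 1) sp$label else paste0(sp$label, seq_len(sp$n))
    entries <- rbind(entries, data.frame(m = .intermediate_slots[[sp$label]],
                                         label = labs, t = ts,
                                         kind = "intermediate",
                                         stringsAsFactors = FALSE))
  }
  entries <- entries[order(entries$m), , drop = FALSE]
  rownames(entries) <- NULL
  entries$leg <- ifelse(entries$m <= 11, "stance", "swing")
  entries <- dedupe_indexes(entries)
  if (any(entries$t < 0 | entries$t > 100)) stop("schedule index outside grid")
  entries$t <- as.integer(entries$t)
  entries$m <- as.integer(entries$m)
  class(entries) <- c("gi_schedule", "data.frame")
  entries
}

#' Extract the 22 vGRF features of a cycle
#'
#' Stance-phase features (feature numbers 1--11) are the stance-leg vGRF
#' at the scheduled indexes.  Swing-phase features (12--22) are taken
#' from the opposite-leg vGRF — the swing foot itself is off the ground —
#' and multiplied by -1 so they cannot clash with stance-phase patterns.
#'
#' @param cycle a `gait_cycle` record.
#' @param schedule its `gi_schedule`.
#' @return named numeric vector of 22 features (body-weight units).
#' @export
extract_features <- function(cycle, schedule) {
  t <- schedule$t
  if (any(t < 0 | t > 100)) stop("schedule index outside the phase grid")
  vals <- ifelse(schedule$m <= 11, cycle$f[t + 1], -cycle$f_prime[t + 1])
  stats::setNames(vals, schedule$label)
}

#' Extract the 66 joint-angle targets of a cycle
#'
#' Samples the ankle, knee and hip angle channels at every scheduled
#' event index and concatenates the three blocks (ankle rows 1--22, knee
#' 23--44, hip 45--66).
#'
#' @inheritParams extract_features
#' @return named numeric vector of 66 target angles (degrees).
#' @export
extract_targets <- function(cycle, schedule) {
  t <- schedule$t
  if (any(t < 0 | t > 100)) stop("schedule index outside the phase grid")
  vals <- c(cycle$theta_a[t + 1], cycle$theta_k[t + 1], cycle$theta_h[t + 1])
  stats::setNames(vals, paste(rep(c("ankle", "knee", "hip"), each = 22),
                              rep(schedule$label, 3), sep = "_"))
}

#' Assemble feature and target matrices from per-cycle vectors
#'
#' @param features list of 22-vectors (one per sample).
#' @param targets list of 66-vectors, same length.
#' @return list with `x` (22 x n) and `y` (66 x n); columns are samples
#'   in input order.
#' @export
assemble_matrices <- function(features, targets) {
  if (length(features) == 0) stop("no samples to assemble")
  if (length(features) != length(targets))
    stop("feature and target lists differ in length")
  if (any(lengths(features) != 22)) stop("every feature vector must have 22 entries")
  if (any(lengths(targets) != 66)) stop("every target vector must have 66 entries")
  list(x = do.call(cbind, features), y = do.call(cbind, targets))
}

#' Run gait-intervals feature selection over a set of cycles
#'
#' Builds the event schedule and extracts the 22 vGRF features and 66
#' angle targets for each normalized cycle, assembling the design
#' matrices used for network training.
#'
#' @param cycles list of `gait_cycle` records.
#' @param predefined pre-defined primary event map.
#' @return list with `x` (22 x n), `y` (66 x n) and `schedules` (one
#'   `gi_schedule` per sample).
#' @export
gi_transform <- function(cycles, predefined = default_predefined_events()) {
  schedules <- lapply(cycles, build_event_schedule, predefined = predefined)
  feats <- Map(extract_features, cycles, schedules)
  targs <- Map(extract_targets, cycles, schedules)
  c(assemble_matrices(feats, targs), list(schedules = schedules))
}
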