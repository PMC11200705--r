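# From raw recordings to left gait-cycle windows:
# 1 Hz zero-phase high-pass on acceleration -> combined ankle acceleration ->
# one-sample differentiation -> periodic-peak initial contacts -> walking
# phases (TUG sub-phase detection from lumbar angular velocity; first/last
# cycle exclusion for the 10-m walk) -> per-cycle 48-channel windows.
#
# Conventions: 1-based sample indices; all windows/phases are half-open
# [start, end).

#' High-pass filter the acceleration channels of a recording
#'
#' Removes the gravitational component with a zero-phase 4th-order
#' Butterworth high-pass (default cutoff 1 Hz). Angular-velocity channels
#' pass through untouched.
#'
#' @param recording an [imu_recording()].
#' @param cutoff_hz high-pass cutoff in Hz.
#' @param order filter order.
#' @return The recording with filtered acceleration channels.
#' @export
highpass_acceleration <- function(recording, cutoff_hz = 1.0, order = 4L) {
  stopifnot(inherits(recording, "imu_recording"))
  if (cutoff_hz >= recording$sample_rate_hz / 2)
    stop("cutoff_hz must be below the Nyquist frequency")
  f <- butter_highpass(order, cutoff_hz, recording$sample_rate_hz)
  for (site in sensor_sites()) {
    for (j in 1:3) {
      recording$data[[site]][, j] <-
        filtfilt(f$b, f$a, recording$data[[site]][, j])
    }
  }
  recording
}

#' Combined (resultant) acceleration
#'
#' Euclidean norm of the three acceleration axes, sample by sample.
#'
#' @param acc_x,acc_y,acc_z numeric vectors of equal length, or `acc_x` may
#'   be an `n x 3` matrix with the other arguments missing.
#' @return Nonnegative numeric vector.
#' @export
combined_acceleration <- function(acc_x, acc_y = NULL, acc_z = NULL) {
  if (is.matrix(acc_x) && is.null(acc_y)) {
    stopifnot(ncol(acc_x) == 3L)
    acc_y <- acc_x[, 2L]; acc_z <- acc_x[, 3L]; acc_x <- acc_x[, 1L]
  }
  if (length(acc_y) != length(acc_x) || length(acc_z) != length(acc_x))
    stop("acceleration axes must have equal length")
  sqrt(acc_x^2 + acc_y^2 + acc_z^2)
}

#' Detect initial contacts from ankle acceleration
#'
#' The combined acceleration of the ankle is differentiated over one sample
#' and its periodic peaks are taken as initial contacts. Peaks must be
#' separated by at least `min_separation_s` and reach a prominence of
#' `prominence_factor` times the robust standard deviation
#' (1.4826 * median absolute deviation) of the differentiated series, which
#' makes detection invariant to overall amplitude scaling.
#'
#' @param acc `n x 3` matrix of high-pass-filtered ankle acceleration (or an
#'   [imu_recording()] together with `site`).
#' @param sample_rate_hz sampling rate in Hz (taken from the recording if one
#'   is supplied).
#' @param site ankle site name when `acc` is a recording.
#' @param min_separation_s minimum inter-contact interval, seconds.
#' @param prominence_factor prominence floor as a multiple of the robust SD.
#' @param height_fraction periodic-peak criterion: a peak must reach this
#'   fraction of the reference peak height (the median of the five tallest
#'   candidates — robust to a single artifact spike and to noise candidates
#'   from still periods), which separates the once-per-cycle contact
#'   transient from smaller within-cycle maxima without reference to an
#'   absolute amplitude.
#' @param periodicity_fraction second periodic-peak criterion: whenever two
#'   accepted peaks lie closer than this fraction of the median inter-peak
#'   gap, the smaller of the pair is discarded. This enforces the observed
#'   gait rhythm itself instead of a fixed time constant, so it adapts to
#'   each subject's cadence.
#' @return Strictly increasing integer vector of IC sample indices.
#' @export
detect_initial_contacts <- function(acc, sample_rate_hz = NULL,
                                    site = "left_ankle",
                                    min_separation_s = 0.6,
                                    prominence_factor = 0.3,
                                    height_fraction = 0.4,
                                    periodicity_fraction = 0.6) {
  if (inherits(acc, "imu_recording")) {
    sample_rate_hz <- acc$sample_rate_hz
    acc <- acc$data[[match.arg(site, sensor_sites())]][, 1:3, drop = FALSE]
  }
  stopifnot(is.matrix(acc), ncol(acc) == 3L, !is.null(sample_rate_hz))
  if (nrow(acc) < ceiling(min_separation_s * sample_rate_hz))
    stop("recording shorter than one expected gait cycle")
  ca <- combined_acceleration(acc)
  d <- diff(ca)
  sd_rob <- stats::mad(d)
  if (sd_rob == 0) return(integer(0))
  cand <- find_peaks(d, min_distance = round(min_separation_s * sample_rate_hz),
                     min_prominence = prominence_factor * sd_rob)
  if (length(cand) > 2L) {
    top <- sort(d[cand], decreasing = TRUE)
    ref <- stats::median(top[seq_len(min(5L, length(top)))])
    cand <- cand[d[cand] >= height_fraction * ref]
  }
  # periodicity cleanup: drop the smaller of any pair of peaks whose gap
  # breaks the subject's own rhythm
  while (length(cand) > 2L) {
    gaps <- diff(cand)
    short <- which(gaps < periodicity_fraction * stats::median(gaps))
    if (!length(short)) break
    i <- short[1L]
    drop <- if (d[cand[i]] < d[cand[i + 1L]]) i else i + 1L
    cand <- cand[-drop]
  }
  cand
}

# expand from an anchor over the contiguous region where |x|/max|x| >= thr;
# returns (start, end) half-open, where start is the last sample below the
# threshold before the anchor and end the first below it after
.threshold_interval <- function(x_norm, anchor, thr) {
  s <- anchor
  while (s > 1L && abs(x_norm[s - 1L]) >= thr) s <- s - 1L
  e <- anchor
  n <- length(x_norm)
  while (e < n && abs(x_norm[e + 1L]) >= thr) e <- e + 1L
  c(max(1L, s - 1L), min(n, e + 1L))
}

#' Segment a TUG recording into its six sub-phases
#'
#' Sit-to-stand and stand-to-sit are anchored at the global maximum and
#' minimum of the lumbar pitch angular velocity; the two turns at the two
#' largest absolute yaw values between them. Each phase interval is the
#' contiguous region around its anchor where the channel, unit-normalized by
#' its maximum absolute value within the trial, stays at or above
#' `threshold`. The two walking phases span the gaps: sit-to-stand end to
#' first-turn start, and first-turn end to second-turn start.
#'
#' @param recording a TUG [imu_recording()], or an `n x 2` matrix of lumbar
#'   `(pitch, yaw)` angular velocity with `sample_rate_hz` given.
#' @param sample_rate_hz sampling rate in Hz.
#' @param threshold dimensionless boundary threshold (default 0.1).
#' @return A [tug_phases()] object.
#' @export
segment_tug_phases <- function(recording, sample_rate_hz = NULL,
                               threshold = 0.1) {
  if (inherits(recording, "imu_recording")) {
    sample_rate_hz <- recording$sample_rate_hz
    lb <- recording$data[["lower_back"]]
    pitch <- lb[, "gyr_pitch"]; yaw <- lb[, "gyr_yaw"]
  } else {
    stopifnot(is.matrix(recording), ncol(recording) == 2L)
    pitch <- recording[, 1L]; yaw <- recording[, 2L]
  }
  pitch_n <- pitch / max(abs(pitch))
  yaw_n <- yaw / max(abs(yaw))
  a_sts <- which.max(pitch)
  a_sit <- which.min(pitch)
  if (a_sts >= a_sit)
    stop("pitch maximum (sit-to-stand) must precede pitch minimum (stand-to-sit)")
  sts <- .threshold_interval(pitch_n, a_sts, threshold)
  sit <- .threshold_interval(pitch_n, a_sit, threshold)
  # turns: two largest |yaw| anchors between the pitch events
  yaw_mid <- abs(yaw_n)
  yaw_mid[seq_len(sts[2L])] <- 0
  yaw_mid[sit[1L]:length(yaw_mid)] <- 0
  a_t1 <- which.max(yaw_mid)
  if (yaw_mid[a_t1] < threshold) stop("no yaw turning burst found")
  t1 <- .threshold_interval(yaw_n, a_t1, threshold)
  yaw_mid[t1[1L]:t1[2L]] <- 0
  a_t2 <- which.max(yaw_mid)
  if (yaw_mid[a_t2] < threshold) stop("fewer than two yaw turning bursts found")
  t2 <- .threshold_interval(yaw_n, a_t2, threshold)
  if (a_t2 < a_t1) { tmp <- t1; t1 <- t2; t2 <- tmp }
  tug_phases(sit_to_stand = sts, turn1 = t1, turn2 = t2, stand_to_sit = sit)
}

#' Extract the walking intervals of a trial
#'
#' For the 10-m walk test the whole trial is walking, minus the first and
#' last detected gait cycle (the analysis unit), so the interval runs from
#' the second IC to the second-to-last. For the TUG, the two walking
#' sub-phases are returned.
#'
#' @param recording an [imu_recording()].
#' @param phases [tug_phases()] for TUG trials, `NULL` for 10MWT.
#' @param ic initial contacts of the analyzed side for 10MWT trials
#'   (detected with [detect_initial_contacts()] if omitted; the recording
#'   must then already be high-pass filtered).
#' @param side side used for the 10MWT first/last-cycle exclusion.
#' @return List of half-open `(start, end)` integer intervals.
#' @export
extract_walking_intervals <- function(recording, phases = NULL, ic = NULL,
                                      side = "left") {
  stopifnot(inherits(recording, "imu_recording"))
  if (recording$trial_type == "TUG") {
    if (is.null(phases)) phases <- segment_tug_phases(recording)
    return(list(phases$walk1, phases$walk2))
  }
  if (is.null(ic)) {
    ankle <- paste0(match.arg(side, c("left", "right")), "_ankle")
    ic <- detect_initial_contacts(recording, site = ankle)
  }
  if (length(ic) < 4L)
    stop("10MWT trial with fewer than 3 detected gait cycles")
  list(c(ic[2L], ic[length(ic) - 1L]))
}

#' Slice gait-cycle windows out of walking intervals
#'
#' One window per consecutive pair of same-side initial contacts that both
#' fall inside a single walking interval; the window carries all 48 channels
#' on `[IC_i, IC_{i+1})`.
#'
#' @param recording an [imu_recording()] (high-pass filtered).
#' @param intervals list of half-open walking intervals.
#' @param side `"left"` (default, the analyzed side) or `"right"`.
#' @param ic precomputed IC indices for that side (detected if omitted).
#' @return List of `gait_cycle` windows (possibly empty), each with fields
#'   `subject_id`, `trial_type`, `trial_index`, `side`, `start`, `end`,
#'   `label` and the `length x 48` matrix `data`.
#' @export
extract_gait_cycles <- function(recording, intervals, side = "left",
                                ic = NULL) {
  stopifnot(inherits(recording, "imu_recording"))
  side <- match.arg(side, c("left", "right"))
  if (is.null(ic))
    ic <- detect_initial_contacts(recording, site = paste0(side, "_ankle"))
  full <- recording_matrix(recording)
  windows <- list()
  for (iv in intervals) {
    inside <- ic[ic >= iv[1L] & ic <= iv[2L]]
    if (length(inside) < 2L) next
    for (i in seq_len(length(inside) - 1L)) {
      s <- inside[i]; e <- inside[i + 1L]
      windows[[length(windows) + 1L]] <- structure(
        list(subject_id = recording$subject_id,
             trial_type = recording$trial_type,
             trial_index = recording$trial_index,
             side = side, start = s, end = e,
             data = full[s:(e - 1L), , drop = FALSE],
             label = recording$label),
        class = "gait_cycle")
    }
  }
  windows
}

#' Segment one recording end to end
#'
#' Convenience wrapper: high-pass filtering, IC detection, TUG sub-phase
#' segmentation (for TUG trials), walking-interval extraction and gait-cycle
#' slicing.
#'
#' @param recording an [imu_recording()] (raw).
#' @param side analyzed side.
#' @param ... passed to [detect_initial_contacts()].
#' @return List of `gait_cycle` windows.
#' @export
segment_recording <- function(recording, side = "left", ...) {
  rec <- highpass_acceleration(recording)
  ic <- detect_initial_contacts(rec, site = paste0(side, "_ankle"), ...)
  phases <- if (rec$trial_type == "TUG") segment_tug_phases(rec) else NULL
  intervals <- extract_walking_intervals(rec, phases = phases, ic = ic,
                                         side = side)
  extract_gait_cycles(rec, intervals, side = side, ic = ic)
}

#' Segment every recording of a cohort
#'
#' Pools the left gait-cycle windows of all of each subject's trials.
#' Subjects whose TUG trials are absent contribute 10MWT windows only; no
#' subject is dropped. Trials whose segmentation fails raise an error unless
#' `skip_failures = TRUE`.
#'
#' @param cohort an `imu_cohort`.
#' @param side analyzed side.
#' @param skip_failures if `TRUE`, trials that cannot be segmented are
#'   skipped with a warning instead of failing the whole cohort.
#' @param ... passed to [segment_recording()].
#' @return List of `gait_cycle` windows across all subjects, with a
#'   `cycle_counts` attribute (data frame subject/label/n_cycles).
#' @export
segment_cohort <- function(cohort, side = "left", skip_failures = FALSE, ...) {
  windows <- list()
  for (subj in cohort) {
    for (rec in subj$recordings) {
      w <- if (skip_failures) {
        tryCatch(segment_recording(rec, side = side, ...),
                 error = function(e) {
                   warning(sprintf("skipping %s %s trial %d: %s",
                                   subj$subject_id, rec$trial_type,
                                   rec$trial_index, conditionMessage(e)))
                   list()
                 })
      } else segment_recording(rec, side = side, ...)
      windows <- c(windows, w)
    }
  }
  subj_ids <- vapply(windows, `[[`, character(1), "subject_id")
  labels <- vapply(windows, `[[`, character(1), "label")
  counts <- as.data.frame(table(subject_id = subj_ids), stringsAsFactors = FALSE)
  names(counts)[2L] <- "n_cycles"
  counts$label <- labels[match(counts$subject_id, subj_ids)]
  attr(windows, "cycle_counts") <- counts
  windows
}
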