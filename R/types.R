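#' Construct a single-trial IMU recording
#'
#' An `imu_recording` holds one trial's synchronized data from all eight
#' sensor sites: per site an `n x 6` matrix with columns
#' `acc_x, acc_y, acc_z` (g) and `gyr_roll, gyr_pitch, gyr_yaw` (deg/s).
#'
#' @param subject_id character subject identifier.
#' @param trial_type `"10MWT"` or `"TUG"`.
#' @param trial_index integer >= 1.
#' @param sample_rate_hz sampling rate in Hz (default 120).
#' @param data named list of 8 numeric matrices (one per site, canonical
#'   names from [sensor_sites()]), all with 6 columns and equal row count.
#' @param truth optional ground-truth annotation (synthetic data only): list
#'   with `ic_left`, `ic_right` (1-based sample indices) and, for TUG trials,
#'   `tug_phases`.
#' @param label optional group label, `"WA"` or `"NA"`.
#' @return Object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, trial_type, trial_index,
                          sample_rate_hz = 120, data, truth = NULL,
                          label = NULL) {
  trial_type <- match.arg(trial_type, c("10MWT", "TUG"))
  stopifnot(is.numeric(trial_index), trial_index >= 1,
            sample_rate_hz > 0, is.list(data))
  missing_sites <- setdiff(sensor_sites(), names(data))
  if (length(missing_sites))
    stop("missing sensor site(s): ", paste(missing_sites, collapse = ", "))
  data <- data[sensor_sites()]
  n <- nrow(data[[1L]])
  for (s in sensor_sites()) {
    m <- data[[s]]
    if (!is.matrix(m) || ncol(m) != 6L)
      stop("site ", s, ": expected an n x 6 matrix")
    if (nrow(m) != n)
      stop("site ", s, ": ragged channel length (", nrow(m), " vs ", n, ")")
  }
  if (n < 2L) stop("recording must contain at least 2 samples")
  acc <- vapply(data, function(m) max(abs(m[, 1:3])), numeric(1))
  gyr <- vapply(data, function(m) max(abs(m[, 4:6])), numeric(1))
  if (max(acc) > .ACC_RANGE_G)
    stop("acceleration exceeds sensor range of ", .ACC_RANGE_G, " g")
  if (max(gyr) > .GYR_RANGE_DPS)
    stop("angular velocity exceeds sensor range of ", .GYR_RANGE_DPS, " deg/s")
  if (!is.null(label)) label <- match.arg(label, c("WA", "NA"))
  structure(list(subject_id = as.character(subject_id),
                 trial_type = trial_type,
                 trial_index = as.integer(trial_index),
                 sample_rate_hz = sample_rate_hz,
                 data = data, truth = truth, label = label),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s, %s trial %d: %d samples @ %g Hz (%.1f s)%s\n",
              x$subject_id, x$trial_type, x$trial_index,
              nrow(x$data[[1L]]), x$sample_rate_hz,
              nrow(x$data[[1L]]) / x$sample_rate_hz,
              if (is.null(x$label)) "" else paste0(", group ", x$label)))
  invisible(x)
}

# number of samples in a recording
n_samples <- function(rec) nrow(rec$data[[1L]])

# stack a recording's 8 site matrices into the canonical n x 48 matrix
recording_matrix <- function(rec) {
  out <- do.call(cbind, rec$data[sensor_sites()])
  colnames(out) <- channel_names()
  out
}

#' Ordered TUG sub-phase boundaries
#'
#' Half-open `[start, end)` 1-based sample intervals for the six sub-phases.
#' Walking phases are derived: `walk1` spans from the end of sit-to-stand to
#' the start of the first turn, `walk2` from the end of the first turn to the
#' start of the second.
#'
#' @param sit_to_stand,turn1,turn2,stand_to_sit length-2 integer vectors
#'   `(start, end)`.
#' @return Object of class `tug_phases` with all six phases.
#' @export
tug_phases <- function(sit_to_stand, turn1, turn2, stand_to_sit) {
  ph <- list(sit_to_stand = sit_to_stand,
             walk1 = c(sit_to_stand[2L], turn1[1L]),
             turn1 = turn1,
             walk2 = c(turn1[2L], turn2[1L]),
             turn2 = turn2,
             stand_to_sit = stand_to_sit)
  ph <- lapply(ph, function(p) as.integer(round(p)))
  bounds <- unlist(ph, use.names = FALSE)
  if (any(diff(bounds) < 0))
    stop("TUG phases out of order or overlapping")
  if (any(vapply(ph, function(p) p[2L] <= p[1L], logical(1))))
    stop("empty TUG phase interval")
  structure(ph, class = "tug_phases")
}

#' @export
print.tug_phases <- function(x, ...) {
  cat("<tug_phases> [start, end) sample indices\n")
  for (nm in names(x))
    cat(sprintf("  %-13s %6d  %6d\n", nm, x[[nm]][1L], x[[nm]][2L]))
  invisible(x)
}
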