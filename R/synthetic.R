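# Synthetic cohort generator.
#
# The generator is a stated stand-in for unavailable patient recordings: it
# reproduces the statistical structure the downstream analysis relies on
# (periodic multi-harmonic walking signals with sharp initial-contact
# transients at the ankles, TUG trials with lumbar pitch/yaw bursts bounding
# the six sub-phases, two groups differing in cadence, amplitude, arm swing
# and cycle-to-cycle variability), not the biomechanics of real gait.

# per-channel fundamental amplitudes by site: acc in g, gyro in deg/s
.base_amplitudes <- function() {
  amp <- rbind(
    chest       = c(0.15, 0.10, 0.25, 10,  8,  6),
    lower_back  = c(0.20, 0.15, 0.30, 12, 10,  8),
    left_wrist  = c(0.25, 0.15, 0.20, 40, 30, 20),
    right_wrist = c(0.25, 0.15, 0.20, 40, 30, 20),
    left_thigh  = c(0.30, 0.15, 0.35, 30, 60, 15),
    right_thigh = c(0.30, 0.15, 0.35, 30, 60, 15),
    left_ankle  = c(0.50, 0.20, 0.60, 40, 80, 20),
    right_ankle = c(0.50, 0.20, 0.60, 40, 80, 20))
  colnames(amp) <- sensor_channels()
  amp
}

.HARMONIC_WEIGHTS <- c(1, 0.5, 0.25, 0.12)   # 1st-4th harmonic of the gait cycle
.TUG_BURST_DPS <- 150                        # lumbar burst peak, deg/s
.BURST_CROSS_FRAC <- acos(1 - 2 * 0.1) / (2 * pi)  # 10%-of-peak crossing of a raised cosine

#' Per-group signal parameters for the synthetic generator
#'
#' Defaults encode the stated world of the two groups: walking-acquired (WA)
#' subjects walk with a shorter, steadier gait cycle and full arm swing;
#' not-acquired (NA) subjects are slower (mirroring the roughly 0.85 vs 0.61
#' m/s group speeds of slow hospitalized cohorts), lower-amplitude, with
#' reduced arm swing and more cycle-to-cycle variability.
#'
#' @param cycle_duration_mean,cycle_duration_sd mean and between-subject SD
#'   of the left gait-cycle duration, seconds.
#' @param cycle_variability within-subject cycle-to-cycle SD, seconds.
#' @param step_amplitude_scale multiplier on all signal amplitudes.
#' @param arm_swing_scale additional multiplier on wrist channels.
#' @return List of class parameters.
#' @export
gait_class_params <- function(cycle_duration_mean, cycle_duration_sd,
                              cycle_variability, step_amplitude_scale,
                              arm_swing_scale) {
  stopifnot(cycle_duration_mean > 0, cycle_duration_sd >= 0,
            cycle_variability >= 0, step_amplitude_scale > 0,
            arm_swing_scale > 0)
  list(cycle_duration_mean = cycle_duration_mean,
       cycle_duration_sd = cycle_duration_sd,
       cycle_variability = cycle_variability,
       step_amplitude_scale = step_amplitude_scale,
       arm_swing_scale = arm_swing_scale)
}

#' Synthetic cohort configuration
#'
#' @param n_wa,n_na number of subjects per group; `n_wa + n_na >= 2`.
#' @param seed master seed; per-subject seeds are derived deterministically.
#' @param wa,na per-group signal parameters ([gait_class_params()]).
#' @param sample_rate_hz sampling rate, Hz (device default 120).
#' @param sensor_noise_sd additive Gaussian sensor noise SD on acceleration
#'   channels, in g; gyro channels receive `50 *` this value in deg/s.
#' @param n_trials trials per test type per subject (protocol default 2).
#' @param mwt_cycles left gait cycles per 10-m walk trial.
#' @param tug_walk_cycles left gait cycles per TUG walking phase.
#' @param missing_tug_fraction probability that a subject's TUG trials are
#'   absent (emulates missing measurements in real cohorts).
#' @param ic_pulse_width_s width of the ankle initial-contact transient, s.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_wa, n_na, seed = 1L,
                          wa = gait_class_params(1.10, 0.08, 0.020, 1.0, 1.0),
                          na = gait_class_params(1.45, 0.12, 0.035, 0.7, 0.5),
                          sample_rate_hz = 120,
                          sensor_noise_sd = 0.03,
                          n_trials = 2L,
                          mwt_cycles = 10L,
                          tug_walk_cycles = 4L,
                          missing_tug_fraction = 0.05,
                          ic_pulse_width_s = 0.08) {
  stopifnot(n_wa >= 0, n_na >= 0, sample_rate_hz > 0, sensor_noise_sd >= 0,
            n_trials >= 1, mwt_cycles >= 3, tug_walk_cycles >= 2,
            missing_tug_fraction >= 0, missing_tug_fraction <= 1,
            ic_pulse_width_s > 0)
  if (n_wa + n_na < 2) stop("cohort must contain at least 2 subjects")
  structure(list(n_wa = as.integer(n_wa), n_na = as.integer(n_na),
                 seed = as.integer(seed), wa = wa, na = na,
                 sample_rate_hz = sample_rate_hz,
                 sensor_noise_sd = sensor_noise_sd,
                 n_trials = as.integer(n_trials),
                 mwt_cycles = as.integer(mwt_cycles),
                 tug_walk_cycles = as.integer(tug_walk_cycles),
                 missing_tug_fraction = missing_tug_fraction,
                 ic_pulse_width_s = ic_pulse_width_s),
            class = "cohort_config")
}

# raised-cosine burst sampled at times t, centered on [t0, t0 + width]
.raised_cosine <- function(t, t0, width, amplitude) {
  u <- (t - t0) / width
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  out[inside] <- amplitude * 0.5 * (1 - cos(2 * pi * u[inside]))
  out
}

# shared inter-channel phase pattern of the gait harmonics: biomechanics
# constrains when each channel peaks within the cycle, so the pattern is
# common to all subjects (individuality enters as a small jitter below)
.base_phases <- function() {
  ch <- matrix(rep(0:47, 4), nrow = 48)
  k <- matrix(rep(1:4, each = 48), nrow = 48)
  (2 * pi * ((ch * 5 + k * 11) %% 24)) / 24
}

# subject-level draw of signal parameters
.draw_subject_params <- function(params) {
  cyc <- max(0.6, stats::rnorm(1, params$cycle_duration_mean,
                               params$cycle_duration_sd))
  amp <- .base_amplitudes() * params$step_amplitude_scale *
    exp(stats::rnorm(1, 0, 0.08))
  # mild per-channel individuality on top of the common amplitude profile
  amp <- amp * matrix(exp(stats::rnorm(48, 0, 0.10)), 8, 6, byrow = TRUE)
  amp[c("left_wrist", "right_wrist"), ] <-
    amp[c("left_wrist", "right_wrist"), ] * params$arm_swing_scale
  theta <- .base_phases() + matrix(stats::rnorm(48 * 4, 0, 0.3), nrow = 48)
  list(cycle_s = cyc, cycle_var_s = params$cycle_variability,
       amp = amp, theta = theta)
}

# one walking bout: returns an n x 48 signal matrix (noise-free) plus
# left/right IC times in seconds relative to the bout start
.gen_walk_bout <- function(n_cycles, subj, fs, ic_pulse_width_s) {
  lead <- 0.3; tail <- 0.4; taper <- 0.25
  durations <- pmax(0.5, stats::rnorm(n_cycles, subj$cycle_s, subj$cycle_var_s))
  ic_left <- lead + c(0, cumsum(durations))            # n_cycles + 1 left ICs
  ic_right <- ic_left[-length(ic_left)] + 0.5 * durations
  total <- ic_left[length(ic_left)] + tail
  n <- ceiling(total * fs)
  t <- (seq_len(n) - 1) / fs
  # piecewise-linear gait phase: phi(ic_left[i]) = i - 1
  phi <- stats::approx(ic_left, seq_along(ic_left) - 1, xout = t, rule = 2)$y
  before <- t < ic_left[1L]
  phi[before] <- (t[before] - ic_left[1L]) / durations[1L]
  after <- t > ic_left[length(ic_left)]
  phi[after] <- (n_cycles) +
    (t[after] - ic_left[length(ic_left)]) / durations[n_cycles]
  # edge taper on the oscillatory part only (ICs stay clear of the taper)
  ramp <- pmin(1, pmin(t, total - t) / taper)
  ramp[ramp < 0] <- 0
  side_offset <- rep(c(0, 0, 0.5, 0, 0, 0.5, 0, 0.5), each = 6)  # half-cycle shift
  side_offset[site_columns("left_wrist")] <- 0.5                  # arms anti-phase to legs
  side_offset[site_columns("right_wrist")] <- 0
  amp_vec <- as.vector(t(subj$amp))                               # site-major, 48
  x <- matrix(0, n, 48L)
  for (ch in 1:48) {
    s <- 0
    for (k in 1:4) {
      s <- s + .HARMONIC_WEIGHTS[k] *
        sin(2 * pi * k * (phi + side_offset[ch]) + subj$theta[ch, k])
    }
    x[, ch] <- amp_vec[ch] * ramp * s
  }
  # initial-contact transient: sharp half-sine on the ankle acceleration,
  # onset at the ground-truth IC so the differentiated combined acceleration
  # peaks there. A device sampling at fs cannot resolve a transient shorter
  # than a few sampling intervals, so the width is floored at 3.5 / fs
  # (no effect at the 120 Hz device rate).
  w_ic <- max(ic_pulse_width_s, 3.5 / fs)
  pulse <- function(col, times, scale) {
    for (tc in times) {
      idx <- which(t >= tc & t <= tc + w_ic)
      x[idx, col] <<- x[idx, col] +
        scale * sin(pi * (t[idx] - tc) / w_ic)
    }
  }
  la <- site_columns("left_ankle"); ra <- site_columns("right_ankle")
  # heel-strike transient: ~2 g vertical at the ankle, scaled with the
  # subject's overall amplitude
  ic_amp <- 2.0 * subj$amp["left_ankle", "acc_z"] /
    .base_amplitudes()["left_ankle", "acc_z"]
  pulse(la[3L], ic_left, ic_amp); pulse(la[1L], ic_left, 0.4 * ic_amp)
  pulse(ra[3L], ic_right, ic_amp); pulse(ra[1L], ic_right, 0.4 * ic_amp)
  list(x = x, ic_left = ic_left, ic_right = ic_right, duration = n / fs, n = n)
}

# quiet segment of given duration (signal zero; noise and gravity added later)
.gen_still <- function(duration_s, fs) {
  n <- ceiling(duration_s * fs)
  list(x = matrix(0, n, 48L), ic_left = numeric(0), ic_right = numeric(0),
       duration = n / fs, n = n)
}

# assemble segments into one recording; seg is a list of pieces with $x and
# IC times; bursts is a list of (channel, t0 within segment k, width, amp)
.assemble_recording <- function(segments, fs, noise_acc, noise_gyr) {
  x <- do.call(rbind, lapply(segments, `[[`, "x"))
  offs <- cumsum(c(0, vapply(segments, `[[`, numeric(1), "duration")))
  ic_left <- unlist(lapply(seq_along(segments), function(i)
    segments[[i]]$ic_left + offs[i]))
  ic_right <- unlist(lapply(seq_along(segments), function(i)
    segments[[i]]$ic_right + offs[i]))
  n <- nrow(x)
  acc_cols <- as.vector(outer(1:3, seq(0, 42, by = 6), `+`))
  gyr_cols <- as.vector(outer(4:6, seq(0, 42, by = 6), `+`))
  x[, acc_cols] <- x[, acc_cols] +
    matrix(stats::rnorm(n * length(acc_cols), 0, noise_acc), n)
  x[, gyr_cols] <- x[, gyr_cols] +
    matrix(stats::rnorm(n * length(gyr_cols), 0, noise_gyr), n)
  # gravity on the vertical axis of every site
  x[, seq(3, 48, by = 6)] <- x[, seq(3, 48, by = 6)] + 1
  list(x = x, offsets = offs, ic_left = ic_left, ic_right = ic_right)
}

.matrix_to_site_list <- function(x) {
  out <- lapply(seq_along(sensor_sites()), function(i) {
    m <- x[, (i - 1L) * 6L + 1:6, drop = FALSE]
    colnames(m) <- sensor_channels()
    m
  })
  names(out) <- sensor_sites()
  out
}

.times_to_index <- function(t_s, fs) as.integer(round(t_s * fs)) + 1L

#' Generate one synthetic subject
#'
#' Produces the subject's full trial set: `n_trials` 10-m-walk trials and
#' (unless the subject is drawn as a missing-TUG case) `n_trials` TUG trials,
#' each an [imu_recording()] carrying ground-truth initial-contact indices
#' and, for TUG, ground-truth sub-phase boundaries.
#'
#' @param class_label `"WA"` or `"NA"`.
#' @param config a [cohort_config()].
#' @param seed integer seed; the same seed reproduces the subject exactly.
#' @param subject_id identifier stored in the recordings.
#' @return List with `subject_id`, `label`, and `recordings` (list of
#'   `imu_recording`).
#' @export
generate_subject <- function(class_label, config, seed,
                             subject_id = sprintf("S_%s_%d", class_label, seed)) {
  class_label <- match.arg(class_label, c("WA", "NA"))
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  params <- if (class_label == "WA") config$wa else config$na
  subj <- .draw_subject_params(params)
  fs <- config$sample_rate_hz
  noise_acc <- config$sensor_noise_sd
  noise_gyr <- 50 * config$sensor_noise_sd
  tug_missing <- stats::runif(1) < config$missing_tug_fraction
  recs <- list()
  for (trial in seq_len(config$n_trials)) {
    walk <- .gen_walk_bout(config$mwt_cycles, subj, fs, config$ic_pulse_width_s)
    segs <- list(.gen_still(0.6, fs), walk, .gen_still(0.6, fs))
    asm <- .assemble_recording(segs, fs, noise_acc, noise_gyr)
    recs[[length(recs) + 1L]] <- imu_recording(
      subject_id, "10MWT", trial, fs, .matrix_to_site_list(asm$x),
      truth = list(ic_left = .times_to_index(asm$ic_left, fs),
                   ic_right = .times_to_index(asm$ic_right, fs),
                   tug_phases = NULL, class_label = class_label),
      label = class_label)
  }
  if (!tug_missing) {
    for (trial in seq_len(config$n_trials)) {
      recs[[length(recs) + 1L]] <-
        .generate_tug_trial(subject_id, trial, subj, config, class_label)
    }
  }
  list(subject_id = subject_id, label = class_label, recordings = recs)
}

.generate_tug_trial <- function(subject_id, trial, subj, config, class_label) {
  fs <- config$sample_rate_hz
  w_sts <- 1.5; w_turn <- 2.0
  jit <- function() .TUG_BURST_DPS * stats::runif(1, 0.9, 1.1)
  walk1 <- .gen_walk_bout(config$tug_walk_cycles, subj, fs, config$ic_pulse_width_s)
  walk2 <- .gen_walk_bout(config$tug_walk_cycles, subj, fs, config$ic_pulse_width_s)
  segs <- list(.gen_still(1.5, fs),       # seated
               .gen_still(w_sts, fs),     # sit-to-stand burst window
               walk1,
               .gen_still(w_turn, fs),    # turn 1
               walk2,
               .gen_still(w_turn, fs),    # turn 2
               .gen_still(w_sts, fs),     # stand-to-sit burst window
               .gen_still(1.0, fs))
  asm <- .assemble_recording(segs, fs, config$sensor_noise_sd,
                             50 * config$sensor_noise_sd)
  offs <- asm$offsets
  t <- (seq_len(nrow(asm$x)) - 1) / fs
  lb <- site_columns("lower_back")
  pitch_col <- lb[5L]; yaw_col <- lb[6L]
  amp_sts <- jit(); amp_turn1 <- jit(); amp_turn2 <- jit(); amp_sit <- jit()
  asm$x[, pitch_col] <- asm$x[, pitch_col] +
    .raised_cosine(t, offs[2L], w_sts,  amp_sts) +
    .raised_cosine(t, offs[7L], w_sts, -amp_sit)
  asm$x[, yaw_col] <- asm$x[, yaw_col] +
    .raised_cosine(t, offs[4L], w_turn, amp_turn1) +
    .raised_cosine(t, offs[6L], w_turn, amp_turn2)
  # ground-truth phase boundaries: the 10%-of-peak crossings of each burst
  cross <- function(t0, w) c(t0 + .BURST_CROSS_FRAC * w,
                             t0 + (1 - .BURST_CROSS_FRAC) * w)
  phases <- tug_phases(
    sit_to_stand = .times_to_index(cross(offs[2L], w_sts), fs),
    turn1        = .times_to_index(cross(offs[4L], w_turn), fs),
    turn2        = .times_to_index(cross(offs[6L], w_turn), fs),
    stand_to_sit = .times_to_index(cross(offs[7L], w_sts), fs))
  imu_recording(
    subject_id, "TUG", trial, fs, .matrix_to_site_list(asm$x),
    truth = list(ic_left = .times_to_index(asm$ic_left, fs),
                 ic_right = .times_to_index(asm$ic_right, fs),
                 tug_phases = phases, class_label = class_label),
    label = class_label)
}

#' Generate a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return List of class `imu_cohort`: one element per subject, each as
#'   returned by [generate_subject()]; WA subjects first. Per-subject seeds
#'   are `config$seed + 1000 * subject_rank`, so any subject can be
#'   regenerated in isolation.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  labels <- c(rep("WA", config$n_wa), rep("NA", config$n_na))
  cohort <- lapply(seq_along(labels), function(i) {
    generate_subject(labels[i], config, seed = config$seed + 1000L * i,
                     subject_id = sprintf("S%02d_%s", i, labels[i]))
  })
  structure(cohort, class = "imu_cohort", config = config)
}

#' @export
print.imu_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, character(1), "label")
  ntr <- vapply(x, function(s) length(s$recordings), integer(1))
  cat(sprintf("<imu_cohort> %d subjects (%d WA, %d NA), %d recordings\n",
              length(x), sum(labs == "WA"), sum(labs == "NA"), sum(ntr)))
  invisible(x)
}
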