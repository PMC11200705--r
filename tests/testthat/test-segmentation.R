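# Signal segmentation: filtering, IC detection, TUG sub-phases, walking
# intervals, gait-cycle windows.

test_that("highpass_acceleration filters acceleration only", {
  cfg <- tiny_cohort_config()
  rec <- generate_subject("WA", cfg, seed = 2)$recordings[[1L]]
  out <- highpass_acceleration(rec)
  for (site in sensor_sites()) {
    # gravity (+1 g on the vertical axis) is removed
    expect_lt(abs(mean(out$data[[site]][, "acc_z"])), 5e-3)
    # angular velocity passes through bitwise unchanged
    expect_identical(out$data[[site]][, 4:6], rec$data[[site]][, 4:6])
    expect_equal(nrow(out$data[[site]]), nrow(rec$data[[site]]))
  }
  expect_error(highpass_acceleration(rec, cutoff_hz = 20), "Nyquist")
})

test_that("combined_acceleration is the per-sample Euclidean norm", {
  expect_equal(combined_acceleration(3, 4, 0), 5)
  expect_equal(combined_acceleration(0, 0, 0), 0)
  expect_equal(combined_acceleration(1, 1, 1), sqrt(3))
  expect_equal(combined_acceleration(cbind(c(3, 0), c(4, 0), c(0, 0))),
               c(5, 0))
  expect_error(combined_acceleration(1:3, 1:2, 1:3), "equal length")
})

test_that("initial contacts are recovered from the ankle signal", {
  cfg <- cohort_config(2, 2, seed = 1)   # full rate, default noise
  for (lab in c("WA", "NA")) {
    rec <- generate_subject(lab, cfg, seed = 3)$recordings[[1L]]
    fs <- rec$sample_rate_hz
    recf <- highpass_acceleration(rec)
    ic <- detect_initial_contacts(recf, site = "left_ankle")
    truth <- rec$truth$ic_left
    in_walk <- ic[ic >= min(truth) - 0.3 * fs & ic <= max(truth) + 0.3 * fs]
    expect_equal(length(in_walk), length(truth))
    err_ms <- abs(in_walk - truth) / fs * 1000
    expect_lt(stats::median(err_ms), 25)
  }
})

test_that("IC detection is invariant to amplitude scaling", {
  cfg <- cohort_config(2, 2, seed = 1)
  rec <- highpass_acceleration(generate_subject("WA", cfg, seed = 4)$recordings[[1L]])
  acc <- rec$data$left_ankle[, 1:3]
  ic1 <- detect_initial_contacts(acc, rec$sample_rate_hz)
  ic2 <- detect_initial_contacts(acc * 2, rec$sample_rate_hz)
  ic3 <- detect_initial_contacts(acc * 0.25, rec$sample_rate_hz)
  expect_identical(ic1, ic2)
  expect_identical(ic1, ic3)
})

test_that("degenerate inputs yield no contacts or an error", {
  expect_identical(detect_initial_contacts(matrix(1, 500, 3), 120),
                   integer(0))
  expect_error(detect_initial_contacts(matrix(0, 10, 3), 120), "shorter")
})

test_that("TUG sub-phases are recovered within 0.1 s of ground truth", {
  cfg <- cohort_config(2, 2, seed = 1, missing_tug_fraction = 0)
  for (seed in c(5, 6)) {
    subj <- generate_subject(if (seed %% 2) "NA" else "WA", cfg, seed = seed)
    rec <- subj$recordings[[3L]]
    expect_equal(rec$trial_type, "TUG")
    fs <- rec$sample_rate_hz
    ph <- segment_tug_phases(highpass_acceleration(rec))
    truth <- rec$truth$tug_phases
    for (nm in names(truth))
      expect_lt(max(abs(ph[[nm]] - truth[[nm]])) / fs, 0.1)
    # structural invariants
    bounds <- unlist(ph)
    expect_true(all(diff(bounds) >= 0))
    expect_identical(ph$walk1[1L], ph$sit_to_stand[2L])
    expect_identical(ph$walk1[2L], ph$turn1[1L])
    expect_identical(ph$walk2[1L], ph$turn1[2L])
    expect_identical(ph$walk2[2L], ph$turn2[1L])
    # each turn interval contains the yaw |max| anchor
    yaw <- rec$data$lower_back[, "gyr_yaw"]
    mid <- ph$sit_to_stand[2L]:ph$stand_to_sit[1L]
    a1 <- mid[which.max(abs(yaw[mid]))]
    expect_true(a1 >= ph$turn1[1L] && a1 < ph$turn1[2L] ||
                  a1 >= ph$turn2[1L] && a1 < ph$turn2[2L])
  }
})

test_that("segment_tug_phases rejects recordings without the burst pattern", {
  flat <- matrix(stats::rnorm(2000, 0, 0.1), 1000, 2)
  expect_error(segment_tug_phases(flat, 120))
})

test_that("walking intervals: two TUG phases, first/last 10MWT cycle dropped", {
  cfg <- tiny_cohort_config(missing_tug_fraction = 0)
  subj <- generate_subject("WA", cfg, seed = 9)
  tug <- highpass_acceleration(subj$recordings[[2L]])
  ph <- segment_tug_phases(tug)
  iv <- extract_walking_intervals(tug, phases = ph)
  expect_length(iv, 2L)
  expect_identical(iv[[1L]], ph$walk1)
  expect_identical(iv[[2L]], ph$walk2)
  # turns lie outside both walking intervals
  expect_lte(iv[[1L]][2L], ph$turn1[1L])
  expect_lte(iv[[2L]][2L], ph$turn2[1L])

  mwt <- highpass_acceleration(subj$recordings[[1L]])
  ic <- detect_initial_contacts(mwt, site = "left_ankle")
  iv2 <- extract_walking_intervals(mwt, ic = ic)
  expect_length(iv2, 1L)
  expect_identical(iv2[[1L]], c(ic[2L], ic[length(ic) - 1L]))
  expect_error(extract_walking_intervals(mwt, ic = ic[1:3]), "fewer than 3")
})

test_that("gait-cycle windows follow the n-1 pairing rule", {
  cfg <- tiny_cohort_config(missing_tug_fraction = 0)
  rec <- highpass_acceleration(generate_subject("WA", cfg, seed = 9)$recordings[[1L]])
  ic <- detect_initial_contacts(rec, site = "left_ankle")
  # 5 contacts in one interval -> 4 windows
  iv <- list(c(ic[1L], ic[5L]))
  w <- extract_gait_cycles(rec, iv, ic = ic)
  expect_length(w, 4L)
  for (i in seq_along(w)) {
    expect_equal(nrow(w[[i]]$data), w[[i]]$end - w[[i]]$start)
    expect_equal(ncol(w[[i]]$data), 48L)
  }
  # windows tile the interval contiguously
  expect_equal(w[[1L]]$start, ic[1L])
  expect_equal(w[[4L]]$end, ic[5L])
  # empty result when no pair of contacts falls inside
  expect_length(extract_gait_cycles(rec, list(c(1L, 5L)), ic = ic), 0L)
})

test_that("TUG step-count arithmetic: k1 and k2 contacts give k1+k2-2 windows", {
  cfg <- cohort_config(2, 2, seed = 1, sample_rate_hz = 30, n_trials = 1,
                       tug_walk_cycles = 4, missing_tug_fraction = 0)
  rec <- generate_subject("WA", cfg, seed = 12)$recordings[[2L]]
  w <- segment_recording(rec)
  recf <- highpass_acceleration(rec)
  ph <- segment_tug_phases(recf)
  ic <- detect_initial_contacts(recf, site = "left_ankle")
  k1 <- sum(ic >= ph$walk1[1L] & ic <= ph$walk1[2L])
  k2 <- sum(ic >= ph$walk2[1L] & ic <= ph$walk2[2L])
  expect_equal(length(w), (k1 - 1L) + (k2 - 1L))
})

test_that("segmentation is deterministic and tolerates missing TUG subjects", {
  cohort <- generate_cohort(tiny_cohort_config(1, 1, seed = 21,
                                               missing_tug_fraction = 1))
  w1 <- segment_cohort(cohort)
  w2 <- segment_cohort(cohort)
  expect_identical(w1[], w2[])
  # both subjects contribute windows even without TUG trials
  counts <- attr(w1, "cycle_counts")
  expect_equal(nrow(counts), 2L)
  expect_true(all(counts$n_cycles > 0))
  expect_true(all(vapply(w1, `[[`, character(1), "trial_type") == "10MWT"))
})

test_that("read_cohort names the missing site and trial on error", {
  dir <- tempfile("cohort")
  cohort <- generate_cohort(tiny_cohort_config(1, 1, seed = 3))
  manifest <- write_cohort(cohort, dir)
  victim <- list.files(dir, pattern = "10MWT_1_left_ankle", recursive = TRUE,
                       full.names = TRUE)[1L]
  unlink(victim)
  expect_error(read_cohort(manifest), "left_ankle")
  unlink(dir, recursive = TRUE)
})
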