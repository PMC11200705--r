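# Normalization, padding, augmentation, masking and fold assembly.

test_that("normalization maps a group extremum to 0 or 1 by its sign", {
  # negative extremum {-2, 1}: -2/2/2 + 0.5 = 0, 1/2/2 + 0.5 = 0.75
  d <- matrix(0.001, 6, 48)
  cols <- channel_group_columns("acc_x")
  d[1L, cols[1L]] <- -2; d[2L, cols[2L]] <- 1
  w <- normalize_windows(list(mk_window(6, data = d)))[[1L]]
  expect_equal(unname(w$data[1L, cols[1L]]), 0)
  expect_equal(unname(w$data[2L, cols[2L]]), 0.75)
  # positive extremum {1, 2}: 1/2/2 + 0.5 = 0.75, 2/2/2 + 0.5 = 1
  d2 <- matrix(0.001, 6, 48)
  d2[1L, cols[1L]] <- 1; d2[2L, cols[2L]] <- 2
  w2 <- normalize_windows(list(mk_window(6, data = d2)))[[1L]]
  expect_equal(unname(w2$data[1L, cols[1L]]), 0.75)
  expect_equal(unname(w2$data[2L, cols[2L]]), 1)
})

test_that("normalization law holds on random inputs", {
  set.seed(31)
  for (rep in 1:5) {
    d <- matrix(stats::rnorm(20 * 48, 0, rep), 20, 48)
    zero_pos <- cbind(sample(20, 6), sample(48, 6))
    d[zero_pos] <- 0
    w <- normalize_windows(list(mk_window(20, data = d)))[[1L]]
    expect_true(all(w$data >= 0 & w$data <= 1))
    expect_true(all(w$data[zero_pos] == 0.5))     # baseline maps exactly
    expect_true(all((d > 0) == (w$data > 0.5)))   # sign structure preserved
    for (ch in sensor_channels()) {
      g <- w$data[, channel_group_columns(ch)]
      expect_true(isTRUE(all.equal(min(g), 0)) ||
                    isTRUE(all.equal(max(g), 1)))
    }
  }
})

test_that("normalization pools the denominator across a subject-trial", {
  w1 <- mk_window(5, fill = 1)   # same trial, different cycles
  w2 <- mk_window(5, fill = 2)
  out <- normalize_windows(list(w1, w2))
  # denominator 2 shared: window 1 maps to 1/2/2 + 0.5 = 0.75
  expect_true(all(out[[1L]]$data == 0.75))
  expect_true(all(out[[2L]]$data == 1))
  # windows of different trials are rejected
  w3 <- mk_window(5, trial_index = 2)
  expect_error(normalize_windows(list(w1, w3)), "single subject-trial")
  expect_error(normalize_windows(list(mk_window(5, fill = 0))), "all-zero")
})

test_that("padding appends exactly 0.5 and refuses to truncate", {
  w <- mk_window(10, fill = 0.3); w$normalized <- TRUE
  s <- pad_window(w, length_max = 20)
  expect_equal(dim(s$matrix), c(20L, 48L))
  expect_true(all(s$matrix[11:20, ] == 0.5))
  expect_true(all(s$matrix[1:10, ] == 0.3))
  expect_equal(s$valid_length, 10L)
  # crop recovers the original window exactly
  expect_equal(s$matrix[seq_len(s$valid_length), ], unname(w$data),
               ignore_attr = TRUE)
  # identity at full length, error beyond it
  expect_equal(pad_window(w, 10)$matrix, w$data, ignore_attr = TRUE)
  w2 <- mk_window(21); w2$normalized <- TRUE
  expect_error(pad_window(w2, 20), "refusing to truncate")
  w3 <- mk_window(5)
  expect_error(pad_window(w3, 20), "normalized")
})

test_that("augmentation is a five-fold bounded-noise expansion", {
  set.seed(1)
  base <- lapply(1:200, function(i)
    mk_sample(8, 12, subject = paste0("S", i %% 5),
              label = if (i %% 2) "WA" else "NA", value = 0.5))
  out <- augment(base, n_copies = 4, seed = 3)
  expect_length(out, 1000L)                       # 200 -> 5 x 200
  expect_identical(augment(base, n_copies = 0), base)
  # originals untouched, copies within the noise bound, labels inherited
  expect_identical(out[[1L]], base[[1L]])
  for (k in 2:5) {
    expect_lte(max(abs(out[[k]]$matrix - base[[1L]]$matrix)), 0.1)
    expect_identical(out[[k]]$subject_id, base[[1L]]$subject_id)
    expect_identical(out[[k]]$label, base[[1L]]$label)
    expect_true(out[[k]]$augmented)
  }
  expect_true(all(vapply(out, function(s)
    all(s$matrix >= 0 & s$matrix <= 1), logical(1))))
  # reproducible under a fixed seed
  expect_identical(augment(base[1:3], seed = 7), augment(base[1:3], seed = 7))
  expect_error(augment(base, n_copies = -1), "nonnegative")
})

test_that("sensor masking writes the 0.5 baseline into excluded sites only", {
  s <- mk_sample(8, 12, value = 0.7)
  m <- mask_sensors(s, "right_ankle")
  cols <- site_columns("right_ankle")
  expect_true(all(m$matrix[, cols] == 0.5))
  expect_true(all(m$matrix[1:8, -cols] == 0.7))
  expect_identical(mask_sensors(s, character(0)), s)
  m6 <- mask_sensors(s, setdiff(sensor_sites(),
                                c("right_ankle", "right_wrist")))
  expect_equal(sum(colSums(m6$matrix == 0.5) == 12), 36L)
  expect_error(mask_sensors(s, "left_elbow"), "unknown sensor site")
  # masking and padding commute (both write the constant 0.5)
  w <- mk_window(8, fill = 0.7); w$normalized <- TRUE
  a <- mask_sensors(pad_window(w, 12), "chest")
  w2 <- w; w2$data <- mask_sensors(w2$data, "chest")
  b <- pad_window(w2, 12)
  expect_equal(a$matrix, b$matrix)
})

test_that("fold assembly balances, splits and never leaks the held-out subject", {
  set.seed(2)
  samples <- list()
  for (subj in 1:6) {
    lab <- if (subj <= 4) "WA" else "NA"     # imbalanced cohort
    for (k in 1:10)
      samples[[length(samples) + 1L]] <-
        mk_sample(8, 12, subject = paste0("S", subj), label = lab,
                  value = stats::runif(1, 0.3, 0.7))
  }
  fold <- assemble_fold(samples, "S1", seed = 5)
  ids <- function(x) vapply(x, `[[`, character(1), "subject_id")
  labs <- function(x) vapply(x, `[[`, character(1), "label")
  expect_false("S1" %in% c(ids(fold$train), ids(fold$val)))
  expect_equal(length(fold$test), 10L)
  expect_false(any(vapply(fold$test, `[[`, logical(1), "augmented")))
  # balanced before split: 20 per class kept from the 30/20 pool
  pre_aug <- fold$train[!vapply(fold$train, `[[`, logical(1), "augmented")]
  pool_labs <- c(labs(pre_aug), labs(fold$val))
  expect_equal(sum(pool_labs == "WA"), sum(pool_labs == "NA"))
  # augmentation applied to the train portion only, five-fold
  expect_equal(length(fold$train), 5L * length(pre_aug))
  expect_length(fold$val, round(0.1 * 40))
  # reproducibility and error paths
  f2 <- assemble_fold(samples, "S1", seed = 5)
  expect_identical(ids(f2$train), ids(fold$train))
  expect_error(assemble_fold(samples, "S99", seed = 1), "no samples")
  one_class <- samples[labs(samples) == "WA"]
  expect_error(assemble_fold(one_class, "S1", seed = 1), "single class")
})

test_that("prepare_samples pads to the longest observed cycle", {
  w <- get_tiny_windows()
  s <- prepare_samples(w)
  lens <- vapply(w, function(x) nrow(x$data), integer(1))
  expect_true(all(vapply(s, function(x) nrow(x$matrix), integer(1)) ==
                    max(lens)))
  expect_equal(vapply(s, `[[`, integer(1), "valid_length"), lens)
})
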