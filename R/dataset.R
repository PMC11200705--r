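# Gait-cycle windows -> fixed-size model inputs.
#
# Normalization maps every value to value / M / 2 + 0.5, where M is the
# maximum absolute value of the window's modality-axis channel group taken
# across all 8 sensors and all samples of the same subject-trial. The result
# lies in [0, 1] with 0 as the signal baseline mapped to 0.5; within each
# trial and group either the minimum 0 or the maximum 1 is attained,
# depending on the sign of the extreme value. Windows are then padded with
# the baseline constant 0.5 to a common length.

.trial_key <- function(w) paste(w$subject_id, w$trial_type, w$trial_index,
                                sep = "|")

#' Normalize the gait-cycle windows of one subject-trial
#'
#' @param windows list of `gait_cycle` windows belonging to a single
#'   subject-trial (checked).
#' @return List of windows with `data` mapped into `[0, 1]`; the applied
#'   per-group denominators are attached as attribute `denominators`.
#' @export
normalize_windows <- function(windows) {
  if (!length(windows)) stop("no windows to normalize")
  if (length(unique(vapply(windows, .trial_key, character(1)))) != 1L)
    stop("normalize_windows() expects windows of a single subject-trial")
  denom <- numeric(6L)
  names(denom) <- sensor_channels()
  for (g in seq_len(6L)) {
    cols <- channel_group_columns(sensor_channels()[g])
    denom[g] <- max(vapply(windows, function(w) max(abs(w$data[, cols])),
                           numeric(1)))
    if (denom[g] == 0)
      stop("all-zero channel group '", sensor_channels()[g],
           "': normalization denominator is 0")
  }
  out <- lapply(windows, function(w) {
    for (g in seq_len(6L)) {
      cols <- channel_group_columns(sensor_channels()[g])
      w$data[, cols] <- w$data[, cols] / denom[g] / 2 + 0.5
    }
    w$normalized <- TRUE
    w
  })
  attr(out, "denominators") <- denom
  out
}

#' Normalize all windows of a cohort, trial by trial
#'
#' Groups windows by subject-trial and applies [normalize_windows()] to each
#' group, preserving the input order.
#'
#' @param windows list of `gait_cycle` windows from [segment_cohort()].
#' @return List of normalized windows in the original order.
#' @export
normalize_cohort_windows <- function(windows) {
  keys <- vapply(windows, .trial_key, character(1))
  out <- vector("list", length(windows))
  for (k in unique(keys)) {
    idx <- which(keys == k)
    out[idx] <- normalize_windows(windows[idx])
  }
  out
}

#' Pad a normalized window to a fixed length
#'
#' Appends the baseline constant 0.5 so every sample has the same length;
#' windows longer than `length_max` are rejected, never truncated.
#'
#' @param window a normalized `gait_cycle` window.
#' @param length_max target length in samples (the cohort's longest walking
#'   cycle; 276 in the reference protocol at 120 Hz).
#' @return A `norm_sample`: list with the `length_max x 48` matrix `matrix`,
#'   `subject_id`, `label`, `valid_length` and provenance fields.
#' @export
pad_window <- function(window, length_max = 276L) {
  if (is.null(window$normalized) || !isTRUE(window$normalized))
    stop("window must be normalized before padding")
  len <- nrow(window$data)
  if (len > length_max)
    stop("window length ", len, " exceeds length_max ", length_max,
         "; refusing to truncate")
  m <- matrix(0.5, nrow = length_max, ncol = 48L)
  m[seq_len(len), ] <- window$data
  colnames(m) <- channel_names()
  structure(list(matrix = m, subject_id = window$subject_id,
                 label = window$label, valid_length = len,
                 trial_type = window$trial_type,
                 trial_index = window$trial_index,
                 augmented = FALSE),
            class = "norm_sample")
}

#' Augment normalized samples with uniform noise copies
#'
#' For each input sample, `n_copies` noisy replicas are created by adding
#' i.i.d. uniform noise on `[-noise_half_width, noise_half_width]` to every
#' value (default four copies, a five-fold increase). Originals are returned
#' untouched; noisy values are clipped back to `[0, 1]` unless `clip = FALSE`.
#'
#' @param samples list of `norm_sample`.
#' @param n_copies noisy copies per sample (>= 0).
#' @param noise_half_width half-width of the uniform noise.
#' @param seed optional seed for reproducibility.
#' @param clip clip noisy values to `[0, 1]`.
#' @return List of `(1 + n_copies) * length(samples)` samples; copies carry
#'   their source's subject id and label and `augmented = TRUE`.
#' @export
augment <- function(samples, n_copies = 4L, noise_half_width = 0.1,
                    seed = NULL, clip = TRUE) {
  if (n_copies < 0) stop("n_copies must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (n_copies == 0L) return(samples)
  out <- vector("list", length(samples) * (1L + n_copies))
  j <- 0L
  for (s in samples) {
    j <- j + 1L; out[[j]] <- s
    for (k in seq_len(n_copies)) {
      noisy <- s
      noise <- matrix(stats::runif(length(s$matrix), -noise_half_width,
                                   noise_half_width),
                      nrow = nrow(s$matrix))
      noisy$matrix <- s$matrix + noise
      if (clip) noisy$matrix <- pmin(pmax(noisy$matrix, 0), 1)
      noisy$augmented <- TRUE
      j <- j + 1L; out[[j]] <- noisy
    }
  }
  out
}

#' Replace excluded sensors' channels with the 0.5 baseline
#'
#' Sensor ablation: the six channels of each excluded site are set to the
#' constant 0.5 at every position, so the input shape (48 channels) never
#' changes.
#'
#' @param sample a `norm_sample` (or a plain matrix with 48 columns).
#' @param excluded_sites character vector of site names (may be empty).
#' @return The sample with masked channels.
#' @export
mask_sensors <- function(sample, excluded_sites) {
  if (!length(excluded_sites)) return(sample)
  unknown <- setdiff(excluded_sites, sensor_sites())
  if (length(unknown))
    stop("unknown sensor site(s): ", paste(unknown, collapse = ", "))
  cols <- site_columns(excluded_sites)
  if (is.matrix(sample)) { sample[, cols] <- 0.5; return(sample) }
  sample$matrix[, cols] <- 0.5
  sample
}

#' Assemble one leave-one-subject-out fold
#'
#' The held-out subject's samples form the test set (never augmented). The
#' remaining samples are balanced between the two groups by seeded random
#' undersampling of the majority label, split into train/validation
#' (`val_fraction` to validation), and the training portion only is
#' augmented. Sensor masking, when requested, is applied identically to all
#' three sets.
#'
#' @param samples list of `norm_sample` for the whole cohort.
#' @param held_out_subject subject id to hold out.
#' @param val_fraction fraction of the (balanced) pool used for validation.
#' @param balance balance label counts by undersampling (default `TRUE`).
#' @param seed fold seed (undersampling, split, augmentation noise).
#' @param n_copies,noise_half_width augmentation parameters for the train set.
#' @param excluded_sites sensor sites to mask in all sets.
#' @param augment_train apply augmentation to the training portion.
#' @return List with `train`, `val`, `test` lists of samples.
#' @export
assemble_fold <- function(samples, held_out_subject, val_fraction = 0.1,
                          balance = TRUE, seed = NULL, n_copies = 4L,
                          noise_half_width = 0.1,
                          excluded_sites = character(),
                          augment_train = TRUE) {
  ids <- vapply(samples, `[[`, character(1), "subject_id")
  if (!held_out_subject %in% ids)
    stop("held-out subject '", held_out_subject, "' has no samples")
  if (!is.null(seed)) set.seed(seed)
  test <- samples[ids == held_out_subject]
  pool <- samples[ids != held_out_subject]
  labs <- vapply(pool, `[[`, character(1), "label")
  if (length(unique(labs)) < 2L)
    stop("remaining subjects contain a single class; cannot train")
  if (balance) {
    n_min <- min(table(labs))
    keep <- unlist(lapply(unique(labs), function(l) {
      idx <- which(labs == l)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
    pool <- pool[sort(keep)]
    labs <- labs[sort(keep)]
  }
  n_val <- round(val_fraction * length(pool))
  val_idx <- if (n_val > 0) sort(sample(seq_along(pool), n_val)) else integer(0)
  val <- pool[val_idx]
  train <- if (length(val_idx)) pool[-val_idx] else pool
  if (!length(train)) stop("empty training set after splitting")
  if (augment_train)
    train <- augment(train, n_copies = n_copies,
                     noise_half_width = noise_half_width)
  if (length(excluded_sites)) {
    train <- lapply(train, mask_sensors, excluded_sites = excluded_sites)
    val <- lapply(val, mask_sensors, excluded_sites = excluded_sites)
    test <- lapply(test, mask_sensors, excluded_sites = excluded_sites)
  }
  list(train = train, val = val, test = test)
}

#' Stack samples into a model input array
#'
#' @param samples list of `norm_sample`.
#' @return List with `x`, an array of dim `(length_max, 48, n)`, and `y`, a
#'   factor with levels `WA`, `NA` (`NA` is the positive class).
#' @export
samples_to_array <- function(samples) {
  if (!length(samples)) stop("no samples")
  L <- nrow(samples[[1L]]$matrix)
  x <- array(0, dim = c(L, 48L, length(samples)))
  for (i in seq_along(samples)) x[, , i] <- samples[[i]]$matrix
  y <- factor(vapply(samples, `[[`, character(1), "label"),
              levels = c("WA", "NA"))
  list(x = x, y = y)
}

#' Windows to padded samples
#'
#' Normalizes per subject-trial and pads to a common length.
#'
#' @param windows list of `gait_cycle` windows.
#' @param length_max padding length; defaults to the longest observed cycle.
#' @return List of `norm_sample`.
#' @export
prepare_samples <- function(windows, length_max = NULL) {
  normed <- normalize_cohort_windows(windows)
  lens <- vapply(normed, function(w) nrow(w$data), integer(1))
  if (is.null(length_max)) length_max <- max(lens)
  lapply(normed, pad_window, length_max = length_max)
}
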