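# Cohort on-disk layout: one CSV per sensor per trial
# (columns time_s,acc_x,acc_y,acc_z,gyr_roll,gyr_pitch,gyr_yaw) plus a JSON
# manifest listing subjects, labels, trials and file paths. Ground-truth
# annotations of synthetic cohorts travel in the manifest so a written cohort
# reads back complete.

#' Write a cohort to disk
#'
#' @param cohort an `imu_cohort` (or plain list of subjects as produced by
#'   [generate_subject()]).
#' @param directory output directory, created if needed.
#' @return Path of the written manifest (`manifest.json`), invisibly usable
#'   with [read_cohort()].
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  subjects <- lapply(cohort, function(subj) {
    sdir <- file.path(directory, subj$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    trials <- lapply(subj$recordings, function(rec) {
      t_s <- (seq_len(n_samples(rec)) - 1) / rec$sample_rate_hz
      files <- list()
      for (site in sensor_sites()) {
        df <- data.frame(time_s = t_s, rec$data[[site]], check.names = FALSE)
        rel <- file.path(subj$subject_id,
                         sprintf("%s_%d_%s.csv", rec$trial_type,
                                 rec$trial_index, site))
        utils::write.csv(df, file.path(directory, rel), row.names = FALSE,
                         quote = FALSE)
        files[[site]] <- rel
      }
      truth <- rec$truth
      if (!is.null(truth) && !is.null(truth$tug_phases))
        truth$tug_phases <- unclass(truth$tug_phases)
      list(trial_type = rec$trial_type, trial_index = rec$trial_index,
           sample_rate_hz = rec$sample_rate_hz, n_samples = n_samples(rec),
           files = files, truth = truth)
    })
    tug_present <- any(vapply(subj$recordings, `[[`, character(1),
                              "trial_type") == "TUG")
    list(subject_id = subj$subject_id, label = subj$label,
         tug_missing = !tug_present, trials = trials)
  })
  manifest <- list(format = "imugait-cohort", version = 1L,
                   subjects = subjects)
  path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  path
}

#' Read a cohort from a manifest
#'
#' Validates that every referenced per-sensor CSV exists, that all eight
#' sites are present for every trial, and that channel lengths agree.
#' Subjects whose TUG trials are marked absent load with their 10-m-walk
#' trials only (they are never dropped).
#'
#' @param manifest_path path to a `manifest.json` written by [write_cohort()].
#' @return An `imu_cohort`.
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  root <- dirname(manifest_path)
  manifest <- jsonlite::fromJSON(manifest_path, simplifyVector = FALSE)
  if (!identical(manifest$format, "imugait-cohort"))
    stop("not an imugait cohort manifest: ", manifest_path)
  cohort <- lapply(manifest$subjects, function(subj) {
    recs <- lapply(subj$trials, function(tr) {
      tt <- match.arg(tr$trial_type, c("10MWT", "TUG"))
      data <- list()
      for (site in sensor_sites()) {
        rel <- tr$files[[site]]
        if (is.null(rel) || !file.exists(file.path(root, rel)))
          stop("missing file for site '", site, "' of subject ",
               subj$subject_id, " ", tt, " trial ", tr$trial_index)
        df <- utils::read.csv(file.path(root, rel))
        if (!identical(names(df),
                       c("time_s", sensor_channels())))
          stop("unexpected columns in ", rel)
        data[[site]] <- as.matrix(df[, sensor_channels()])
      }
      truth <- tr$truth
      if (!is.null(truth)) {
        truth$ic_left <- as.integer(unlist(truth$ic_left))
        truth$ic_right <- as.integer(unlist(truth$ic_right))
        if (!is.null(truth$tug_phases)) {
          ph <- lapply(truth$tug_phases, function(p) as.integer(unlist(p)))
          truth$tug_phases <- tug_phases(ph$sit_to_stand, ph$turn1,
                                         ph$turn2, ph$stand_to_sit)
        }
      }
      imu_recording(subj$subject_id, tt, tr$trial_index, tr$sample_rate_hz,
                    data, truth = truth, label = subj$label)
    })
    list(subject_id = subj$subject_id, label = subj$label, recordings = recs)
  })
  structure(cohort, class = "imu_cohort")
}
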