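# Leave-one-subject-out cross-validation and sensor ablation.
#
# One model per subject: the held-out subject's unaugmented gait cycles are
# classified by a model trained on everybody else, and the per-cycle
# predictions of all folds are pooled into a single confusion matrix (NA,
# the not-acquired group, is the positive class). Accuracy, sensitivity and
# specificity follow the usual definitions:
#   accuracy    = (TP + TN) / (TP + FN + FP + TN)
#   sensitivity = TP / (TP + FN)
#   specificity = TN / (TN + FP)

#' Confusion matrix with the NA group as positive
#'
#' @param truth,predicted factors (or characters) with values `WA`/`NA`.
#' @return Object of class `confusion_matrix`: counts `tp`, `fn`, `fp`, `tn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) > 0,
            all(truth %in% c("WA", "NA")), all(predicted %in% c("WA", "NA")))
  structure(list(tp = sum(truth == "NA" & predicted == "NA"),
                 fn = sum(truth == "NA" & predicted == "WA"),
                 fp = sum(truth == "WA" & predicted == "NA"),
                 tn = sum(truth == "WA" & predicted == "WA")),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (positive = NA)\n")
  cat(sprintf("            pred NA  pred WA\n"))
  cat(sprintf("  true NA  %8d %8d\n", x$tp, x$fn))
  cat(sprintf("  true WA  %8d %8d\n", x$fp, x$tn))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Metrics with a zero denominator are returned as `NA_real_` (undefined),
#' never silently as 0.
#'
#' @param cm a [confusion_matrix()] (or list with `tp`, `fn`, `fp`, `tn`).
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(cm) {
  with(cm, {
    total <- tp + fn + fp + tn
    if (total == 0) stop("empty confusion matrix")
    list(accuracy = (tp + tn) / total,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
}

#' Leave-one-subject-out cross-validation
#'
#' Runs the full pipeline on prepared gait-cycle windows: per-trial
#' normalization, padding to a common length, one fold per subject
#' (balanced undersampling, train/validation split, train-set augmentation,
#' optional sensor masking), Transformer training, and prediction of the
#' held-out subject's unaugmented cycles. Per-cycle predictions are pooled
#' across folds. Per-fold seeds are `seed + fold index`.
#'
#' @param windows list of `gait_cycle` windows ([segment_cohort()]).
#' @param model_cfg a [model_config()]; its `seq_len` is overridden by
#'   `length_max`.
#' @param train_cfg a [train_config()].
#' @param excluded_sites sensor sites masked to 0.5 in every set.
#' @param seed master seed.
#' @param length_max padding length (default: longest observed cycle).
#' @param val_fraction,n_copies,noise_half_width fold-assembly parameters.
#' @param fold_metric `"pooled"` (single cycle-level confusion matrix,
#'   default) — per-fold accuracies are always available in the result.
#' @param verbose print per-fold progress.
#' @return Object of class `loocv_result`: `cm`, `metrics`,
#'   `per_subject_accuracy`, `predictions` (per-cycle log), `sensor_set`,
#'   `n_models`.
#' @export
run_loocv <- function(windows, model_cfg = model_config(),
                      train_cfg = train_config(),
                      excluded_sites = character(), seed = 1L,
                      length_max = NULL, val_fraction = 0.1,
                      n_copies = 4L, noise_half_width = 0.1,
                      verbose = FALSE) {
  samples <- prepare_samples(windows, length_max = length_max)
  L <- nrow(samples[[1L]]$matrix)
  model_cfg$seq_len <- L
  ids <- vapply(samples, `[[`, character(1), "subject_id")
  subjects <- unique(ids)
  if (length(subjects) < 2L) stop("LOOCV needs at least 2 subjects")
  labels <- vapply(samples, `[[`, character(1), "label")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  logs <- vector("list", length(subjects))
  for (f in seq_along(subjects)) {
    held <- subjects[f]
    fold_seed <- seed + f
    fold <- assemble_fold(samples, held, val_fraction = val_fraction,
                          seed = fold_seed, n_copies = n_copies,
                          noise_half_width = noise_half_width,
                          excluded_sites = excluded_sites)
    # leakage guard: the held-out subject must not appear in train or val
    train_ids <- vapply(c(fold$train, fold$val), `[[`, character(1),
                        "subject_id")
    stopifnot(!held %in% train_ids)
    model <- build_model(model_cfg, seed = fold_seed)
    tc <- train_cfg; tc$seed <- fold_seed
    model <- train_model(model, fold$train, fold$val, tc)
    pred <- predict(model, fold$test)
    logs[[f]] <- data.frame(
      subject_id = held,
      cycle_index = seq_along(fold$test),
      truth = vapply(fold$test, `[[`, character(1), "label"),
      predicted = as.character(pred$label),
      p_na = pred$prob[, "NA"],
      stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("fold %d/%d (%s): %d/%d cycles correct", f,
                      length(subjects), held,
                      sum(logs[[f]]$truth == logs[[f]]$predicted),
                      nrow(logs[[f]])))
  }
  predictions <- do.call(rbind, logs)
  cm <- confusion_matrix(predictions$truth, predictions$predicted)
  per_subj <- vapply(split(predictions, predictions$subject_id),
                     function(d) mean(d$truth == d$predicted), numeric(1))
  structure(list(cm = cm, metrics = compute_metrics(cm),
                 per_subject_accuracy = per_subj,
                 predictions = predictions,
                 sensor_set = setdiff(sensor_sites(), excluded_sites),
                 excluded_sites = excluded_sites,
                 n_models = length(subjects), seed = seed),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0("<loocv_result> %d folds, %d cycles | accuracy %.3f, ",
                     "sensitivity %.3f, specificity %.3f\n"),
              x$n_models, nrow(x$predictions), m$accuracy, m$sensitivity,
              m$specificity))
  cat("  sensors:", paste(x$sensor_set, collapse = ", "), "\n")
  invisible(x)
}

#' Sensor subsets of the ablation protocol
#'
#' `"full"`: all 8 sensors; `"loo"`: the eight leave-one-sensor-out subsets;
#' `"named"`: the reduced montages examined after the screen — five sensors
#' (right ankle, left wrist, right wrist, right thigh, chest), three
#' (right ankle, both wrists) and the two two-sensor montages
#' (right ankle + left wrist, right ankle + right wrist).
#'
#' @param sweep subset of `c("full", "loo", "named")`.
#' @return Named list of character vectors of retained sites.
#' @export
ablation_subsets <- function(sweep = c("full", "loo", "named")) {
  sweep <- match.arg(sweep, c("full", "loo", "named"), several.ok = TRUE)
  subsets <- list()
  if ("full" %in% sweep) subsets[["all_8"]] <- sensor_sites()
  if ("loo" %in% sweep) {
    for (s in sensor_sites())
      subsets[[paste0("minus_", s)]] <- setdiff(sensor_sites(), s)
  }
  if ("named" %in% sweep) {
    subsets[["five"]] <- c("right_ankle", "left_wrist", "right_wrist",
                           "right_thigh", "chest")
    subsets[["three"]] <- c("right_ankle", "left_wrist", "right_wrist")
    subsets[["two_ra_lw"]] <- c("right_ankle", "left_wrist")
    subsets[["two_ra_rw"]] <- c("right_ankle", "right_wrist")
  }
  subsets
}

#' Sensor-ablation sweep
#'
#' Repeats [run_loocv()] for each requested sensor subset (excluded sensors'
#' channels are replaced by the 0.5 baseline in training, validation and
#' test alike) and tabulates pooled metrics per condition.
#'
#' @param windows list of `gait_cycle` windows.
#' @param model_cfg,train_cfg model and training configuration.
#' @param sweep which subsets to run; see [ablation_subsets()].
#' @param seed master seed (shared across conditions so folds differ only in
#'   masking).
#' @param ... passed to [run_loocv()].
#' @return Object of class `ablation_sweep`: list of `loocv_result` plus a
#'   `table` data frame (sensor_set, accuracy, sensitivity, specificity).
#' @export
ablation_sweep <- function(windows, model_cfg = model_config(),
                           train_cfg = train_config(),
                           sweep = c("full", "loo", "named"), seed = 1L,
                           ...) {
  subsets <- ablation_subsets(sweep)
  results <- lapply(subsets, function(keep) {
    run_loocv(windows, model_cfg, train_cfg,
              excluded_sites = setdiff(sensor_sites(), keep),
              seed = seed, ...)
  })
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    m <- results[[nm]]$metrics
    data.frame(condition = nm,
               sensor_set = paste(results[[nm]]$sensor_set, collapse = "+"),
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, stringsAsFactors = FALSE)
  }))
  structure(list(results = results, table = tab), class = "ablation_sweep")
}

#' @export
print.ablation_sweep <- function(x, ...) {
  cat("<ablation_sweep>\n")
  print(x$table[, c("condition", "accuracy", "sensitivity", "specificity")],
        row.names = FALSE)
  invisible(x)
}

#' Write evaluation reports
#'
#' Writes a metrics table (`metrics.csv`: sensor_set, accuracy, sensitivity,
#' specificity), the pooled per-cycle prediction log, per-subject accuracy
#' bar data and one confusion-matrix figure (PNG) per condition.
#'
#' @param results a `loocv_result`, an `ablation_sweep`, or a list of
#'   `loocv_result`.
#' @param out_dir output directory (created).
#' @return Invisibly, the paths written.
#' @export
report_results <- function(results, out_dir) {
  if (inherits(results, "loocv_result")) results <- list(run = results)
  if (inherits(results, "ablation_sweep")) results <- results$results
  if (!length(results)) stop("no results to report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(results)))
    names(results) <- paste0("run", seq_along(results))
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    m <- results[[nm]]$metrics
    data.frame(sensor_set = paste(results[[nm]]$sensor_set, collapse = "+"),
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, stringsAsFactors = FALSE)
  }))
  paths <- file.path(out_dir, "metrics.csv")
  utils::write.csv(tab, paths, row.names = FALSE)
  preds <- do.call(rbind, lapply(names(results), function(nm)
    cbind(condition = nm, results[[nm]]$predictions)))
  p2 <- file.path(out_dir, "predictions.csv")
  utils::write.csv(preds, p2, row.names = FALSE)
  paths <- c(paths, p2)
  subj <- do.call(rbind, lapply(names(results), function(nm) {
    acc <- results[[nm]]$per_subject_accuracy
    data.frame(condition = nm, subject_id = names(acc), accuracy = acc,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  p3 <- file.path(out_dir, "per_subject_accuracy.csv")
  utils::write.csv(subj, p3, row.names = FALSE)
  paths <- c(paths, p3)
  for (nm in names(results)) {
    p4 <- file.path(out_dir, paste0("confusion_", nm, ".png"))
    grDevices::png(p4, width = 480, height = 480)
    .plot_confusion(results[[nm]]$cm, main = nm)
    grDevices::dev.off()
    paths <- c(paths, p4)
  }
  invisible(paths)
}

.plot_confusion <- function(cm, main = "") {
  counts <- matrix(c(cm$tp, cm$fp, cm$fn, cm$tn), 2, 2)
  graphics::image(1:2, 1:2, counts[, 2:1], col = grDevices::hcl.colors(25, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "True", main = main)
  graphics::axis(1, at = 1:2, labels = c("NA", "WA"))
  graphics::axis(2, at = 1:2, labels = c("WA", "NA"))
  lab <- matrix(c(cm$tp, cm$fp, cm$fn, cm$tn), 2, 2)
  for (i in 1:2) for (j in 1:2)
    graphics::text(i, 3 - j, lab[j, i], cex = 2)
}
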