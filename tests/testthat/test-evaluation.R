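# Metrics, LOOCV orchestration and the ablation protocol.

test_that("compute_metrics evaluates the defining formulas exactly", {
  m <- compute_metrics(list(tp = 9, fn = 1, fp = 2, tn = 8))
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  perfect <- compute_metrics(list(tp = 5, fn = 0, fp = 0, tn = 7))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1))
  # zero denominators are undefined, not zero
  und <- compute_metrics(list(tp = 0, fn = 0, fp = 1, tn = 4))
  expect_true(is.na(und$sensitivity))
  expect_false(is.na(und$specificity))
  expect_error(compute_metrics(list(tp = 0, fn = 0, fp = 0, tn = 0)),
               "empty")
})

test_that("confusion_matrix counts with the NA group as positive", {
  truth <- c("NA", "NA", "WA", "WA", "NA")
  pred <- c("NA", "WA", "NA", "WA", "NA")
  cm <- confusion_matrix(truth, pred)
  expect_equal(cm$tp, 2); expect_equal(cm$fn, 1)
  expect_equal(cm$fp, 1); expect_equal(cm$tn, 1)
  expect_error(confusion_matrix("yes", "NA"))
})

test_that("LOOCV trains one model per subject and pools per-cycle results", {
  w <- get_tiny_windows()
  res <- get_small_loocv()
  n_subj <- length(unique(vapply(w, `[[`, character(1), "subject_id")))
  expect_equal(res$n_models, n_subj)
  # every subject appears exactly once as a test subject
  expect_setequal(unique(res$predictions$subject_id),
                  unique(vapply(w, `[[`, character(1), "subject_id")))
  # conservation: pooled matrix total equals the number of test cycles
  expect_equal(with(res$cm, tp + fn + fp + tn), nrow(res$predictions))
  expect_equal(nrow(res$predictions), length(w))
  expect_true(all(res$per_subject_accuracy >= 0 &
                    res$per_subject_accuracy <= 1))
})

test_that("metrics agree with brute-force recounting of the prediction log", {
  res <- get_small_loocv()
  p <- res$predictions
  # independent recount straight from the per-cycle log
  tp <- sum(p$truth == "NA" & p$predicted == "NA")
  fn <- sum(p$truth == "NA" & p$predicted == "WA")
  fp <- sum(p$truth == "WA" & p$predicted == "NA")
  tn <- sum(p$truth == "WA" & p$predicted == "WA")
  expect_identical(c(res$cm$tp, res$cm$fn, res$cm$fp, res$cm$tn),
                   c(tp, fn, fp, tn))
  expect_equal(res$metrics$accuracy, mean(p$truth == p$predicted))
  # accuracy is the prevalence-weighted mean of sensitivity and specificity
  prev <- (tp + fn) / nrow(p)
  expect_equal(res$metrics$accuracy,
               prev * res$metrics$sensitivity +
                 (1 - prev) * res$metrics$specificity,
               tolerance = 1e-12)
  # per-subject accuracies are reproducible from the stored log
  recomputed <- vapply(split(p, p$subject_id),
                       function(d) mean(d$truth == d$predicted), numeric(1))
  expect_equal(res$per_subject_accuracy, recomputed)
})

test_that("the ablation protocol enumerates 13 sensor subsets", {
  subsets <- ablation_subsets()
  expect_length(subsets, 13L)                    # 1 full + 8 LOO + 4 named
  expect_identical(subsets$all_8, sensor_sites())
  expect_true(all(lengths(subsets[paste0("minus_", sensor_sites())]) == 7L))
  expect_setequal(subsets$five, c("right_ankle", "left_wrist", "right_wrist",
                                  "right_thigh", "chest"))
  expect_setequal(subsets$three, c("right_ankle", "left_wrist",
                                   "right_wrist"))
  expect_length(ablation_subsets("full"), 1L)
})

test_that("excluded sensors are constant 0.5 in every fold input", {
  w <- get_tiny_windows()
  samples <- prepare_samples(w)
  excl <- setdiff(sensor_sites(), c("right_ankle", "right_wrist"))
  subj <- unique(vapply(samples, `[[`, character(1), "subject_id"))
  for (held in subj[1:2]) {
    fold <- assemble_fold(samples, held, seed = 9, excluded_sites = excl)
    cols <- site_columns(excl)
    for (set in fold)
      for (s in set) expect_true(all(s$matrix[, cols] == 0.5))
  }
})

test_that("an all-site exclusion-free sweep condition equals the plain run", {
  # identical seeds and no masking must reproduce the same predictions
  w <- get_tiny_windows()
  tc <- train_config(epochs = 1L, batch_size = 16L, learning_rate = 1e-3)
  mc <- model_config(n_blocks = 1L, ff_dim = 16L)
  r1 <- run_loocv(w, mc, tc, seed = 77)
  r2 <- run_loocv(w, mc, tc, excluded_sites = character(0), seed = 77)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("report_results writes the metric table and prediction logs", {
  res <- get_small_loocv()
  dir <- tempfile("report")
  paths <- report_results(res, dir)
  tab <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_identical(names(tab), c("sensor_set", "accuracy", "sensitivity",
                                 "specificity"))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$accuracy, res$metrics$accuracy)
  preds <- utils::read.csv(file.path(dir, "predictions.csv"))
  expect_equal(nrow(preds), nrow(res$predictions))
  expect_true(file.exists(file.path(dir, "per_subject_accuracy.csv")))
  expect_true(any(grepl("confusion_.*png$", paths)))
  unlink(dir, recursive = TRUE)
})
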