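test_that("fusion follows the highest-probability rule with not_fall ties", {
  p1 <- class_probabilities(0.9, 0.1, 1, "e1")
  p2 <- class_probabilities(0.2, 0.8, 2, "e1")
  expect_equal(fuse_decision(p1, p2, rule = "max"), "fall")

  same <- class_probabilities(0.7, 0.3, 1, "e2")
  same2 <- class_probabilities(0.7, 0.3, 2, "e2")
  expect_equal(fuse_decision(same, same2, "max"), "fall")
  expect_equal(fuse_decision(same, same2, "mean"), "fall")

  tie1 <- class_probabilities(0.5, 0.5, 1, "e3")
  tie2 <- class_probabilities(0.5, 0.5, 2, "e3")
  expect_equal(fuse_decision(tie1, tie2, "max"), "not_fall")
  expect_equal(fuse_decision(tie1, tie2, "mean"), "not_fall")

  expect_error(
    fuse_decision(
      class_probabilities(0.9, 0.1, 1, "e1"),
      class_probabilities(0.9, 0.1, 2, "e9")
    ),
    "same event"
  )
  expect_error(class_probabilities(0.9, 0.3), "1e-06|<=")
})

test_that("fusion is invariant to radar order", {
  set.seed(31)
  for (k in 1:50) {
    a <- runif(1)
    b <- runif(1)
    p1 <- class_probabilities(a, 1 - a, 1, "e")
    p2 <- class_probabilities(b, 1 - b, 2, "e")
    for (rule in c("max", "mean")) {
      expect_identical(
        fuse_decision(p1, p2, rule),
        fuse_decision(p2, p1, rule)
      )
    }
  }
})

test_that("confusion counting matches a brute-force recount", {
  pred <- rep(c("fall", "not_fall"), each = 70)
  cm <- evaluate_predictions(pred, pred)
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(70, 70, 0, 0))

  flip <- ifelse(pred == "fall", "not_fall", "fall")
  cm <- evaluate_predictions(flip, pred)
  expect_equal(c(cm$tp, cm$tn), c(0, 0))
  expect_equal(c(cm$fp, cm$fn), c(70, 70))

  set.seed(23)
  for (k in 1:10) {
    n <- sample(20:200, 1)
    pred <- sample(c("fall", "not_fall"), n, replace = TRUE)
    lab <- sample(c("fall", "not_fall"), n, replace = TRUE)
    cm <- evaluate_predictions(pred, lab)
    bf <- brute_force_metrics(pred, lab)
    expect_equal(c(cm$tp, cm$fp, cm$tn, cm$fn), unname(bf[c("tp", "fp", "tn", "fn")]))
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
  }
  expect_error(evaluate_predictions(c("fall", "maybe"), c("fall", "fall")), "maybe")
})

test_that("metric formulas reproduce the published benchmark arithmetic", {
  # Confusion matrices reconstructed from the printed per-class rates on the
  # 140-record balanced test set.
  cases <- list(
    list(cm = confusion_matrix(tp = 69, fn = 1, tn = 70, fp = 0),
         want = c(99.29, 98.57, 100, 100, 99.28)),
    list(cm = confusion_matrix(tp = 68, fn = 2, tn = 70, fp = 0),
         want = c(98.57, 97.14, 100, 100, 98.55)),
    list(cm = confusion_matrix(tp = 60, fn = 10, tn = 63, fp = 7),
         want = c(87.86, 85.71, 90.00, 89.55, 87.59)),
    list(cm = confusion_matrix(tp = 41, fn = 29, tn = 67, fp = 3),
         want = c(77.14, 58.57, 95.71, 93.18, 71.93)),
    list(cm = confusion_matrix(tp = 50, fn = 0, tn = 50, fp = 0),
         want = c(100, 100, 100, 100, 100))
  )
  for (cs in cases) {
    m <- compute_metrics(cs$cm)
    expect_equal(
      as.numeric(m)[1:5],
      cs$want,
      tolerance = 0.005 / 50 # printed 2-decimal precision
    )
  }
})

test_that("undefined ratios are flagged, not fatal", {
  m <- compute_metrics(confusion_matrix(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(m["sensitivity"]))
  expect_true(is.na(m["precision"]))
  expect_true(all(c("sensitivity", "precision", "f1") %in% attr(m, "undefined")))
  expect_equal(unname(m["accuracy"]), 100)
  expect_error(compute_metrics(confusion_matrix(0, 0, 0, 0)), "empty")
})

test_that("metric identities hold against brute force on a dense grid", {
  for (tp in seq(0, 8, by = 2)) {
    for (fp in seq(0, 8, by = 2)) {
      for (tn in seq(0, 8, by = 2)) {
        for (fn in seq(0, 8, by = 2)) {
          if (tp + fp + tn + fn == 0) next
          m <- compute_metrics(confusion_matrix(tp, fp, tn, fn))
          n <- tp + fp + tn + fn
          expect_equal(unname(m["accuracy"]), 100 * (tp + tn) / n)
          if (tp + fn > 0) expect_equal(unname(m["sensitivity"]), 100 * tp / (tp + fn))
          if (tn + fp > 0) expect_equal(unname(m["specificity"]), 100 * tn / (tn + fp))
          if (tp + fp > 0) expect_equal(unname(m["precision"]), 100 * tp / (tp + fp))
          if (!is.na(m["f1"]) && tp > 0) {
            expect_equal(unname(m["f1"]), 100 * 2 * tp / (2 * tp + fp + fn),
              tolerance = 1e-9
            )
          }
        }
      }
    }
  }
  # Larger random counts, same identities.
  set.seed(41)
  for (k in 1:25) {
    cts <- sample(0:200, 4, replace = TRUE)
    if (sum(cts) == 0) next
    m <- compute_metrics(confusion_matrix(cts[1], cts[2], cts[3], cts[4]))
    if (cts[1] > 0) {
      expect_equal(
        unname(m["f1"]),
        100 * 2 * cts[1] / (2 * cts[1] + cts[2] + cts[4]),
        tolerance = 1e-9
      )
    }
  }
})

test_that("subject-wise splitting partitions records without leakage", {
  # Manifest mirroring the full study design, built directly.
  manifest <- expand.grid(
    subject_id = 1:5, event = 1:70, radar_id = 1:2,
    KEEP.OUT.ATTRS = FALSE
  )
  manifest$record_id <- sprintf(
    "s%02d_e%03d_r%d",
    manifest$subject_id, manifest$event, manifest$radar_id
  )
  sp <- split_by_subject(manifest, train_subjects = 1:3)
  per_radar <- function(ids, r) sum(grepl(paste0("_r", r, "$"), ids))
  expect_equal(per_radar(sp$train_records, 1), 210)
  expect_equal(per_radar(sp$test_records, 1), 140)
  expect_equal(per_radar(sp$train_records, 2), 210)
  expect_equal(per_radar(sp$test_records, 2), 140)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  expect_setequal(
    c(sp$train_records, sp$test_records),
    manifest$record_id
  )
  expect_error(split_by_subject(manifest, 1:5), "empty")
  expect_error(split_by_subject(manifest, c(1, 9)), "9")
})
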