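test_that("confusion joins predictions to labels and tracks coverage", {
  preds <- data.frame(
    protein_id = c("p", "p", "q", "q"), position = c(1L, 2L, 1L, 2L),
    wild_type = c("A", "L", "G", "V"), mutant = c("C", "M", "W", "I"),
    call = c("damaging", "damaging", "tolerated", "tolerated"),
    stringsAsFactors = FALSE
  )
  labels <- data.frame(
    protein_id = c("p", "p", "q", "q"), position = c(1L, 2L, 1L, 2L),
    wild_type = c("A", "L", "G", "V"), mutant = c("C", "M", "W", "I"),
    label = c("disease", "disease", "neutral", "disease"),
    stringsAsFactors = FALSE
  )
  cc <- confusion(preds, labels)
  expect_identical(c(cc$tp, cc$fp, cc$tn, cc$fn), c(2L, 0L, 1L, 1L))
  expect_equal(cc$coverage, 1)
  # no_prediction records are excluded and counted
  preds$call[2] <- "no_prediction"
  cc2 <- confusion(preds, labels)
  expect_identical(c(cc2$tp, cc2$fn), c(1L, 1L))
  expect_identical(cc2$n_no_prediction, 1L)
  expect_equal(cc2$coverage, 0.75)
  # all no_prediction
  preds$call <- "no_prediction"
  cc3 <- confusion(preds, labels)
  expect_identical(c(cc3$tp, cc3$fp, cc3$tn, cc3$fn), c(0L, 0L, 0L, 0L))
  expect_equal(cc3$coverage, 0)
  # label without a prediction row -> join error
  labels2 <- rbind(labels, data.frame(protein_id = "z", position = 1L,
                                      wild_type = "A", mutant = "C",
                                      label = "disease"))
  expect_error(confusion(preds, labels2), "without a matching prediction")
})

test_that("class-balance normalization rescales each class to unit mass", {
  cc <- confusion_counts(5, 0, 5, 0)
  n <- normalize_counts(cc)
  expect_equal(c(n$tp, n$fp, n$tn, n$fn), c(1, 0, 1, 0))
  cc2 <- confusion_counts(14231, 1633, 10146, 2336)
  n2 <- normalize_counts(cc2)
  expect_equal(n2$tp, 14231 / (14231 + 2336), tolerance = 1e-12)
  expect_equal(n2$tn, 10146 / (10146 + 1633), tolerance = 1e-12)
  expect_equal(n2$tp, 0.8590, tolerance = 5e-5)
  expect_equal(n2$tn, 0.8614, tolerance = 5e-5)
  expect_equal(n2$tp + n2$fn, 1)
  expect_equal(n2$tn + n2$fp, 1)
  cc3 <- confusion_counts(0, 2, 3, 4)
  n3 <- normalize_counts(cc3)
  expect_equal(c(n3$tp, n3$fn), c(0, 1))
  expect_error(normalize_counts(confusion_counts(0, 1, 1, 0)),
               "no positive")
})

test_that("the six metrics follow their formulae", {
  cc <- confusion_counts(6, 2, 8, 4)
  ms <- metrics(cc)
  expect_equal(ms$accuracy, 14 / 20)
  expect_equal(ms$precision, 6 / 8)
  expect_equal(ms$specificity, 8 / 10)
  expect_equal(ms$sensitivity, 6 / 10)
  expect_equal(ms$npv, 8 / 12)
  expect_equal(ms$mcc, (6 * 8 - 2 * 4) / sqrt(8 * 10 * 10 * 12),
               tolerance = 1e-12)
  # perfect classifier
  perfect <- metrics(confusion_counts(7, 0, 9, 0))
  expect_equal(unlist(perfect[1:6]), stats::setNames(rep(1, 6),
    c("accuracy", "precision", "specificity", "sensitivity", "npv",
      "mcc")))
  expect_error(metrics(confusion_counts(0, 0, 5, 5)), "precision")
})

test_that("normalized metrics have their closed-form identities", {
  set.seed(41)
  for (i in 1:50) {
    counts <- sample(1:5000, 4)
    cc <- confusion_counts(counts[1], counts[2], counts[3], counts[4])
    ms <- metrics(cc, normalized = TRUE)
    tpr <- counts[1] / (counts[1] + counts[4])
    tnr <- counts[3] / (counts[3] + counts[2])
    # normalized accuracy is balanced accuracy
    expect_equal(ms$accuracy, (tpr + tnr) / 2, tolerance = 1e-12)
    # normalized MCC has a closed form in TPR/TNR alone
    mcc_closed <- (tpr * tnr - (1 - tpr) * (1 - tnr)) /
      sqrt((tpr + 1 - tnr) * (tnr + 1 - tpr))
    expect_equal(ms$mcc, mcc_closed, tolerance = 1e-12)
    # sensitivity and specificity are unchanged by normalization
    raw <- metrics(cc)
    expect_equal(ms$sensitivity, raw$sensitivity, tolerance = 1e-12)
    expect_equal(ms$specificity, raw$specificity, tolerance = 1e-12)
  }
})

test_that("ROC handles hand cases and degenerate inputs", {
  # perfectly separated
  rc <- roc_curve(c(-5, -4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc$auc, 1)
  # all scores identical
  rc2 <- roc_curve(c(0, 0, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc2$auc, 0.5)
  # 4-point hand case
  rc3 <- roc_curve(c(-4, -2, -1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rc3$auc, 1)
  rc4 <- roc_curve(c(-4, -2, -1, 0), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rc4$auc, 0.75)
  expect_equal(rc4$auc,
               auc_oracle(c(-4, -2, -1, 0), c(TRUE, FALSE, TRUE, FALSE)))
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "positive and one")
})

test_that("ROC agrees with brute force and with pROC on random data", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    scores <- stats::rnorm(n)
    labels <- stats::runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    rc <- roc_curve(scores, labels)
    expect_equal(rc$auc, auc_oracle(scores, labels), tolerance = 1e-12)
    # independent cross-check: pROC with the same orientation
    proc_auc <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, direction = ">",
      quiet = TRUE)))
    expect_equal(rc$auc, proc_auc, tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(63)
  scores <- stats::rnorm(200)
  labels <- stats::runif(200) < 0.5
  base <- roc_curve(scores, labels)$auc
  for (f in list(function(x) 3 * x - 7, function(x) x^3,
                 function(x) atan(x), function(x) -exp(-x))) {
    expect_equal(roc_curve(f(scores), labels)$auc, base,
                 tolerance = 1e-12)
  }
  # orientation flag flips the curve for higher-is-positive scorers
  flipped <- roc_curve(-scores, labels, lower_is_positive = FALSE)$auc
  expect_equal(flipped, base, tolerance = 1e-12)
})

test_that("threshold calibration maximizes min(sensitivity, specificity)", {
  # separable: positives below -5, negatives above -1
  scores <- c(-8, -7, -6, -0.5, -0.2, 0)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cal <- calibrate_threshold(scores, labels)
  expect_equal(cal$sensitivity, 1)
  expect_equal(cal$specificity, 1)
  expect_gt(cal$threshold, -6)
  expect_lt(cal$threshold, -0.5)
  # two points, one per class
  cal2 <- calibrate_threshold(c(-2, 2), c(TRUE, FALSE))
  expect_equal(cal2$threshold, 0)
  expect_equal(c(cal2$sensitivity, cal2$specificity), c(1, 1))
  expect_error(calibrate_threshold(1:4, rep(TRUE, 4)), "positive and")
  # exhaustive-scan oracle on random data
  set.seed(74)
  for (i in 1:10) {
    s <- stats::rnorm(40)
    l <- stats::runif(40) < 0.5
    if (!any(l) || all(l)) next
    cal3 <- calibrate_threshold(s, l)
    grid <- sort(unique(c(s, s + 1e-9, s - 1e-9, -10, 10)))
    best <- max(sapply(grid, function(t) {
      called <- s < t
      min(sum(called & l) / sum(l), sum(!called & !l) / sum(!l))
    }))
    expect_equal(min(cal3$sensitivity, cal3$specificity), best,
                 tolerance = 1e-12)
  }
})

test_that("label-independent scores calibrate to min(sens, spec) near 0.5", {
  set.seed(85)
  s <- stats::rnorm(10000)
  l <- stats::runif(10000) < 0.5
  cal <- calibrate_threshold(s, l)
  expect_equal(min(cal$sensitivity, cal$specificity), 0.5,
               tolerance = 0.05)
})

test_that("method overlap partitions the union into Venn regions", {
  ov <- method_overlap(list(A = c("a", "b"), B = c("b", "c")))
  expect_identical(ov[["A"]], 1L)
  expect_identical(ov[["B"]], 1L)
  expect_identical(ov[["A&B"]], 1L)
  expect_identical(sum(ov), 3L)
  # disjoint sets
  ov2 <- method_overlap(list(A = "x", B = "y", C = "z"))
  expect_identical(unname(ov2[c("A&B", "A&C", "B&C", "A&B&C")]),
                   rep(0L, 4))
  expect_identical(sum(ov2), 3L)
  # random three-way fixture vs enumeration oracle
  set.seed(96)
  univ <- sprintf("m%03d", 1:200)
  sets <- lapply(1:3, function(i) sample(univ, sample(20:150, 1)))
  names(sets) <- c("X", "Y", "Z")
  ov3 <- method_overlap(sets)
  expect_identical(sum(ov3), length(unique(unlist(sets))))
  for (el in unique(unlist(sets))) {
    inside <- names(sets)[vapply(sets, function(s) el %in% s, logical(1))]
    region <- paste(inside, collapse = "&")
    # every element is counted in exactly its own region
    expect_true(region %in% names(ov3))
  }
  brute <- table(vapply(unique(unlist(sets)), function(el)
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&"), character(1)))
  for (nm in names(brute))
    expect_identical(ov3[[nm]], as.integer(brute[[nm]]))
  expect_error(method_overlap(list(a = "x")), "2 or 3")
  expect_error(method_overlap(list("x", "y")), "named")
})
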