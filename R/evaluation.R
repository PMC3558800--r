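# Classifier evaluation: confusion counts, class-balance normalization,
# the six standard performance metrics, ROC analysis, threshold
# calibration at the sensitivity = specificity optimum, and method
# overlap.

#' Confusion counts from predictions and labels
#'
#' Positives are disease-associated records, negatives neutral ones. A
#' damaging call on a disease record is a true positive; records with
#' call `no_prediction` are excluded from the counts, and the fraction of
#' labeled records that did receive a prediction is reported as
#' `coverage`.
#'
#' @param predictions data.frame from [predict_substitutions()] (needs
#'   columns `protein_id, position, wild_type, mutant, call`).
#' @param labels data.frame with columns `protein_id, position,
#'   wild_type, mutant, label` (label `disease`/`neutral`).
#' @return list of class `ConfusionCounts`: `tp, fp, tn, fn`, plus
#'   `n_no_prediction` and `coverage`.
#' @export
confusion <- function(predictions, labels) {
  pk <- paste(predictions$protein_id, predictions$position,
              predictions$wild_type, predictions$mutant, sep = "\r")
  lk <- paste(labels$protein_id, labels$position, labels$wild_type,
              labels$mutant, sep = "\r")
  i <- match(lk, pk)
  if (anyNA(i))
    stop("labels present without a matching prediction: ",
         paste(utils::head(lk[is.na(i)]), collapse = "; "))
  call <- predictions$call[i]
  label <- labels$label
  scored <- call != "no_prediction"
  counts <- list(
    tp = sum(scored & label == "disease" & call == "damaging"),
    fp = sum(scored & label == "neutral" & call == "damaging"),
    tn = sum(scored & label == "neutral" & call == "tolerated"),
    fn = sum(scored & label == "disease" & call == "tolerated"),
    n_no_prediction = sum(!scored),
    coverage = if (length(scored)) mean(scored) else 0
  )
  structure(counts, class = "ConfusionCounts")
}

#' Bare confusion counts
#'
#' @param tp,fp,tn,fn non-negative counts (reals allowed, for normalized
#'   counts).
#' @return a `ConfusionCounts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  if (any(c(tp, fp, tn, fn) < 0))
    stop("confusion counts must be non-negative")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 n_no_prediction = 0L, coverage = 1),
            class = "ConfusionCounts")
}

#' @export
print.ConfusionCounts <- function(x, ...) {
  cat(sprintf("ConfusionCounts tp=%g fp=%g tn=%g fn=%g (coverage %.3f)\n",
              x$tp, x$fp, x$tn, x$fn, x$coverage))
  invisible(x)
}

#' Class-balance normalization of confusion counts
#'
#' Rescales the positive (disease) and negative (neutral) classes to unit
#' mass: `tp' = tp/(tp+fn)`, `fn' = 1 - tp'`, `tn' = tn/(tn+fp)`,
#' `fp' = 1 - tn'`. Metrics computed on normalized counts are immune to
#' class imbalance; in particular normalized accuracy equals
#' `(sensitivity + specificity) / 2`.
#'
#' @param c a `ConfusionCounts` object.
#' @return a `ConfusionCounts` object with normalized (real) counts.
#' @export
normalize_counts <- function(c) {
  stopifnot(inherits(c, "ConfusionCounts"))
  if (c$tp + c$fn <= 0)
    stop("cannot normalize: no positive (disease) records")
  if (c$tn + c$fp <= 0)
    stop("cannot normalize: no negative (neutral) records")
  tp <- c$tp / (c$tp + c$fn)
  tn <- c$tn / (c$tn + c$fp)
  out <- confusion_counts(tp, 1 - tn, tn, 1 - tp)
  out$n_no_prediction <- c$n_no_prediction
  out$coverage <- c$coverage
  out
}

#' The six performance metrics
#'
#' Computes accuracy `(tp+tn)/(tp+fp+tn+fn)`, precision `tp/(tp+fp)`,
#' specificity `tn/(tn+fp)`, sensitivity `tp/(tp+fn)`, negative
#' predictive value `tn/(tn+fn)` and the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`. With
#' `normalized = TRUE` (how benchmark tables are usually reported) the
#' counts are first passed through [normalize_counts()].
#'
#' @param c a `ConfusionCounts` object.
#' @param normalized compute on class-balance normalized counts.
#' @return named list of class `MetricSet` with the six metrics and the
#'   `normalized` flag.
#' @export
metrics <- function(c, normalized = FALSE) {
  stopifnot(inherits(c, "ConfusionCounts"))
  if (normalized) c <- normalize_counts(c)
  need <- function(den, metric) {
    if (den <= 0) stop("undefined metric '", metric, "': zero denominator")
    den
  }
  tp <- c$tp; fp <- c$fp; tn <- c$tn; fn <- c$fn
  mcc_den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
    sqrt((tn + fn))
  structure(list(
    accuracy = (tp + tn) / need(tp + fp + tn + fn, "accuracy"),
    precision = tp / need(tp + fp, "precision"),
    specificity = tn / need(tn + fp, "specificity"),
    sensitivity = tp / need(tp + fn, "sensitivity"),
    npv = tn / need(tn + fn, "npv"),
    mcc = (tp * tn - fp * fn) / need(mcc_den, "mcc"),
    normalized = normalized
  ), class = "MetricSet")
}

#' @export
print.MetricSet <- function(x, ...) {
  cat(sprintf(paste0("MetricSet%s: acc %.3f prec %.3f spec %.3f ",
                     "sens %.3f npv %.3f mcc %.3f\n"),
              if (x$normalized) " (normalized)" else "",
              x$accuracy, x$precision, x$specificity, x$sensitivity,
              x$npv, x$mcc))
  invisible(x)
}

# Candidate thresholds: midpoints between adjacent distinct scores plus
# sentinels below and above everything.
candidate_thresholds <- function(scores) {
  s <- sort(unique(scores))
  c(-Inf, if (length(s) > 1L) (s[-1L] + s[-length(s)]) / 2, Inf)
}

# Sensitivity/specificity at one threshold under the strict-inequality
# damaging rule (score < t = positive call).
sens_spec_at <- function(scores, positive, t) {
  called <- scores < t
  c(sens = sum(called & positive) / sum(positive),
    spec = sum(!called & !positive) / sum(!positive))
}

#' ROC curve and area under it
#'
#' Sweeps all candidate thresholds (midpoints between adjacent distinct
#' scores plus sentinels) with the convention that a lower score is more
#' disease-like (set `lower_is_positive = FALSE` for scorers oriented the
#' other way), and integrates the curve by the trapezoid rule. The AUC is
#' invariant under strictly monotone transformations of the scores.
#'
#' @param scores numeric scores.
#' @param labels logical (`TRUE` = disease) or character
#'   (`"disease"`/`"neutral"`) labels, one per score.
#' @param lower_is_positive orientation flag (default `TRUE`).
#' @param max_fpr optionally truncate the returned curve at this
#'   false-positive rate (the AUC is still over the full curve).
#' @return list of class `RocCurve`: `points` (data.frame `threshold,
#'   fpr, tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels, lower_is_positive = TRUE,
                      max_fpr = NULL) {
  positive <- if (is.logical(labels)) labels else labels == "disease"
  if (!any(positive) || all(positive))
    stop("ROC needs at least one positive and one negative record")
  s <- if (lower_is_positive) scores else -scores
  ts <- candidate_thresholds(s)
  pts <- t(vapply(ts, function(t) {
    ss <- sens_spec_at(s, positive, t)
    c(fpr = 1 - ss[["spec"]], tpr = ss[["sens"]])
  }, c(fpr = 0, tpr = 0)))
  ord <- order(pts[, "fpr"], pts[, "tpr"])
  pts <- pts[ord, , drop = FALSE]
  ts <- ts[ord]
  auc <- sum(diff(pts[, "fpr"]) *
             (utils::head(pts[, "tpr"], -1) + utils::tail(pts[, "tpr"], -1)) / 2)
  points <- data.frame(threshold = ts, fpr = pts[, "fpr"],
                       tpr = pts[, "tpr"])
  if (!is.null(max_fpr))
    points <- points[points$fpr <= max_fpr, , drop = FALSE]
  structure(list(points = points, auc = auc), class = "RocCurve")
}

#' @export
print.RocCurve <- function(x, ...) {
  cat(sprintf("RocCurve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Calibrate a prediction threshold
#'
#' Returns the threshold at which sensitivity and specificity are jointly
#' maximized: among candidate thresholds (midpoints between adjacent
#' distinct scores plus infinite sentinels) the one maximizing
#' `min(sensitivity, specificity)`; ties break toward the larger
#' `sensitivity + specificity`, then toward the larger threshold.
#'
#' @inheritParams roc_curve
#' @return list of class `ThresholdCalibration`: `threshold`,
#'   `sensitivity`, `specificity` at that threshold.
#' @export
calibrate_threshold <- function(scores, labels, lower_is_positive = TRUE) {
  positive <- if (is.logical(labels)) labels else labels == "disease"
  if (!any(positive) || all(positive))
    stop("calibration needs at least one positive and one negative record")
  s <- if (lower_is_positive) scores else -scores
  ts <- candidate_thresholds(s)
  prof <- t(vapply(ts, function(t) sens_spec_at(s, positive, t),
                   c(sens = 0, spec = 0)))
  key <- cbind(pmin(prof[, "sens"], prof[, "spec"]),
               prof[, "sens"] + prof[, "spec"], ts)
  best <- order(-key[, 1L], -key[, 2L], -key[, 3L])[1L]
  t_best <- ts[[best]]
  if (!lower_is_positive) t_best <- -t_best
  structure(list(threshold = t_best,
                 sensitivity = unname(prof[best, "sens"]),
                 specificity = unname(prof[best, "spec"])),
            class = "ThresholdCalibration")
}

#' @export
print.ThresholdCalibration <- function(x, ...) {
  cat(sprintf("ThresholdCalibration: t = %.4f (sens %.3f, spec %.3f)\n",
              x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Overlap (Venn region) counts of correctly identified positives
#'
#' Given two or three named sets of correctly identified positives, one
#' per method, counts every Venn region. The regions partition the union
#' of the sets.
#'
#' @param tp_sets named list of 2 or 3 character vectors.
#' @return named integer vector of region counts; region names join
#'   method names with `&` (e.g. `"A"`, `"A&B"`, `"A&B&C"`).
#' @export
method_overlap <- function(tp_sets) {
  k <- length(tp_sets)
  if (k < 2L || k > 3L)
    stop("method_overlap supports 2 or 3 sets, got ", k)
  if (is.null(names(tp_sets)) || any(!nzchar(names(tp_sets))))
    stop("tp_sets must be named")
  sets <- lapply(tp_sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  out <- integer(nrow(combos))
  nm <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    sel <- as.logical(combos[r, ])
    inside <- rowSums(membership[, sel, drop = FALSE]) == sum(sel)
    outside <- rowSums(membership[, !sel, drop = FALSE]) == 0
    out[[r]] <- sum(inside & outside)
    nm[[r]] <- paste(names(sets)[sel], collapse = "&")
  }
  stats::setNames(out, nm)
}
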