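#' Clinical outcome change from baseline
#'
#' Per-patient gain of an outcome scale (FMA, 0-66, or ARAT, 0-57) at a
#' follow-up week relative to the pre-trial baseline (week 0, phase "pre"),
#' with the mean gain, its standard error (sd / sqrt(n)), and a one-tailed
#' paired t-test of improvement > 0. With zero variance in the gains the
#' t-statistic is undefined: the boundary convention returns p = 0.5 for a
#' zero mean gain, p = 0 for a positive one and p = 1 for a negative one.
#'
#' @param table `data.frame` with columns `patient_id`, `scale`, `week`,
#'   `phase` (`"pre"`/`"post"`), `score`.
#' @param week Follow-up week to compare (e.g. 6 or 12).
#' @param scale Outcome scale to analyse (`"FMA"` or `"ARAT"`).
#' @param baseline_week,baseline_phase Definition of the pre-trial baseline.
#' @return A list: `mean_gain`, `sem`, `p_value`, `n`, `gains`.
#' @export
outcome_change <- function(table, week, scale = "FMA",
                           baseline_week = 0, baseline_phase = "pre") {
  d <- table[table$scale == scale, , drop = FALSE]
  base <- d[d$week == baseline_week & d$phase == baseline_phase, ]
  foll <- d[d$week == week, ]
  ids <- intersect(base$patient_id, foll$patient_id)
  if (length(ids) < 2)
    stop("need at least 2 patients with both timepoints", call. = FALSE)
  gains <- vapply(ids, function(id) {
    foll$score[foll$patient_id == id][1] -
      base$score[base$patient_id == id][1]
  }, numeric(1))
  m <- mean(gains)
  if (sd(gains) == 0) {
    p <- if (m > 0) 0 else if (m < 0) 1 else 0.5
    return(list(mean_gain = m, sem = 0, p_value = p, n = length(gains),
                gains = gains))
  }
  tt <- t.test(gains, mu = 0, alternative = "greater")
  list(mean_gain = m, sem = sd(gains) / sqrt(length(gains)),
       p_value = tt$p.value, n = length(gains), gains = gains)
}

#' Confusion-matrix summary metrics
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)` and accuracy
#' `(TP + TN) / total` of binary predictions. If a class is absent from the
#' labels, the corresponding rate is undefined and returned as `NA` with a
#' warning.
#'
#' @param predictions,labels Vectors of predicted and true class labels.
#' @param positive Label of the positive class (default: `"mi"` when
#'   present, otherwise the last sorted level of `labels`).
#' @return A list: `sensitivity`, `specificity`, `accuracy`, `confusion`.
#' @export
confusion_metrics <- function(predictions, labels, positive = NULL) {
  predictions <- as.character(predictions)
  labels <- as.character(labels)
  if (length(predictions) != length(labels))
    stop("`predictions` and `labels` must have equal length", call. = FALSE)
  lev <- sort(unique(c(labels, predictions)))
  if (is.null(positive)) positive <- if ("mi" %in% lev) "mi" else lev[length(lev)]
  tp <- sum(predictions == positive & labels == positive)
  fn <- sum(predictions != positive & labels == positive)
  tn <- sum(predictions != positive & labels != positive)
  fp <- sum(predictions == positive & labels != positive)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  if (is.na(sens) || is.na(spec))
    warning("single-class labels: a rate is undefined", call. = FALSE)
  list(sensitivity = sens, specificity = spec,
       accuracy = (tp + tn) / length(labels),
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}
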