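#' Build a spatial-temporal feature matrix from hemoglobin epochs
#'
#' The post-cue HbO of each trial is averaged into `n_time_bins` equal time
#' bins per channel and vectorized (channel-major: all bins of channel 1,
#' then channel 2, ...). Features are returned unscaled; z-scoring happens
#' inside cross-validation using training-fold statistics only, so no
#' information from validation trials leaks into the scaling.
#'
#' @param epochs A `hb_epochs` from [extract_epochs()].
#' @param n_time_bins Number of time bins over the post-cue window.
#' @param window Post-cue window (s) to featurize, default `c(0, 9)`.
#' @return A list of class `feature_matrix`: `x` (trials x features),
#'   `labels`, `feature_names`, `n_time_bins`.
#' @export
build_features <- function(epochs, n_time_bins = 3, window = c(0, 9)) {
  if (!inherits(epochs, "hb_epochs"))
    stop("`epochs` must be an hb_epochs", call. = FALSE)
  sel <- which(epochs$rel_time >= window[1] & epochs$rel_time <= window[2])
  if (n_time_bins > length(sel))
    stop("`n_time_bins` exceeds the number of post-cue samples", call. = FALSE)
  if (length(unique(epochs$labels)) < 2)
    stop("need at least two classes", call. = FALSE)
  bins <- split(sel, cut(seq_along(sel), n_time_bins, labels = FALSE))
  nt <- dim(epochs$hbo)[1]
  n_ch <- dim(epochs$hbo)[2]
  x <- matrix(NA_real_, nt, n_ch * n_time_bins)
  for (c_i in seq_len(n_ch)) {
    for (b in seq_len(n_time_bins)) {
      x[, (c_i - 1) * n_time_bins + b] <-
        rowMeans(epochs$hbo[, c_i, bins[[b]], drop = FALSE], dims = 1)
    }
  }
  fn <- as.vector(t(outer(
    if (is.null(epochs$channels)) paste0("ch", seq_len(n_ch)) else epochs$channels,
    paste0("bin", seq_len(n_time_bins)), paste, sep = ".")))
  colnames(x) <- fn
  structure(list(x = x, labels = epochs$labels, feature_names = fn,
                 n_time_bins = n_time_bins),
            class = "feature_matrix")
}

# Shrinkage-regularized LDA. Pooled covariance shrunk toward a scaled
# identity: S_g = (1 - gamma) S + gamma * mean(diag(S)) * I, which keeps the
# fit well-posed when features outnumber trials.
.lda_fit <- function(x, y, gamma = 0.3) {
  lev <- sort(unique(y))
  stopifnot(length(lev) == 2)
  x0 <- x[y == lev[1], , drop = FALSE]
  x1 <- x[y == lev[2], , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  n0 <- nrow(x0); n1 <- nrow(x1)
  sc <- (crossprod(sweep(x0, 2, m0)) + crossprod(sweep(x1, 2, m1))) /
    (n0 + n1 - 2)
  p <- ncol(x)
  sg <- (1 - gamma) * sc + gamma * mean(diag(sc)) * diag(p)
  w <- solve(sg, m1 - m0)
  b <- -sum(w * (m0 + m1)) / 2 + log(n1 / n0)
  list(w = w, b = b, levels = lev, means = cbind(m0, m1))
}

.lda_decision <- function(fit, x) {
  as.numeric(x %*% fit$w + fit$b)
}

# Stratified fold assignment: within each class, shuffled balanced folds.
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- which(labels == lev)
    if (length(idx) < k)
      stop("fewer than k trials in class '", lev, "'", call. = FALSE)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated motor-imagery decoding
#'
#' Stratified k-fold cross-validation of a shrinkage-regularized linear
#' discriminant on the spatial-temporal features. Within each fold, features
#' are z-scored with training-fold statistics, the discriminant is fit on the
#' training trials, and decision values are computed for the held-out trials.
#' Reports per-fold accuracy, the pooled AUC-ROC over all out-of-fold
#' decision values, and sensitivity/specificity with the motor-imagery class
#' as positive.
#'
#' @param features A `feature_matrix` from [build_features()], or a numeric
#'   matrix (then supply `labels`).
#' @param labels Class labels (two classes), taken from `features` if absent.
#' @param k Number of folds; every class must have at least `k` trials.
#' @param seed Integer seed for the fold assignment.
#' @param gamma Covariance shrinkage intensity in `[0, 1]`.
#' @param positive Label treated as the positive (motor-imagery) class;
#'   defaults to `"mi"` when present, otherwise the last sorted level.
#' @param auc_per_fold If `TRUE`, also return the mean of per-fold AUCs.
#' @return A list of class `decoder_result`: `fold_accuracy`, `accuracy`
#'   (pooled), `auc`, `sensitivity`, `specificity`, `confusion` (tp, fp, tn,
#'   fn), `decision_values`, `positive`, `seed`.
#' @export
crossval_decode <- function(features, labels = NULL, k = 10, seed = 1L,
                            gamma = 0.3, positive = NULL,
                            auc_per_fold = FALSE) {
  if (inherits(features, "feature_matrix")) {
    x <- features$x
    if (is.null(labels)) labels <- features$labels
  } else x <- as.matrix(features)
  if (is.null(labels)) stop("`labels` required", call. = FALSE)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- if ("mi" %in% lev) "mi" else lev[2]
  negative <- setdiff(lev, positive)

  set.seed(seed)
  fold <- .stratified_folds(labels, k)
  dec <- numeric(length(labels))
  fold_acc <- numeric(k)
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- fold != f
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- apply(x[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    xs <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    # discriminant oriented so positive class has positive decision values
    yy <- ifelse(labels == positive, "z_pos", "a_neg")
    fit <- .lda_fit(xs[tr, , drop = FALSE], yy[tr], gamma)
    d <- .lda_decision(fit, xs[!tr, , drop = FALSE])
    dec[!tr] <- d
    pred <- ifelse(d > 0, positive, negative)
    fold_acc[f] <- mean(pred == labels[!tr])
    if (auc_per_fold && length(unique(labels[!tr])) == 2) {
      fold_auc[f] <- as.numeric(pROC::auc(
        pROC::roc(labels[!tr], d, levels = c(negative, positive),
                  direction = "<", quiet = TRUE)))
    }
  }
  pred_all <- ifelse(dec > 0, positive, negative)
  tp <- sum(pred_all == positive & labels == positive)
  fn <- sum(pred_all == negative & labels == positive)
  tn <- sum(pred_all == negative & labels == negative)
  fp <- sum(pred_all == positive & labels == negative)
  auc <- as.numeric(pROC::auc(pROC::roc(
    labels, dec, levels = c(negative, positive), direction = "<",
    quiet = TRUE)))
  structure(list(
    fold_accuracy = fold_acc,
    accuracy = (tp + tn) / length(labels),
    auc = auc,
    auc_fold_mean = if (auc_per_fold) mean(fold_auc, na.rm = TRUE),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    decision_values = dec, positive = positive, seed = seed
  ), class = "decoder_result")
}

#' @export
print.decoder_result <- function(x, ...) {
  cat(sprintf(
    "<decoder_result> accuracy %.3f (folds %.3f +/- %.3f), AUC %.3f, sens %.3f, spec %.3f\n",
    x$accuracy, mean(x$fold_accuracy), sd(x$fold_accuracy), x$auc,
    x$sensitivity, x$specificity))
  invisible(x)
}

#' Test decoding accuracy against chance level
#'
#' One-sample, one-tailed t-test of the fold accuracies against chance
#' (0.5), with Bonferroni-corrected significance threshold
#' `alpha = 0.05 / n_participants` (0.005 for 10 participants). When the fold
#' accuracies have zero variance, the t-statistic is undefined and the mean
#' is compared to chance exactly (p set to 0 above chance, 1 otherwise),
#' which is reported via `method`.
#'
#' @param fold_accuracies Numeric vector of per-fold accuracies (>= 2).
#' @param n_participants Number of participants in the family of tests.
#' @param chance Chance accuracy (0.5 for two balanced classes).
#' @param alpha_family Family-wise alpha before correction.
#' @return A list: `mean`, `t`, `df`, `p_value`, `alpha`, `significant`,
#'   `method`.
#' @export
above_chance_test <- function(fold_accuracies, n_participants = 10,
                              chance = 0.5, alpha_family = 0.05) {
  if (length(fold_accuracies) < 2)
    stop("need at least two folds", call. = FALSE)
  alpha <- alpha_family / n_participants
  if (sd(fold_accuracies) == 0) {
    p <- if (mean(fold_accuracies) > chance) 0 else 1
    return(list(mean = mean(fold_accuracies), t = NA_real_, df = NA_real_,
                p_value = p, alpha = alpha, significant = p < alpha,
                method = "exact comparison (zero variance)"))
  }
  tt <- t.test(fold_accuracies, mu = chance, alternative = "greater")
  list(mean = mean(fold_accuracies), t = unname(tt$statistic),
       df = unname(tt$parameter), p_value = tt$p.value, alpha = alpha,
       significant = tt$p.value < alpha, method = "one-tailed t-test")
}

#' Correlation between dispersion index and decoding accuracy
#'
#' Pearson correlation (with two-sided p-value) between per-participant
#' dispersion indices and decoding accuracies, plus the paired data for
#' plotting.
#'
#' @param di_values,accuracies Paired numeric vectors, length >= 3.
#' @return A list: `r`, `p_value`, `n`, `data` (a `data.frame`).
#' @export
di_accuracy_correlation <- function(di_values, accuracies) {
  if (length(di_values) != length(accuracies))
    stop("inputs must be paired", call. = FALSE)
  if (length(di_values) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(di_values) == 0 || sd(accuracies) == 0)
    stop("zero variance in input", call. = FALSE)
  ct <- cor.test(di_values, accuracies, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(di_values),
       data = data.frame(di = di_values, accuracy = accuracies))
}
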