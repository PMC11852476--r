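test_that("feature building vectorizes channels by time bins", {
  s <- gen_fnirs_session(tiny_protocol(6), default_montage, sim_config(seed = 3))
  hb <- od_to_hemoglobin(intensity_to_od(s$intensity))
  ep <- extract_epochs(hb, s$schedule, seed = 1)
  f <- build_features(ep, n_time_bins = 3)
  expect_equal(dim(f$x), c(6L, 60L))
  expect_error(build_features(ep, n_time_bins = 1000), "exceeds")
  # constant epochs carry no information after centering
  ep0 <- ep
  ep0$hbo[] <- 4.2
  f0 <- build_features(ep0)
  expect_equal(max(abs(scale(f0$x, scale = FALSE))), 0)
})

test_that("lateralized responses concentrate class contrast on contralateral channels", {
  cfg <- sim_config(seed = 6, resp_osc_amplitude = 0, noise_sd = 2e-7)
  # motor imagery versus idle: imagery activates the contralateral (left)
  # hemisphere fully and the ipsilateral one at the reduced gain
  p <- protocol_spec(n_blocks = 1, trials_per_block = 30,
                     labels = c("mi", "idle"))
  s <- gen_fnirs_session(p, default_montage, cfg)
  hb <- bandpass_hb(od_to_hemoglobin(intensity_to_od(s$intensity)))
  ep <- extract_epochs(hb, s$schedule, seed = 1)
  f <- build_features(ep)
  hemi <- rep(s$montage$channels$hemisphere, each = 3)
  gap <- abs(colMeans(f$x[f$labels == "mi", , drop = FALSE]) -
               colMeans(f$x[f$labels == "idle", , drop = FALSE]))
  expect_gt(mean(gap[hemi == "left"]), 1.5 * mean(gap[hemi == "right"]))
})

test_that("separable features decode perfectly and noise decodes at chance", {
  sep <- make_features(n_per_class = 30, p = 6, delta = 8, seed = 2)
  res <- crossval_decode(sep$x, sep$labels, k = 10, seed = 1)
  expect_equal(res$accuracy, 1)
  expect_equal(res$auc, 1)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)

  aucs <- vapply(1:20, function(s) {
    nz <- make_features(n_per_class = 25, p = 8, delta = 0, seed = 100 + s)
    crossval_decode(nz$x, nz$labels, k = 10, seed = s)$auc
  }, numeric(1))
  expect_true(all(aucs > 0.2 & aucs < 0.8))
  expect_lt(abs(mean(aucs) - 0.5), 0.07)
})

test_that("decoder accuracy is consistent with its own confusion counts", {
  f <- make_features(n_per_class = 40, p = 10, delta = 0.5, seed = 3)
  res <- crossval_decode(f$x, f$labels, k = 10, seed = 2)
  cm <- res$confusion
  n_pos <- cm["tp"] + cm["fn"]; n_neg <- cm["tn"] + cm["fp"]
  expect_equal(res$accuracy,
               unname((res$sensitivity * n_pos + res$specificity * n_neg) /
                        (n_pos + n_neg)))
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
})

test_that("validation trials never leak into fold scaling or training", {
  f <- make_features(n_per_class = 30, p = 5, delta = 1, seed = 4)
  res1 <- crossval_decode(f$x, f$labels, k = 5, seed = 7)
  # corrupt a single trial's features wildly; only that trial's own decision
  # value may change, because scaling and fitting exclude validation trials
  set.seed(7)
  fold <- rsbci:::.stratified_folds(f$labels, 5)
  victim <- which(fold == 1)[1]
  x2 <- f$x
  x2[victim, ] <- x2[victim, ] + 1e6
  res2 <- crossval_decode(x2, f$labels, k = 5, seed = 7)
  same_fold_others <- setdiff(which(fold == 1), victim)
  expect_equal(res2$decision_values[same_fold_others],
               res1$decision_values[same_fold_others], tolerance = 1e-12)
})

test_that("the shrinkage discriminant agrees with a reference LDA when shrinkage vanishes", {
  skip_if_not_installed("MASS")
  f <- make_features(n_per_class = 60, p = 4, delta = 0.8, seed = 5)
  fit <- rsbci:::.lda_fit(f$x, f$labels, gamma = 1e-10)
  d <- rsbci:::.lda_decision(fit, f$x)
  ref <- MASS::lda(f$x, grouping = f$labels)
  pred <- predict(ref, f$x)
  expect_equal(ifelse(d > 0, "right", "left"), as.character(pred$class))
  expect_gt(abs(cor(d, pred$x[, 1])), 0.999999)
})

test_that("above-chance testing applies the corrected threshold", {
  folds <- c(0.9, 0.85, 0.95, 0.9, 0.88, 0.92, 0.87, 0.91, 0.9, 0.89)
  res <- above_chance_test(folds, n_participants = 10)
  expect_equal(res$alpha, 0.005)
  # closed-form oracle for the one-sample t statistic
  m <- mean(folds); s <- sqrt(sum((folds - m)^2) / 9)
  t_hand <- (m - 0.5) / (s / sqrt(10))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_true(res$significant)

  flat <- above_chance_test(rep(0.5, 10))
  expect_false(flat$significant)
  expect_match(flat$method, "zero variance")
  expect_error(above_chance_test(0.9), "two folds")
})

test_that("dispersion-accuracy correlation handles exact and null cases", {
  di <- c(0.2, 0.5, 0.9, 1.1, 1.4)
  perfect <- di_accuracy_correlation(di, -di)
  expect_equal(perfect$r, -1)
  rs <- vapply(1:30, function(s) {
    set.seed(s)
    di_accuracy_correlation(runif(12), runif(12))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.12)
  expect_error(di_accuracy_correlation(1:5, 1:4), "paired")
  expect_error(di_accuracy_correlation(rep(1, 5), runif(5)), "zero variance")
})

test_that("decoding accuracy grows monotonically with the evoked amplitude", {
  amps <- c(0.5, 1, 2, 4, 8) * 1e-7
  mean_acc <- vapply(seq_along(amps), function(i) {
    accs <- vapply(1:6, function(s) {
      cfg <- sim_config(seed = 40 + s, hrf_amplitude = amps[i],
                        noise_sd = 4e-7)
      p <- protocol_spec(n_blocks = 1, trials_per_block = 20)
      rep_ <- run_pipeline(run_config(protocol = p, sim = cfg,
                                      seed = 40 + s,
                                      decoder = list(k = 5, n_time_bins = 3,
                                                     gamma = 0.3)))
      rep_$decoder$accuracy
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_equal(cor(mean_acc, seq_along(amps), method = "spearman"), 1)
})
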