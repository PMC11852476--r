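test_that("the default montage enumerates 10 channels per hemisphere at 3 cm", {
  m <- build_montage()
  expect_equal(nrow(m$channels), 20)
  expect_equal(as.integer(table(m$channels$hemisphere)), c(10L, 10L))
  expect_true(all(abs(m$channels$separation_m - 0.03) < 1e-9))
})

test_that("montage building filters pairs by separation", {
  one <- data.frame(optode = c("S1", "D1"), type = c("source", "detector"),
                    hemisphere = "left", x_m = c(0, 0.03), y_m = 0)
  expect_equal(nrow(build_montage(one)$channels), 1)
  far <- one
  far$x_m <- c(0, 0.06)
  expect_warning(m <- build_montage(far), "excluded")
  expect_equal(nrow(m$channels), 0)
})

test_that("the band-pass filter rejects DC, passes the hemodynamic band and kills cardiac frequencies", {
  rate <- 8.72
  n <- round(240 * rate)
  t <- (seq_len(n) - 1) / rate
  trim <- t > 20 & t < 220
  # DC rejection
  dc <- bandpass(rep(2.5, n), rate)
  expect_lt(max(abs(dc[trim])), 1e-9)
  # passband: 0.25 Hz preserved within 5%
  s_pass <- sin(2 * pi * 0.25 * t)
  out <- bandpass(s_pass, rate)
  gain <- sqrt(mean(out[trim]^2) / mean(s_pass[trim]^2))
  expect_lt(abs(gain - 1), 0.05)
  # stopband: 1.5 Hz attenuated by at least 90%
  s_stop <- sin(2 * pi * 1.5 * t)
  out2 <- bandpass(s_stop, rate)
  gain2 <- sqrt(mean(out2[trim]^2) / mean(s_stop[trim]^2))
  expect_lt(gain2, 0.1)
  expect_error(bandpass(s_pass, rate, high_hz = 5), "Nyquist")
})

test_that("optical-density conversion obeys its log identities", {
  mk_raw <- function(vals) {
    structure(list(data = array(vals, c(length(vals), 1, 2)),
                   time = seq_along(vals), rate = 1, channels = "ch1",
                   wavelengths = c(760, 850)),
              class = "raw_intensity")
  }
  expect_equal(max(abs(intensity_to_od(mk_raw(rep(3, 50)))$data)), 0)
  # one sample at a tenth of the temporal mean has dOD exactly 1
  b <- 1
  a <- 10 * b / 109          # makes a = mean(c(a, rep(b, 10))) / 10
  od <- intensity_to_od(mk_raw(c(a, rep(b, 10))))
  expect_equal(od$data[1, 1, 1], 1, tolerance = 1e-12)
  bad <- mk_raw(c(1, -1, 1))
  expect_error(intensity_to_od(bad), "non-positive intensity")
})

test_that("Beer-Lambert inversion is the exact inverse of the forward model", {
  set.seed(4)
  n <- 200; n_ch <- 3
  hbo <- matrix(rnorm(n * n_ch, sd = 1e-6), n, n_ch)
  hbr <- matrix(rnorm(n * n_ch, sd = 1e-6), n, n_ch)
  ext <- extinction_table()
  od <- structure(list(data = rsbci:::.forward_mbll(hbo, hbr, ext),
                       time = (1:n), rate = 1, channels = paste0("c", 1:n_ch),
                       wavelengths = ext$wavelengths),
                  class = "od_series")
  hb <- od_to_hemoglobin(od, ext)
  expect_lt(max(abs(hb$hbo - hbo)), 1e-10)
  expect_lt(max(abs(hb$hbr - hbr)), 1e-10)
  # zero optical density maps to zero concentrations
  od0 <- od; od0$data[] <- 0
  hb0 <- od_to_hemoglobin(od0, ext)
  expect_equal(max(abs(hb0$hbo)), 0)
  # doubling the pathlength factor halves recovered concentrations
  ext2 <- extinction_table(dpf = 2 * ext$dpf)
  hb2 <- od_to_hemoglobin(od, ext2)
  expect_equal(hb2$hbo, hbo / 2, tolerance = 1e-10)
  expect_error(extinction_table(eps = matrix(1, 2, 2)), "invertible")
})

test_that("epoch extraction keeps in-bounds trials and drops the rest with a warning", {
  s <- gen_fnirs_session(tiny_protocol(6), default_montage, sim_config(seed = 2))
  hb <- od_to_hemoglobin(intensity_to_od(s$intensity))
  ep <- extract_epochs(hb, s$schedule, seed = 1)
  expect_equal(dim(ep$hbo)[1], 6)
  expect_equal(dim(ep$hbo)[2], 20)
  # a cue 1 s into the recording cannot host a 2 s pre-cue window
  sch_bad <- s$schedule
  sch_bad$cue_onset_s[1] <- 1
  expect_warning(ep2 <- extract_epochs(hb, sch_bad, seed = 1), "dropped")
  expect_equal(dim(ep2$hbo)[1], 5)
  expect_equal(ep2$n_dropped, 1)
})

test_that("the average over synchronized epochs reproduces the generator's evoked response", {
  amp <- 5e-7
  cfg <- sim_config(hrf_amplitude = amp, resp_osc_amplitude = 0,
                    pulse_amplitude = 0, drift_slope = 0, noise_sd = 1e-7)
  p <- protocol_spec(n_blocks = 1, trials_per_block = 40,
                     labels = c("left", "right"))
  s <- gen_fnirs_session(p, default_montage, cfg)
  hb <- od_to_hemoglobin(intensity_to_od(s$intensity))
  ep <- extract_epochs(hb, s$schedule, b1_mode = "none")
  lab <- "left"
  sel <- ep$labels == lab
  contra <- which(s$montage$channels$hemisphere == "right")[1]
  obs <- colMeans(ep$hbo[sel, contra, ])
  # truth: amplitude times the mean baseline-corrected evoked regressor cut
  # at the same trial onsets
  rate <- hb$rate
  onsets <- round(s$schedule$cue_onset_s[!s$schedule$skipped] * rate) + 1
  onsets <- onsets[sel]
  rel <- seq(-round(2 * rate), round(9 * rate))
  tru <- rowMeans(vapply(onsets, function(o)
    s$truth$evoked[o + rel, lab], numeric(length(rel))))
  tru <- amp * (tru - mean(tru[rel / rate < 0]))
  se <- cfg$noise_sd / sqrt(sum(sel))
  expect_lt(max(abs(obs - tru)), 5 * se)
})

test_that("the dispersion index reproduces hand-worked and degenerate cases", {
  # hand evaluation: B1 = {1, 3}, B2 = {2, 2.5} -> 0.125 / 2 = 0.0625
  di <- dispersion_index(matrix(c(2, 2.5), ncol = 1),
                         matrix(c(1, 3), ncol = 1))
  expect_equal(di$di_mean, 0.0625)
  expect_equal(di$nt, 2)
  # identical segments give exactly 1
  v <- matrix(c(0.3, 1.2, -0.4, 0.9), ncol = 1)
  expect_equal(dispersion_index(v, v)$di_mean, 1)
  # constant B2 gives 0
  expect_equal(dispersion_index(matrix(rep(2, 4), ncol = 1), v)$di_mean, 0)
  # zero B1 variance is undefined
  expect_error(dispersion_index(v, matrix(rep(1, 4), ncol = 1)),
               "zero B1 variance")
})

test_that("the dispersion index is invariant under joint affine rescaling", {
  set.seed(8)
  b1 <- matrix(rnorm(60), 20, 3)
  b2 <- matrix(rnorm(60, sd = 0.5), 20, 3)
  d0 <- dispersion_index(b2, b1)
  for (a in c(-2, 0.1, 7)) {
    d1 <- dispersion_index(a * b2 + 3, a * b1 + 3)
    expect_equal(d1$di, d0$di, tolerance = 1e-12)
  }
})
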