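#' Extinction coefficients and pathlength settings
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at 760 and
#' 850 nm from the standard compiled tabulation used by common fNIRS
#' toolchains (units: cm^-1 per mol/L), together with the differential
#' pathlength factor and source-detector distance used by the modified
#' Beer-Lambert law. All values are editable; the 2x2 matrix must stay
#' invertible.
#'
#' @param wavelengths Wavelengths in nm (names of the rows of `eps`).
#' @param eps 2x2 matrix of extinction coefficients, rows = wavelengths,
#'   columns `hbo`, `hbr` (cm^-1 M^-1).
#' @param dpf Differential pathlength factor (dimensionless).
#' @param distance_cm Source-detector separation in cm.
#' @return A list of class `extinction_table`.
#' @export
extinction_table <- function(wavelengths = c(760, 850),
                             eps = matrix(c(1486.5865, 3843.707,
                                            2526.391, 1798.643),
                                          nrow = 2, byrow = TRUE,
                                          dimnames = list(c("760", "850"),
                                                          c("hbo", "hbr"))),
                             dpf = 6, distance_cm = 3) {
  if (!all(dim(eps) == c(2, 2)) || abs(det(eps)) < .Machine$double.eps)
    stop("extinction matrix must be an invertible 2x2 matrix", call. = FALSE)
  structure(list(wavelengths = wavelengths, eps = eps, dpf = dpf,
                 distance_cm = distance_cm),
            class = "extinction_table")
}

#' Default optode layout
#'
#' Per hemisphere, 4 sources and 4 detectors on a 2 x 4 grid with 3 cm
#' spacing in a checkerboard arrangement over the motor cortex, which yields
#' exactly 10 source-detector pairs at the standard 3 cm separation per
#' hemisphere (20 channels in total).
#'
#' @return A `data.frame` with columns `optode`, `type` (`source` or
#'   `detector`), `hemisphere`, `x_m`, `y_m`.
#' @export
montage_layout_default <- function() {
  d <- 0.03
  one_hemi <- function(hemi, x0) {
    grid <- expand.grid(i = 0:3, j = 0:1)
    type <- ifelse((grid$i + grid$j) %% 2 == 0, "source", "detector")
    pre <- ifelse(type == "source", "S", "D")
    data.frame(
      optode = paste0(pre, seq_len(nrow(grid)), "_", substr(hemi, 1, 1)),
      type = type, hemisphere = hemi,
      x_m = x0 + grid$i * d, y_m = grid$j * d,
      stringsAsFactors = FALSE
    )
  }
  rbind(one_hemi("left", -0.20), one_hemi("right", 0.20))
}

#' Build a montage from an optode layout
#'
#' Enumerates all source-detector pairs whose separation is within
#' `tolerance_m` of `separation_m`. Pairs outside the tolerance are
#' excluded; when the exclusions leave any optode without a channel (a
#' likely layout mistake), a warning reports how many pairs were dropped.
#'
#' @param layout Optode table as returned by [montage_layout_default()].
#' @param separation_m Nominal source-detector separation (m).
#' @param tolerance_m Accepted deviation from the nominal separation (m).
#' @return A list of class `montage` with element `channels`, a `data.frame`
#'   with columns `channel`, `source`, `detector`, `hemisphere`,
#'   `separation_m`.
#' @export
build_montage <- function(layout = montage_layout_default(),
                          separation_m = 0.03, tolerance_m = 0.005) {
  need <- c("optode", "type", "hemisphere", "x_m", "y_m")
  if (!all(need %in% names(layout)))
    stop("layout must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  src <- layout[layout$type == "source", , drop = FALSE]
  det <- layout[layout$type == "detector", , drop = FALSE]
  pairs <- expand.grid(s = seq_len(nrow(src)), d = seq_len(nrow(det)))
  sep <- sqrt((src$x_m[pairs$s] - det$x_m[pairs$d])^2 +
                (src$y_m[pairs$s] - det$y_m[pairs$d])^2)
  keep <- abs(sep - separation_m) <= tolerance_m
  n_drop <- sum(!keep)
  used <- c(src$optode[pairs$s[keep]], det$optode[pairs$d[keep]])
  orphans <- setdiff(c(src$optode, det$optode), used)
  if (n_drop > 0 && length(orphans) > 0)
    warning(sprintf(
      "%d source-detector pair(s) outside %.3g +/- %.3g m excluded; %d optode(s) left without a channel",
      n_drop, separation_m, tolerance_m, length(orphans)), call. = FALSE)
  pairs <- pairs[keep, , drop = FALSE]
  sep <- sep[keep]
  channels <- data.frame(
    channel = character(nrow(pairs)),
    source = src$optode[pairs$s],
    detector = det$optode[pairs$d],
    hemisphere = src$hemisphere[pairs$s],
    separation_m = sep,
    stringsAsFactors = FALSE
  )
  channels$channel <- paste(channels$source, channels$detector, sep = "-")
  if (nrow(channels) == 0) channels$channel <- character(0)
  channels <- channels[order(channels$hemisphere, channels$channel), ,
                       drop = FALSE]
  rownames(channels) <- NULL
  structure(list(channels = channels, separation_m = separation_m),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  tab <- table(x$channels$hemisphere)
  cat(sprintf("<montage> %d channels (%s)\n", nrow(x$channels),
              paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order Butterworth band-pass applied forward and backward
#' (zero-phase) per channel, removing slow drift below `low_hz` and cardiac
#' pulsation above `high_hz` while passing the hemodynamic band. A causal
#' (forward-only) variant is available for online simulation.
#'
#' @param x Numeric vector, matrix (time x channels), or 3-d array
#'   (time x channels x wavelengths).
#' @param rate Sampling rate in Hz; must exceed `2 * high_hz`.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Filter order.
#' @param zero_phase If `FALSE`, apply the filter causally (single forward
#'   pass) instead of forward-backward.
#' @return Filtered data of the same shape as `x`.
#' @export
bandpass <- function(x, rate, low_hz = 0.05, high_hz = 0.60, order = 3,
                     zero_phase = TRUE) {
  if (high_hz >= rate / 2)
    stop("`high_hz` must be below the Nyquist frequency", call. = FALSE)
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / (rate / 2), type = "pass")
  f1 <- function(v) {
    # demean (the pass band excludes DC anyway) and reflect-pad so the
    # forward-backward pass settles before the data start
    mu <- mean(v)
    v <- v - mu
    if (!zero_phase) return(as.numeric(signal::filter(bf, v)))
    n <- length(v)
    p <- min(n - 1, ceiling(3 * rate / low_hz))
    vp <- c(2 * v[1] - rev(v[2:(p + 1)]), v, 2 * v[n] - rev(v[(n - p):(n - 1)]))
    out <- signal::filtfilt(bf, vp)
    out[(p + 1):(p + n)]
  }
  if (is.null(dim(x))) return(f1(x))
  out <- x
  if (length(dim(x)) == 2) {
    for (j in seq_len(ncol(x))) out[, j] <- f1(x[, j])
  } else if (length(dim(x)) == 3) {
    for (j in seq_len(dim(x)[2])) for (w in seq_len(dim(x)[3]))
      out[, j, w] <- f1(x[, j, w])
  } else stop("`x` must have at most 3 dimensions", call. = FALSE)
  out
}

# Apply bandpass to a hemoglobin series object.
#' @rdname bandpass
#' @param hb A `hb_series` object.
#' @param ... Passed on to [bandpass()].
#' @export
bandpass_hb <- function(hb, ...) {
  hb$hbo <- bandpass(hb$hbo, hb$rate, ...)
  hb$hbr <- bandpass(hb$hbr, hb$rate, ...)
  hb
}

#' Convert raw intensity to optical-density changes
#'
#' `dOD(lambda, t) = -log10(I(lambda, t) / mean_t I(lambda))`, per channel
#' and wavelength, with the temporal mean of the same channel-wavelength
#' series as the reference intensity.
#'
#' @param raw A `raw_intensity` object (see [gen_fnirs_session()] or
#'   [read_session()]).
#' @return A list of class `od_series`: `data` (time x channels x
#'   wavelengths), `time`, `rate`, `channels`, `wavelengths`.
#' @export
intensity_to_od <- function(raw) {
  if (!inherits(raw, "raw_intensity"))
    stop("`raw` must be a raw_intensity object", call. = FALSE)
  x <- raw$data
  if (any(!is.finite(x)) || any(x <= 0)) {
    bad <- which(x <= 0 | !is.finite(x), arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at sample %d, channel %s, %s nm",
                 bad[1], raw$channels[bad[2]], raw$wavelengths[bad[3]]),
         call. = FALSE)
  }
  od <- x
  for (w in seq_len(dim(x)[3])) {
    xw <- matrix(x[, , w], nrow = dim(x)[1])
    od[, , w] <- -log10(sweep(xw, 2, colMeans(xw), "/"))
  }
  structure(list(data = od, time = raw$time, rate = raw$rate,
                 channels = raw$channels, wavelengths = raw$wavelengths),
            class = "od_series")
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Solves the modified Beer-Lambert system per channel and sample:
#' `dOD(lambda) / (d * DPF) = eps(lambda, HbO) * dHbO + eps(lambda, HbR) * dHbR`
#' which, with two wavelengths, is an exactly determined 2x2 linear system.
#'
#' @param od An `od_series` (both wavelengths present).
#' @param extinction An [extinction_table()].
#' @return A list of class `hb_series`: `hbo`, `hbr` (time x channels,
#'   mol/L), `time`, `rate`, `channels`.
#' @export
od_to_hemoglobin <- function(od, extinction = extinction_table()) {
  if (!inherits(od, "od_series"))
    stop("`od` must be an od_series", call. = FALSE)
  if (dim(od$data)[3] != 2)
    stop("both wavelengths must be present", call. = FALSE)
  leff <- extinction$distance_cm * extinction$dpf
  einv <- solve(extinction$eps)
  n <- dim(od$data)[1]; n_ch <- dim(od$data)[2]
  od1 <- od$data[, , 1, drop = TRUE] / leff
  od2 <- od$data[, , 2, drop = TRUE] / leff
  if (n_ch == 1) { od1 <- matrix(od1, ncol = 1); od2 <- matrix(od2, ncol = 1) }
  hbo <- einv["hbo", 1] * od1 + einv["hbo", 2] * od2
  hbr <- einv["hbr", 1] * od1 + einv["hbr", 2] * od2
  structure(list(hbo = hbo, hbr = hbr, time = od$time, rate = od$rate,
                 channels = od$channels),
            class = "hb_series")
}

#' Cut trial epochs around cue onsets
#'
#' Extracts per-trial HbO/HbR windows relative to each cue onset and stores
#' the mean HbO of the 2 s pre-cue baseline segment per trial and channel.
#' For a synchronized schedule the pre-cue segments are the
#' respiration-locked baselines (B2); an unsynchronized baseline set (B1) is
#' emulated by re-epoching the same recording at cue onsets jittered
#' uniformly over one breath period, which randomizes the respiratory phase
#' while keeping the segments in the pre-cue quiet zone. For an
#' unsynchronized schedule the pre-cue segments are stored as B1.
#'
#' @param hb A `hb_series`.
#' @param schedule A `trial_schedule`.
#' @param window Epoch window relative to cue onset (s), default `c(-2, 9)`.
#' @param baseline Baseline segment (s), default `c(-2, 0)`.
#' @param baseline_correct Subtract the per-trial baseline mean from the
#'   epoch traces (the stored segment means are always uncorrected).
#' @param b1_mode For synchronized schedules: `"phase_jitter"` (default;
#'   onsets jittered by `-U(0, b1_jitter_span_s)`), `"uniform"` (onsets drawn
#'   uniformly over the whole recording), or `"none"`.
#' @param b1_jitter_span_s Span of the phase jitter (s); defaults to one
#'   nominal breath period.
#' @param seed Seed for the B1 re-epoching draw (`NULL`: current stream).
#' @return A list of class `hb_epochs`: `hbo`, `hbr` (trials x channels x
#'   time), `rel_time`, `labels`, `b2`, `b1` (trials x channels segment-mean
#'   matrices; one of them may be `NULL`), `n_dropped`, `sync_mode`.
#' @export
extract_epochs <- function(hb, schedule, window = c(-2, 9),
                           baseline = c(-2, 0), baseline_correct = TRUE,
                           b1_mode = c("phase_jitter", "uniform", "none"),
                           b1_jitter_span_s = 4, seed = NULL) {
  b1_mode <- match.arg(b1_mode)
  if (!inherits(hb, "hb_series")) stop("`hb` must be an hb_series", call. = FALSE)
  sync <- identical(attr(schedule, "sync_mode"), "synchronized")
  rate <- hb$rate
  n <- nrow(hb$hbo)
  pre_n <- round(-window[1] * rate)
  post_n <- round(window[2] * rate)
  rel_idx <- seq(-pre_n, post_n)
  rel_time <- rel_idx / rate

  ok <- !schedule$skipped & !is.na(schedule$cue_onset_s)
  onset_idx <- round(schedule$cue_onset_s * rate) + 1
  in_bounds <- ok & (onset_idx - pre_n >= 1) & (onset_idx + post_n <= n)
  n_dropped <- sum(ok & !in_bounds)
  if (n_dropped > 0)
    warning(sprintf("%d trial(s) outside the recording dropped", n_dropped),
            call. = FALSE)
  keep <- which(in_bounds)
  nt <- length(keep)
  if (nt == 0) stop("no trial fits inside the recording", call. = FALSE)
  n_ch <- ncol(hb$hbo)

  cut_segments <- function(onsets_idx) {
    arr <- array(NA_real_, c(length(onsets_idx), n_ch, length(rel_idx)))
    for (i in seq_along(onsets_idx)) {
      rows <- onsets_idx[i] + rel_idx
      arr[i, , ] <- t(hb$hbo[rows, , drop = FALSE])
    }
    arr
  }

  hbo_e <- cut_segments(onset_idx[keep])
  hbr_e <- array(NA_real_, dim(hbo_e))
  for (i in seq_along(keep)) {
    rows <- onset_idx[keep[i]] + rel_idx
    hbr_e[i, , ] <- t(hb$hbr[rows, , drop = FALSE])
  }

  bl_sel <- rel_time >= baseline[1] & rel_time < baseline[2]
  seg_mean <- function(arr) {
    apply(arr[, , bl_sel, drop = FALSE], c(1, 2), mean)
  }
  pre_means <- seg_mean(hbo_e)

  if (baseline_correct) {
    hbo_e <- sweep(hbo_e, c(1, 2), pre_means, "-")
    bm_r <- apply(hbr_e[, , bl_sel, drop = FALSE], c(1, 2), mean)
    hbr_e <- sweep(hbr_e, c(1, 2), bm_r, "-")
  }

  b1 <- b2 <- NULL
  if (sync) {
    b2 <- pre_means
    if (b1_mode != "none") {
      if (!is.null(seed)) set.seed(seed)
      base_on <- schedule$cue_onset_s[keep]
      if (b1_mode == "phase_jitter") {
        jit <- runif(nt, -b1_jitter_span_s, 0)
        b1_onsets <- base_on + jit
      } else {
        lo <- (pre_n + 1) / rate
        hi <- (n - post_n - 1) / rate
        b1_onsets <- runif(nt, lo, hi)
      }
      b1_idx <- round(b1_onsets * rate) + 1
      b1_idx <- pmin(pmax(b1_idx, pre_n + 1), n - post_n)
      b1 <- seg_mean(cut_segments(b1_idx))
    }
  } else {
    b1 <- pre_means
  }

  structure(list(hbo = hbo_e, hbr = hbr_e, rel_time = rel_time,
                 labels = schedule$label[keep], b2 = b2, b1 = b1,
                 channels = hb$channels, rate = rate,
                 n_dropped = n_dropped,
                 sync_mode = if (sync) "synchronized" else "unsynchronized"),
            class = "hb_epochs")
}

#' Dispersion index of pre-cue HbO baselines
#'
#' The ratio of across-trial sums of squares of the pre-cue HbO segment
#' means, synchronized (B2) over unsynchronized (B1):
#' `DI = sum_i (x_i^B2 - xbar^B2)^2 / sum_i (x_i^B1 - xbar^B1)^2`, computed
#' per channel and averaged over channels. `DI < 1` means respiration
#' synchronization reduced the dispersion of pre-cue baselines. The index is
#' invariant under joint affine rescaling of B1 and B2.
#'
#' @param epochs A `hb_epochs` containing B2 (and B1, unless `b1_epochs`
#'   supplies it), or a trials x channels matrix of B2 segment values.
#' @param b1_epochs Optional second `hb_epochs` (e.g. from an unsynchronized
#'   recording) or matrix providing the B1 segment values.
#' @return A list of class `dispersion_result`: `di` (per channel),
#'   `di_mean`, `nt`, `mean_b1`, `mean_b2`.
#' @export
dispersion_index <- function(epochs, b1_epochs = NULL) {
  get_mat <- function(x, field) {
    if (is.matrix(x)) return(x)
    if (inherits(x, "hb_epochs")) return(x[[field]])
    stop("expected an hb_epochs or a matrix", call. = FALSE)
  }
  b2 <- get_mat(epochs, "b2")
  b1 <- if (is.null(b1_epochs)) get_mat(epochs, "b1") else
    get_mat(b1_epochs, "b1")
  if (is.null(b2) || is.null(b1))
    stop("both B1 and B2 segments are required", call. = FALSE)
  if (is.null(dim(b2))) b2 <- matrix(b2, ncol = 1)
  if (is.null(dim(b1))) b1 <- matrix(b1, ncol = 1)
  if (nrow(b1) != nrow(b2))
    stop("B1 and B2 must have equal trial counts", call. = FALSE)
  ss <- function(v) sum((v - mean(v))^2)
  den <- apply(b1, 2, ss)
  if (any(den == 0))
    stop("zero B1 variance: dispersion index undefined", call. = FALSE)
  num <- apply(b2, 2, ss)
  di <- num / den
  structure(list(di = di, di_mean = mean(di), nt = nrow(b2),
                 mean_b1 = colMeans(b1), mean_b2 = colMeans(b2)),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("<dispersion_result> DI_mean = %.4g over %d channels, nt = %d\n",
              x$di_mean, length(x$di), x$nt))
  invisible(x)
}
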