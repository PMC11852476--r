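#' Simulation configuration
#'
#' Bundles every knob of the synthetic generators: respiration timing, the
#' hemodynamic response amplitude, the physiological confounds that share the
#' hemodynamic band, and measurement noise. Concentrations are expressed in
#' mol/L of hemoglobin change, matching the units the modified Beer-Lambert
#' inversion recovers.
#'
#' Defaults emulate a resting adult: a 4 s breath period (0.25 Hz, inside the
#' typical 0.2-0.3 Hz band) with 0.3 s per-cycle jitter, a task-evoked HbO
#' peak of 5e-7 mol/L, a respiration-coupled HbO oscillation at half the
#' evoked amplitude, cardiac pulsation at 1.2 Hz (72 bpm), a slow linear
#' drift, and white sensor noise.
#'
#' @param breath_period_s Mean breath period in seconds.
#' @param period_jitter_sd Standard deviation of the per-cycle breath period
#'   (seconds); periods are truncated below at `0.5 * breath_period_s`.
#' @param hrf_amplitude Peak task-evoked change in HbO (mol/L).
#' @param resp_osc_amplitude Amplitude of the respiration-phase-locked HbO
#'   oscillation (mol/L).
#' @param pulse_amplitude Amplitude of cardiac pulsation in HbO (mol/L).
#' @param pulse_rate_hz Cardiac frequency (Hz).
#' @param drift_slope Linear drift of HbO (mol/L per second).
#' @param noise_sd White measurement noise on HbO (mol/L per sample).
#' @param seed Integer seed; fixing it makes every generated sample
#'   bit-reproducible.
#' @param fnirs_rate_hz Optical sampling rate (Hz).
#' @param resp_rate_hz Respiration-sensor sampling rate (Hz).
#' @param resp_amplitude Strain-signal amplitude (arbitrary units).
#' @param resp_noise_sd Sensor noise on the strain signal (same units).
#' @param ipsi_gain Fraction of the evoked response expressed on the
#'   hemisphere ipsilateral to the imagined limb.
#' @param hbr_ratio Ratio of the evoked HbR response to the evoked HbO
#'   response (canonically negative).
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(breath_period_s = 4,
                       period_jitter_sd = 0.3,
                       hrf_amplitude = 5e-7,
                       resp_osc_amplitude = 2.5e-7,
                       pulse_amplitude = 1e-7,
                       pulse_rate_hz = 1.2,
                       drift_slope = 5e-9,
                       noise_sd = 1e-7,
                       seed = 1L,
                       fnirs_rate_hz = 8.72,
                       resp_rate_hz = 25,
                       resp_amplitude = 1,
                       resp_noise_sd = 0.02,
                       ipsi_gain = 0.3,
                       hbr_ratio = -1 / 3) {
  stopifnot(breath_period_s > 0, period_jitter_sd >= 0,
            hrf_amplitude >= 0, resp_osc_amplitude >= 0,
            pulse_amplitude >= 0, pulse_rate_hz > 0,
            noise_sd >= 0, fnirs_rate_hz > 0, resp_rate_hz > 0)
  structure(list(
    breath_period_s = breath_period_s,
    period_jitter_sd = period_jitter_sd,
    hrf_amplitude = hrf_amplitude,
    resp_osc_amplitude = resp_osc_amplitude,
    pulse_amplitude = pulse_amplitude,
    pulse_rate_hz = pulse_rate_hz,
    drift_slope = drift_slope,
    noise_sd = noise_sd,
    seed = as.integer(seed),
    fnirs_rate_hz = fnirs_rate_hz,
    resp_rate_hz = resp_rate_hz,
    resp_amplitude = resp_amplitude,
    resp_noise_sd = resp_noise_sd,
    ipsi_gain = ipsi_gain,
    hbr_ratio = hbr_ratio
  ), class = "sim_config")
}

#' Respiration trace constructor
#'
#' A uniformly sampled abdominal-strain signal.
#'
#' @param samples Numeric vector of strain amplitudes (arbitrary units).
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Session-clock time of the first sample (seconds).
#' @return An object of class `resp_trace` with fields `samples`, `rate`, `t0`.
#' @export
resp_trace <- function(samples, rate, t0 = 0) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("`rate` must be a single positive number", call. = FALSE)
  if (length(samples) < 2)
    stop("a respiration trace needs at least 2 samples", call. = FALSE)
  structure(list(samples = as.numeric(samples), rate = rate, t0 = t0),
            class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %d samples @ %.4g Hz (%.1f s)\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

# Time stamps of a resp_trace
resp_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$rate
}

# Breath-onset sequence from the current RNG stream. Returns trough
# (inhalation-onset) times starting at 0 and covering at least duration_s.
.gen_breath_onsets <- function(duration_s, config) {
  n_draw <- ceiling(duration_s / config$breath_period_s * 1.5) + 8
  periods <- rnorm(n_draw, config$breath_period_s, config$period_jitter_sd)
  periods <- pmax(periods, 0.5 * config$breath_period_s)
  onsets <- c(0, cumsum(periods))
  while (max(onsets) < duration_s) {
    p <- max(rnorm(1, config$breath_period_s, config$period_jitter_sd),
             0.5 * config$breath_period_s)
    onsets <- c(onsets, max(onsets) + p)
  }
  onsets
}

# Instantaneous respiratory phase (radians) at times t given trough onsets.
# Phase is 0 at each inhalation onset (trough) and advances linearly to 2*pi
# at the next trough; extrapolates with the edge periods outside the range.
resp_phase <- function(t, onsets) {
  if (length(onsets) < 2) stop("need at least two breath onsets", call. = FALSE)
  periods <- diff(onsets)
  k <- findInterval(t, onsets)
  k_on <- pmin(pmax(k, 1L), length(onsets))
  k_per <- pmin(pmax(k, 1L), length(periods))
  2 * pi * (t - onsets[k_on]) / periods[k_per]
}

#' Generate a synthetic respiration trace with ground-truth breath events
#'
#' Produces a quasi-sinusoidal abdominal-strain signal whose per-cycle period
#' is drawn from `Normal(breath_period_s, period_jitter_sd)` truncated below
#' at half the mean period. The trough of each cycle (start of abdominal
#' expansion) is the ground-truth inhalation onset; the mid-cycle peak start
#' of contraction is the exhalation onset.
#'
#' @param duration_s Positive duration in seconds.
#' @param config A [sim_config()].
#' @return A list with `trace` (a [resp_trace()]) and `breaths` (class
#'   `breath_truth`: `inhalation_onsets`, `exhalation_onsets`, seconds).
#' @export
gen_respiration <- function(duration_s, config = sim_config()) {
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0)
    stop("`duration_s` must be a single positive number", call. = FALSE)
  set.seed(config$seed)
  .gen_respiration_core(duration_s, config)
}

# Core generator drawing from the current RNG stream (stream order:
# breath periods first, then sensor noise).
.gen_respiration_core <- function(duration_s, config) {
  onsets_all <- .gen_breath_onsets(duration_s + 2 * config$breath_period_s,
                                   config)
  n <- floor(duration_s * config$resp_rate_hz)
  t <- (seq_len(n) - 1) / config$resp_rate_hz
  phase <- resp_phase(t, onsets_all)
  x <- config$resp_amplitude * (-cos(phase))
  if (config$resp_noise_sd > 0) x <- x + rnorm(n, 0, config$resp_noise_sd)
  inh <- onsets_all[onsets_all < duration_s]
  periods <- diff(onsets_all)
  exh <- inh + periods[seq_along(inh)] / 2
  exh <- exh[exh < duration_s]
  breaths <- structure(list(inhalation_onsets = inh, exhalation_onsets = exh,
                            all_onsets = onsets_all),
                       class = "breath_truth")
  list(trace = resp_trace(x, config$resp_rate_hz), breaths = breaths)
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the response peaking at 6 s and the
#' undershoot at 16 s, scaled to unit peak.
#'
#' @param t Time in seconds (>= 0 contributes; negative times return 0).
#' @param peak_s Time-to-peak of the positive lobe (seconds).
#' @param undershoot_s Time-to-peak of the undershoot (seconds).
#' @param undershoot_ratio Amplitude ratio undershoot / peak.
#' @return Numeric vector of the same length as `t`.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6) {
  a1 <- peak_s + 1
  a2 <- undershoot_s + 1
  h <- ifelse(t < 0, 0,
              stats::dgamma(t, shape = a1, rate = 1) -
                undershoot_ratio * stats::dgamma(t, shape = a2, rate = 1))
  h / max(stats::dgamma(peak_s, shape = a1, rate = 1))
}

# Convolve a stimulus vector with a kernel, keeping the first n samples.
.conv_causal <- function(stim, kernel) {
  out <- convolve(stim, rev(kernel), type = "open")
  out[seq_along(stim)]
}

#' Generate a full synthetic fNIRS session
#'
#' Simulates ground-truth per-channel HbO/HbR time series (a canonical
#' double-gamma hemodynamic response convolved with the cue boxcars on
#' task-lateralized channels, a respiration-phase-locked oscillation, cardiac
#' pulsation, slow drift and white noise) and maps them through the forward
#' modified Beer-Lambert model to strictly positive dual-wavelength
#' intensities sampled at the optical rate.
#'
#' The evoked regressor of each class is normalized to unit peak before
#' scaling, so `hrf_amplitude` is the peak evoked change in HbO in mol/L.
#' Channels contralateral to the imagined limb carry the full amplitude,
#' ipsilateral channels `ipsi_gain` of it, and idle trials none.
#'
#' Stream order under the single seed: breath periods, respiration sensor
#' noise, cue-label shuffling, per-channel respiration coupling gains,
#' per-channel drift gains, HbO noise, HbR noise.
#'
#' @param protocol A [protocol_spec()].
#' @param montage A [build_montage()] montage.
#' @param config A [sim_config()].
#' @param sync_mode `"synchronized"` (cues locked to inhalation onsets) or
#'   `"unsynchronized"` (cues at fixed times); defaults to the protocol's.
#' @param unsync_wait_range Optional per-trial wait range for unsynchronized
#'   scheduling; see [schedule_session()].
#' @return A list of class `fnirs_session` with elements `intensity` (class
#'   `raw_intensity`), `schedule` (the trial log), `resp` (a [resp_trace()]),
#'   `breaths` (ground truth), `truth` (noiseless bookkeeping: `hbo`, `hbr`,
#'   `od`, `evoked` regressors), `config`, `montage`, and `protocol`.
#' @export
gen_fnirs_session <- function(protocol, montage = build_montage(),
                              config = sim_config(),
                              sync_mode = protocol$sync_mode,
                              unsync_wait_range = NULL) {
  sync_mode <- match.arg(sync_mode, c("synchronized", "unsynchronized"))
  if (!inherits(protocol, "protocol_spec"))
    stop("`protocol` must be a protocol_spec", call. = FALSE)
  if (nrow(montage$channels) == 0)
    stop("montage has no channels", call. = FALSE)
  set.seed(config$seed)

  n_trials <- protocol$n_blocks * protocol$trials_per_block
  est_dur <- n_trials * (protocol$prep_s + protocol$cue_s + protocol$iti_s +
                           2 * config$breath_period_s) + 60
  resp <- .gen_respiration_core(est_dur, config)
  events <- structure(list(
    inhalation_onsets = resp$breaths$inhalation_onsets,
    detection_latency_s = rep(0, length(resp$breaths$inhalation_onsets))
  ), class = "breath_events")
  schedule <- schedule_session(protocol,
                               breath_events = if (sync_mode == "synchronized") events,
                               sync_mode = sync_mode, seed = NULL,
                               unsync_wait_range = unsync_wait_range)
  kept <- schedule[!schedule$skipped, , drop = FALSE]
  dur <- max(kept$cue_onset_s) + protocol$cue_s + protocol$iti_s + 12

  rate <- config$fnirs_rate_hz
  n <- floor(dur * rate)
  t <- (seq_len(n) - 1) / rate
  ch <- montage$channels
  n_ch <- nrow(ch)

  # Evoked regressors, one per non-idle class, unit peak.
  kernel <- hrf_double_gamma(seq(0, 32, by = 1 / rate))
  classes <- setdiff(unique(kept$label), "idle")
  evoked <- matrix(0, n, length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    stim <- numeric(n)
    for (on in kept$cue_onset_s[kept$label == cl]) {
      i0 <- floor(on * rate) + 1
      i1 <- min(floor((on + protocol$cue_s) * rate) + 1, n)
      stim[i0:i1] <- 1
    }
    r <- .conv_causal(stim, kernel)
    if (max(r) > 0) r <- r / max(r)
    evoked[, cl] <- r
  }

  # Lateralized evoked gain per channel and class: full response on the
  # hemisphere contralateral to the imagined limb ("mi" behaves like right-
  # limb imagery, activating the left hemisphere).
  contra <- c(left = "right", right = "left", mi = "left")
  gain <- matrix(0, n_ch, length(classes), dimnames = list(NULL, classes))
  for (cl in classes) {
    hemi <- contra[[cl]]
    gain[, cl] <- ifelse(ch$hemisphere == hemi, 1, config$ipsi_gain)
  }

  phase <- resp_phase(t, resp$breaths$all_onsets)
  resp_gain <- runif(n_ch, 0.5, 1.5)
  drift_gain <- runif(n_ch, -1, 1)

  hrf_part <- evoked %*% t(gain) * config$hrf_amplitude       # n x n_ch
  resp_part <- outer(sin(phase), resp_gain) * config$resp_osc_amplitude
  pulse_part <- config$pulse_amplitude * sin(2 * pi * config$pulse_rate_hz * t)
  drift_part <- outer(t, drift_gain) * config$drift_slope

  hbo <- hrf_part + resp_part + pulse_part + drift_part
  if (config$noise_sd > 0)
    hbo <- hbo + matrix(rnorm(n * n_ch, 0, config$noise_sd), n, n_ch)
  hbr <- config$hbr_ratio * hrf_part + 0.25 * resp_part
  if (config$noise_sd > 0)
    hbr <- hbr + matrix(rnorm(n * n_ch, 0, 0.5 * config$noise_sd), n, n_ch)

  ext <- extinction_table()
  od <- .forward_mbll(hbo, hbr, ext)
  intensity <- 10^(-od)

  raw <- structure(list(
    data = intensity, time = t, rate = rate,
    channels = ch$channel, wavelengths = ext$wavelengths,
    montage = montage
  ), class = "raw_intensity")

  structure(list(
    intensity = raw, schedule = schedule, resp = resp$trace,
    breaths = resp$breaths,
    truth = list(hbo = hbo, hbr = hbr, od = od, evoked = evoked,
                 time = t, rate = rate),
    config = config, montage = montage, protocol = protocol,
    sync_mode = sync_mode
  ), class = "fnirs_session")
}

# Forward modified Beer-Lambert model: concentration matrices (n x C, mol/L)
# to an optical-density array (n x C x 2 wavelengths).
.forward_mbll <- function(hbo, hbr, ext = extinction_table()) {
  n <- nrow(hbo); n_ch <- ncol(hbo)
  leff <- ext$distance_cm * ext$dpf
  od <- array(0, c(n, n_ch, length(ext$wavelengths)),
              dimnames = list(NULL, colnames(hbo), ext$wavelengths))
  for (w in seq_along(ext$wavelengths)) {
    od[, , w] <- (ext$eps[w, "hbo"] * hbo + ext$eps[w, "hbr"] * hbr) * leff
  }
  od
}

#' Upper-limb tasks and joints of the ability database
#'
#' The six upper-limb tasks and four joint-angle channels used for movement
#' scoring.
#'
#' @return Character vector of task (joint) names.
#' @export
ability_tasks <- function() {
  c("towel_fold_toward", "towel_fold_sideways", "forward_reach",
    "lateral_transfer", "hand_to_mouth", "key_turn")
}

#' @rdname ability_tasks
#' @export
ability_joints <- function() {
  c("shoulder_flexion", "elbow_flexion", "forearm_pronation",
    "wrist_extension")
}

#' Physiological range of motion per joint
#'
#' Textbook physiological joint-angle limits in degrees, the denominator of
#' the range-of-motion joint weights.
#'
#' @return Named list of `c(min, max)` vectors (degrees).
#' @export
physiological_rom <- function() {
  list(
    shoulder_flexion = c(0, 180),
    elbow_flexion = c(0, 150),
    forearm_pronation = c(-80, 80),
    wrist_extension = c(-70, 70)
  )
}

# Deterministic smooth trajectory template for a task/joint pair: a powered
# half-sine excursion inside the physiological range.
.traj_template <- function(task, joint, u, rom_table = physiological_rom()) {
  ti <- match(task, ability_tasks())
  ji <- match(joint, ability_joints())
  if (is.na(ti)) ti <- 1L
  if (is.na(ji)) ji <- 1L
  lim <- rom_table[[joint]]
  if (is.null(lim)) lim <- c(0, 90)
  range <- lim[2] - lim[1]
  base <- lim[1] + (0.15 + 0.05 * ((ti + ji) %% 3)) * range
  rom <- (0.35 + 0.05 * ((ti * ji) %% 4)) * range
  p <- 1 + 0.5 * ((ti + 2 * ji) %% 3)
  base + rom * sin(pi * u)^p
}

#' Generate a synthetic kinematic cohort
#'
#' Emulates a motion-capture ability database: per subject, task, joint and
#' repetition, a joint-angle trajectory equal to a smooth task template plus
#' subject idiosyncrasy and smooth repetition noise. The idiosyncrasy is
#' dominated by a subject-level offset and amplitude gain shared across all
#' tasks and joints (body geometry and movement habit travel with the
#' subject), with a smaller independent per-task/joint component. Impaired
#' (patient) trajectories get a reduced range of motion, a temporal phase
#' distortion, and an offset shift, each scaled by the task's entry in
#' `impairment_profile`; a zero profile makes patients draws from the
#' normative distribution.
#'
#' @param n_normative Number of normative subjects (>= 3).
#' @param n_reps Repetitions per subject/task (>= 1).
#' @param tasks,joints Character vectors (default: the ability set).
#' @param impairment_profile Named numeric in `[0, 1]` per task (missing tasks
#'   are treated as 0); applied to every patient.
#' @param n_patients Number of patient subjects.
#' @param seed Integer seed.
#' @param n_samples Samples per recorded repetition.
#' @param ages Ages for the normative subjects (recycled); defaults keep all
#'   subjects in one decade so everyone is age-matched.
#' @param patient_age Age assigned to patients.
#' @param subject_offset_sd,subject_gain_sd Between-subject variation
#'   (degrees; multiplicative gain sd), shared across tasks and joints; the
#'   per-task/joint component has a quarter of the offset sd.
#' @param rep_noise_sd Smooth within-subject repetition noise (degrees).
#' @return A long-format `data.frame` with columns `subject_id`, `group`,
#'   `age`, `task`, `joint`, `repetition`, `sample_idx`, `angle_deg`.
#' @export
gen_kinematic_cohort <- function(n_normative = 8, n_reps = 5,
                                 tasks = ability_tasks(),
                                 joints = ability_joints(),
                                 impairment_profile = NULL,
                                 n_patients = 1,
                                 seed = 1L,
                                 n_samples = 100,
                                 ages = 60 + (seq_len(n_normative) - 1) %% 10,
                                 patient_age = 64,
                                 subject_offset_sd = 2,
                                 subject_gain_sd = 0.05,
                                 rep_noise_sd = 1.5) {
  if (n_normative < 3) stop("`n_normative` must be >= 3", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (length(tasks) == 0 || length(joints) == 0)
    stop("`tasks` and `joints` must be non-empty", call. = FALSE)
  set.seed(seed)
  imp <- stats::setNames(numeric(length(tasks)), tasks)
  if (!is.null(impairment_profile)) {
    common <- intersect(names(impairment_profile), tasks)
    imp[common] <- impairment_profile[common]
  }
  u <- seq(0, 1, length.out = n_samples)
  ages <- rep_len(ages, n_normative)

  gen_subject <- function(sid, group, age, profile) {
    out <- vector("list", length(tasks) * length(joints) * n_reps)
    k <- 1L
    offs_subj <- rnorm(1, 0, subject_offset_sd)
    g_subj <- rnorm(1, 1, subject_gain_sd)
    for (task in tasks) {
      e <- profile[[task]]
      for (joint in joints) {
        offs <- offs_subj + rnorm(1, 0, subject_offset_sd / 4)
        g <- g_subj * rnorm(1, 1, subject_gain_sd / 4)
        lim <- physiological_rom()[[joint]]
        base <- .traj_template(task, joint, 0)
        for (r in seq_len(n_reps)) {
          uu <- if (e > 0) u^(1 + e) else u
          tmpl <- .traj_template(task, joint, uu)
          ang <- base + (tmpl - base) * g * (1 - 0.5 * e) + offs - 4 * e
          a1 <- rnorm(1, 0, rep_noise_sd)
          ph <- runif(1, 0, 2 * pi)
          ang <- ang + a1 * sin(2 * pi * u + ph) +
            rnorm(n_samples, 0, rep_noise_sd / 3)
          out[[k]] <- data.frame(
            subject_id = sid, group = group, age = age,
            task = task, joint = joint, repetition = r,
            sample_idx = seq_len(n_samples), angle_deg = ang,
            stringsAsFactors = FALSE
          )
          k <- k + 1L
        }
      }
    }
    do.call(rbind, out)
  }

  zero <- stats::setNames(numeric(length(tasks)), tasks)
  recs <- vector("list", n_normative + n_patients)
  for (s in seq_len(n_normative)) {
    recs[[s]] <- gen_subject(sprintf("N%02d", s), "normative", ages[s], zero)
  }
  for (p in seq_len(n_patients)) {
    recs[[n_normative + p]] <- gen_subject(sprintf("P%02d", p), "patient",
                                           patient_age, imp)
  }
  do.call(rbind, recs)
}
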