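#' Experimental protocol specification
#'
#' Defines the trial structure of a motor-imagery session: a preparation
#' period, a cue (motor-imagery) period, an inter-trial interval, the block
#' structure, and the class labels, balanced within each block.
#'
#' @param prep_s Preparation period (s, > 0).
#' @param cue_s Cue / motor-imagery period (s, > 0).
#' @param iti_s Inter-trial interval (s, > 0).
#' @param n_blocks Number of blocks (runs).
#' @param trials_per_block Trials per block; must be divisible by the number
#'   of labels so classes balance within each block.
#' @param labels Class labels, e.g. `c("left", "right")` or `c("mi", "idle")`.
#' @param sync_mode `"synchronized"` (cues locked to inhalation) or
#'   `"unsynchronized"` (cue at the end of preparation).
#' @param timeout_s In synchronized mode, how long after the preparation
#'   period to wait for an inhalation before flagging and skipping the trial.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(prep_s = 2, cue_s = 10, iti_s = 10,
                          n_blocks = 4, trials_per_block = 40,
                          labels = c("left", "right"),
                          sync_mode = c("synchronized", "unsynchronized"),
                          timeout_s = 10) {
  sync_mode <- match.arg(sync_mode)
  stopifnot(prep_s > 0, cue_s > 0, iti_s > 0, n_blocks >= 1,
            trials_per_block >= 1, timeout_s > 0)
  if (trials_per_block %% length(labels) != 0)
    stop("`trials_per_block` must be divisible by the number of labels ",
         "so classes balance within each block", call. = FALSE)
  structure(list(prep_s = prep_s, cue_s = cue_s, iti_s = iti_s,
                 n_blocks = n_blocks, trials_per_block = trials_per_block,
                 labels = labels, sync_mode = sync_mode,
                 timeout_s = timeout_s),
            class = "protocol_spec")
}

#' Stock protocols
#'
#' `protocol_healthy()` is the laboratory motor-imagery session: 4 blocks of
#' 40 trials (160 total), balanced left/right imagery, 2 s preparation, 10 s
#' cue, 10 s inter-trial interval. `protocol_clinical()` is the clinical
#' calibration session: 4 runs of 80 trials (320 total), half motor imagery
#' and half idle, with a roughly 12 s trial.
#'
#' @param sync_mode Scheduling mode, passed to [protocol_spec()].
#' @return A `protocol_spec`.
#' @export
protocol_healthy <- function(sync_mode = "synchronized") {
  protocol_spec(prep_s = 2, cue_s = 10, iti_s = 10, n_blocks = 4,
                trials_per_block = 40, labels = c("left", "right"),
                sync_mode = sync_mode)
}

#' @rdname protocol_healthy
#' @export
protocol_clinical <- function(sync_mode = "synchronized") {
  protocol_spec(prep_s = 2, cue_s = 6, iti_s = 4, n_blocks = 4,
                trials_per_block = 80, labels = c("mi", "idle"),
                sync_mode = sync_mode)
}

#' Causal inhalation detection from a respiration trace
#'
#' Streaming-compatible hysteresis detector. An inhalation onset is emitted
#' once the signal, after a local trough, has risen by `hysteresis_frac`
#' times the running peak-to-trough amplitude; the event is timestamped at
#' the trough. Consecutive onsets are at least `min_breath_s` apart
#' (refractory period). A flat trace yields zero events. The detector only
#' ever looks at past samples, so feeding the trace in chunks (threading
#' `state` through the calls) reproduces the batch output exactly.
#'
#' @param trace A [resp_trace()].
#' @param min_breath_s Refractory period between onsets (s, > 0).
#' @param hysteresis_frac Fraction of the running amplitude the signal must
#'   rise above the trough before an onset fires (in (0, 1)).
#' @param state Internal detector state from a previous chunk, or `NULL`.
#' @param return_state If `TRUE`, attach the final detector state as
#'   attribute `"state"` for streaming use.
#' @return An object of class `breath_events`: `inhalation_onsets` (s) and
#'   `detection_latency_s` (emission time minus trough time, per event).
#' @export
detect_inhalations <- function(trace, min_breath_s = 1.5,
                               hysteresis_frac = 0.3,
                               state = NULL, return_state = FALSE) {
  if (!inherits(trace, "resp_trace"))
    stop("`trace` must be a resp_trace", call. = FALSE)
  if (min_breath_s <= 0) stop("`min_breath_s` must be > 0", call. = FALSE)
  if (hysteresis_frac <= 0 || hysteresis_frac >= 1)
    stop("`hysteresis_frac` must be in (0, 1)", call. = FALSE)

  if (is.null(state)) {
    state <- list(cur_min = Inf, cur_min_t = NA_real_,
                  cur_max = -Inf, prev_amp = 0, last_event = -Inf)
  }
  x <- trace$samples
  t <- resp_times(trace)
  onsets <- numeric(0)
  latency <- numeric(0)
  cur_min <- state$cur_min; cur_min_t <- state$cur_min_t
  cur_max <- state$cur_max; prev_amp <- state$prev_amp
  last_event <- state$last_event

  for (i in seq_along(x)) {
    xi <- x[i]; ti <- t[i]
    if (xi < cur_min) { cur_min <- xi; cur_min_t <- ti }
    if (xi > cur_max) cur_max <- xi
    amp <- max(cur_max - cur_min, prev_amp)
    if (amp > 0 &&
        xi - cur_min >= hysteresis_frac * amp &&
        xi > cur_min &&
        cur_min_t - last_event >= min_breath_s) {
      onsets <- c(onsets, cur_min_t)
      latency <- c(latency, ti - cur_min_t)
      last_event <- cur_min_t
      prev_amp <- max(cur_max - cur_min, prev_amp)
      cur_min <- xi; cur_min_t <- ti; cur_max <- xi
    }
  }

  out <- structure(list(inhalation_onsets = onsets,
                        detection_latency_s = latency),
                   class = "breath_events")
  if (return_state) {
    attr(out, "state") <- list(cur_min = cur_min, cur_min_t = cur_min_t,
                               cur_max = cur_max, prev_amp = prev_amp,
                               last_event = last_event)
  }
  out
}

#' Schedule a session's cues
#'
#' Builds the trial schedule for a protocol. In unsynchronized mode the cue
#' fires exactly at the end of each preparation period. In synchronized mode
#' the cue fires at the first detected inhalation onset at or after the end
#' of the preparation period; the extra delay is recorded as `wait_s`. If no
#' inhalation arrives within `timeout_s` of the preparation end, the trial is
#' flagged (`skipped = TRUE`) and the session moves on. Labels are shuffled
#' within each block with balanced classes.
#'
#' @param protocol A [protocol_spec()].
#' @param breath_events A `breath_events` object (required in synchronized
#'   mode).
#' @param sync_mode Override of the protocol's mode.
#' @param seed Integer seed for the label shuffle, or `NULL` to draw from the
#'   current RNG stream.
#' @param t_start Session time at which the first preparation period begins.
#' @param unsync_wait_range In unsynchronized mode, an optional `c(min, max)`
#'   range (s) from which a per-trial wait between preparation end and cue is
#'   drawn uniformly. This emulates a conventional protocol whose trial
#'   timing jitter matches the synchronized protocol's inhalation waits while
#'   remaining ignorant of respiration, which isolates respiratory-phase
#'   alignment as the only difference between the two modes.
#' @return A `data.frame` (class `trial_schedule`) with columns `trial_idx`,
#'   `block`, `prep_onset_s`, `cue_onset_s`, `label`, `wait_s`, `skipped`,
#'   and attribute `sync_mode`.
#' @export
schedule_session <- function(protocol, breath_events = NULL,
                             sync_mode = protocol$sync_mode, seed = NULL,
                             t_start = 0, unsync_wait_range = NULL) {
  sync_mode <- match.arg(sync_mode, c("synchronized", "unsynchronized"))
  if (sync_mode == "synchronized" && is.null(breath_events))
    stop("synchronized scheduling requires `breath_events`", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  labels <- unlist(lapply(seq_len(protocol$n_blocks), function(b) {
    sample(rep(protocol$labels,
               protocol$trials_per_block / length(protocol$labels)))
  }))
  n <- length(labels)
  onsets <- if (!is.null(breath_events)) breath_events$inhalation_onsets
  uwait <- if (sync_mode == "unsynchronized" && !is.null(unsync_wait_range))
    runif(n, unsync_wait_range[1], unsync_wait_range[2]) else numeric(n)
  prep_onset <- cue_onset <- wait <- numeric(n)
  skipped <- logical(n)
  cursor <- t_start
  for (i in seq_len(n)) {
    prep_onset[i] <- cursor
    prep_end <- cursor + protocol$prep_s
    if (sync_mode == "unsynchronized") {
      cue_onset[i] <- prep_end + uwait[i]
      wait[i] <- uwait[i]
    } else {
      nxt <- onsets[onsets >= prep_end]
      if (length(nxt) == 0 || nxt[1] > prep_end + protocol$timeout_s) {
        skipped[i] <- TRUE
        cue_onset[i] <- NA_real_
        wait[i] <- NA_real_
        cursor <- prep_end + protocol$timeout_s + protocol$iti_s
        next
      }
      cue_onset[i] <- nxt[1]
      wait[i] <- nxt[1] - prep_end
    }
    cursor <- cue_onset[i] + protocol$cue_s + protocol$iti_s
  }
  out <- data.frame(
    trial_idx = seq_len(n),
    block = rep(seq_len(protocol$n_blocks), each = protocol$trials_per_block),
    prep_onset_s = prep_onset, cue_onset_s = cue_onset,
    label = labels, wait_s = wait, skipped = skipped,
    stringsAsFactors = FALSE
  )
  attr(out, "sync_mode") <- sync_mode
  class(out) <- c("trial_schedule", "data.frame")
  out
}
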