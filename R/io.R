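#' Write and read session artifacts as tidy CSV
#'
#' Intensity is stored long (`time_s`, `channel`, `wavelength_nm`, `value`),
#' respiration as (`time_s`, `value`) with the rate recoverable from the
#' time stamps, and trial logs as (`trial_idx`, `block`, `prep_onset_s`,
#' `cue_onset_s`, `label`, `wait_s`, `skipped`). All files are UTF-8,
#' comma-separated, '.' decimal, with a mandatory header row; times are
#' seconds as floats.
#'
#' @param raw A `raw_intensity` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_intensity_csv <- function(raw, path) {
  n <- dim(raw$data)[1]; n_ch <- dim(raw$data)[2]; n_w <- dim(raw$data)[3]
  df <- data.frame(
    time_s = rep(raw$time, times = n_ch * n_w),
    channel = rep(rep(raw$channels, each = n), times = n_w),
    wavelength_nm = rep(raw$wavelengths, each = n * n_ch),
    value = as.vector(raw$data)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_csv
#' @param trace A [resp_trace()].
#' @export
write_respiration_csv <- function(trace, path) {
  write.csv(data.frame(time_s = resp_times(trace), value = trace$samples),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_csv
#' @param schedule A `trial_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  df <- as.data.frame(schedule)
  df$sync_mode <- attr(schedule, "sync_mode")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s: missing column(s) %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

# Infer a single uniform sampling rate from time stamps; errors on
# non-monotone or irregular spacing.
.infer_rate <- function(time_s, what, tol = 1e-6) {
  dt <- diff(time_s)
  if (any(dt <= 0))
    stop(sprintf("%s: time stamps not strictly increasing (row %d)",
                 what, which(dt <= 0)[1] + 1), call. = FALSE)
  if (max(dt) - min(dt) > tol * mean(dt) * 100)
    stop(sprintf("%s: mixed sampling rates", what), call. = FALSE)
  1 / mean(dt)
}

#' Read a recorded session from CSV files
#'
#' Validates and loads the CSV schemas written by [write_intensity_csv()]
#' and friends. Schema violations (missing columns, non-monotone time,
#' mixed sampling rates) are reported with the offending column or row.
#'
#' @param intensity_csv Path to the long-format intensity CSV.
#' @param respiration_csv Optional path to the respiration CSV.
#' @param schedule_csv Optional path to the trial-log CSV.
#' @return A list with `intensity` (`raw_intensity`), `resp`
#'   ([resp_trace()] or `NULL`), `schedule` (`trial_schedule` or `NULL`).
#' @export
read_session <- function(intensity_csv, respiration_csv = NULL,
                         schedule_csv = NULL) {
  df <- read.csv(intensity_csv)
  .require_columns(df, c("time_s", "channel", "wavelength_nm", "value"),
                   "intensity CSV")
  channels <- unique(df$channel)
  wavelengths <- sort(unique(df$wavelength_nm))
  time <- sort(unique(df$time_s))
  rate <- .infer_rate(time, "intensity CSV")
  n <- length(time)
  arr <- array(NA_real_, c(n, length(channels), length(wavelengths)),
               dimnames = list(NULL, channels, wavelengths))
  for (w in seq_along(wavelengths)) {
    for (c_i in seq_along(channels)) {
      sel <- df$channel == channels[c_i] & df$wavelength_nm == wavelengths[w]
      sub <- df[sel, , drop = FALSE]
      if (nrow(sub) != n)
        stop(sprintf("intensity CSV: channel %s @ %g nm has %d rows, expected %d",
                     channels[c_i], wavelengths[w], nrow(sub), n),
             call. = FALSE)
      arr[, c_i, w] <- sub$value[order(sub$time_s)]
    }
  }
  raw <- structure(list(data = arr, time = time, rate = rate,
                        channels = channels, wavelengths = wavelengths,
                        montage = NULL),
                   class = "raw_intensity")
  resp <- NULL
  if (!is.null(respiration_csv)) {
    rd <- read.csv(respiration_csv)
    .require_columns(rd, c("time_s", "value"), "respiration CSV")
    r_rate <- .infer_rate(rd$time_s, "respiration CSV")
    resp <- resp_trace(rd$value, r_rate, t0 = rd$time_s[1])
  }
  schedule <- NULL
  if (!is.null(schedule_csv)) {
    sd_ <- read.csv(schedule_csv)
    .require_columns(sd_, c("trial_idx", "cue_onset_s", "label", "wait_s"),
                     "schedule CSV")
    sync <- if ("sync_mode" %in% names(sd_)) sd_$sync_mode[1] else
      "unsynchronized"
    if (!"skipped" %in% names(sd_)) sd_$skipped <- FALSE
    sd_$sync_mode <- NULL
    attr(sd_, "sync_mode") <- sync
    class(sd_) <- c("trial_schedule", "data.frame")
    schedule <- sd_
  }
  list(intensity = raw, resp = resp, schedule = schedule)
}

#' Read long-format joint-angle kinematics
#'
#' @param path CSV with columns `subject_id`, `group`, `age`, `task`,
#'   `joint`, `repetition`, `sample_idx`, `angle_deg`.
#' @return A validated `data.frame`.
#' @export
read_kinematics <- function(path) {
  df <- read.csv(path)
  .require_columns(df, c("subject_id", "group", "age", "task", "joint",
                         "repetition", "sample_idx", "angle_deg"),
                   "kinematics CSV")
  df
}
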