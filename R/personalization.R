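#' Resample a trajectory to a percent-of-movement time base
#'
#' Linear resampling of a repetition onto `n_points` equally spaced points
#' from 0 to 100% of the movement, the common time base on which repetition
#' means, group references and DTW all operate.
#'
#' @param y Numeric trajectory (length >= 2).
#' @param n_points Number of output points (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
resample_trajectory <- function(y, n_points = 101) {
  if (length(y) < 2) stop("repetition shorter than 2 samples", call. = FALSE)
  approx(seq(0, 1, length.out = length(y)),
         y, xout = seq(0, 1, length.out = n_points))$y
}

# Decade age bin used for age matching.
.age_bin <- function(age) floor(age / 10)

#' Per-subject mean trajectories on a common time base
#'
#' For every (subject, task, joint), each repetition is resampled to
#' `n_points` percent-of-movement points and averaged over the subject's
#' repetitions. Repetitions shorter than 2 samples are dropped with a
#' warning.
#'
#' @param dataset Long-format kinematics (`subject_id`, `group`, `age`,
#'   `task`, `joint`, `repetition`, `sample_idx`, `angle_deg`), as produced
#'   by [gen_kinematic_cohort()] or [read_kinematics()].
#' @param n_points Points of the common time base.
#' @return A list of class `trajectory_summary`: `meta` (one row per
#'   subject/task/joint with `subject_id`, `group`, `age`, `task`, `joint`,
#'   `n_reps`), `mean_traj` (rows matching `meta`, `n_points` columns), and
#'   `reps` (list of per-repetition matrices, rows = repetitions).
#' @export
summarize_trajectories <- function(dataset, n_points = 101) {
  need <- c("subject_id", "group", "age", "task", "joint", "repetition",
            "sample_idx", "angle_deg")
  if (nrow(dataset) == 0) stop("empty dataset", call. = FALSE)
  if (!all(need %in% names(dataset)))
    stop("dataset must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  key <- interaction(dataset$subject_id, dataset$task, dataset$joint,
                     drop = TRUE, lex.order = TRUE)
  groups <- split(seq_len(nrow(dataset)), key)
  meta <- vector("list", length(groups))
  mt <- matrix(NA_real_, length(groups), n_points)
  reps <- vector("list", length(groups))
  dropped <- 0L
  for (g in seq_along(groups)) {
    d <- dataset[groups[[g]], , drop = FALSE]
    rmat <- NULL
    for (r in sort(unique(d$repetition))) {
      y <- d$angle_deg[d$repetition == r][order(d$sample_idx[d$repetition == r])]
      if (length(y) < 2) { dropped <- dropped + 1L; next }
      rmat <- rbind(rmat, resample_trajectory(y, n_points))
    }
    if (is.null(rmat))
      stop("no usable repetition for ", levels(key)[g], call. = FALSE)
    meta[[g]] <- data.frame(
      subject_id = d$subject_id[1], group = d$group[1], age = d$age[1],
      task = d$task[1], joint = d$joint[1], n_reps = nrow(rmat),
      stringsAsFactors = FALSE
    )
    mt[g, ] <- colMeans(rmat)
    reps[[g]] <- rmat
  }
  if (dropped > 0)
    warning(sprintf("%d repetition(s) shorter than 2 samples dropped", dropped),
            call. = FALSE)
  structure(list(meta = do.call(rbind, meta), mean_traj = mt, reps = reps,
                 n_points = n_points),
            class = "trajectory_summary")
}

# Pooled group-reference trajectory for one (task, joint): the mean over all
# repetitions of the age-matched normative subjects (each subject weighted
# by its repetition count), optionally excluding one subject (leave-one-out).
.reference_trajectory <- function(summary, task, joint, age_bin,
                                  exclude_subject = NULL) {
  m <- summary$meta
  keep <- m$group == "normative" & m$task == task & m$joint == joint &
    .age_bin(m$age) == age_bin
  if (!is.null(exclude_subject)) keep <- keep & m$subject_id != exclude_subject
  sel <- which(keep)
  if (length(sel) == 0)
    stop(sprintf("no age-matched normative subjects in decade bin %d for %s/%s",
                 age_bin, task, joint), call. = FALSE)
  all_reps <- do.call(rbind, summary$reps[sel])
  colMeans(all_reps)
}

#' Classic dynamic time warping distance
#'
#' Full-alignment DTW with absolute-difference local cost and symmetric
#' steps (1,0), (0,1), (1,1); no window, no path normalization. Returns the
#' total accumulated cost of the optimal monotone alignment. Symmetric in
#' its arguments and zero iff the sequences are identical.
#'
#' @param a,b Numeric sequences (length >= 1).
#' @return The DTW cost (same units as the inputs, summed over the path).
#' @export
dtw_distance <- function(a, b) {
  if (length(a) < 1 || length(b) < 1)
    stop("sequences must be non-empty", call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("sequences must be finite", call. = FALSE)
  .dtw_cost_cpp(as.numeric(a), as.numeric(b))
}

#' Deviation-from-normative movement scores (DSS)
#'
#' For each requested (subject, task, joint), the DTW cost between the
#' subject's repetition-mean trajectory and the pooled mean trajectory of
#' the age-matched normative subjects, on the common percent-of-movement
#' time base. For normative subjects the reference excludes the subject
#' itself (leave-one-out); for patients it uses all age-matched normative
#' subjects.
#'
#' @param dataset Long-format kinematics, or a `trajectory_summary`.
#' @param subjects,tasks,joints Optional filters (default: everything).
#' @param n_points Common time base length (when `dataset` is raw).
#' @return A `data.frame` with columns `subject_id`, `group`, `age`, `task`,
#'   `joint`, `dss`, `loo`.
#' @export
compute_dss <- function(dataset, subjects = NULL, tasks = NULL,
                        joints = NULL, n_points = 101) {
  summary <- if (inherits(dataset, "trajectory_summary")) dataset else
    summarize_trajectories(dataset, n_points)
  m <- summary$meta
  rows <- seq_len(nrow(m))
  if (!is.null(subjects)) rows <- rows[m$subject_id[rows] %in% subjects]
  if (!is.null(tasks)) rows <- rows[m$task[rows] %in% tasks]
  if (!is.null(joints)) rows <- rows[m$joint[rows] %in% joints]
  out <- vector("list", length(rows))
  for (k in seq_along(rows)) {
    i <- rows[k]
    loo <- m$group[i] == "normative"
    ref <- .reference_trajectory(
      summary, m$task[i], m$joint[i], .age_bin(m$age[i]),
      exclude_subject = if (loo) m$subject_id[i]
    )
    out[[k]] <- data.frame(
      subject_id = m$subject_id[i], group = m$group[i], age = m$age[i],
      task = m$task[i], joint = m$joint[i],
      dss = dtw_distance(summary$mean_traj[i, ], ref), loo = loo,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Normative interval of DSS scores
#'
#' Parametric 95% interval of the pooled normative DSS per (task, joint):
#' `mean +/- z_(1 - alpha/2) * sd`, with the lower bound clipped at 0 (DTW
#' costs are non-negative). At least 3 normative scores are required per
#' cell.
#'
#' @param dss_scores Output of [compute_dss()] (normative rows are used), or
#'   a bare numeric vector of scores for a single cell.
#' @param level Coverage level (default 0.95).
#' @return A `data.frame` with columns `task`, `joint`, `n`, `mean`, `sd`,
#'   `lower`, `upper` (single-row with `task = joint = NA` for vector
#'   input).
#' @export
normative_interval <- function(dss_scores, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  one <- function(v, task = NA_character_, joint = NA_character_) {
    if (length(v) < 3)
      stop("need at least 3 normative scores per (task, joint)",
           call. = FALSE)
    mu <- mean(v); s <- sd(v)
    data.frame(task = task, joint = joint, n = length(v), mean = mu, sd = s,
               lower = max(mu - z * s, 0), upper = mu + z * s,
               stringsAsFactors = FALSE)
  }
  if (is.numeric(dss_scores)) return(one(dss_scores))
  d <- dss_scores[dss_scores$group == "normative", , drop = FALSE]
  cells <- unique(d[, c("task", "joint")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    v <- d$dss[d$task == cells$task[i] & d$joint == cells$joint[i]]
    out[[i]] <- one(v, cells$task[i], cells$joint[i])
  }
  do.call(rbind, out)
}

#' Range-of-motion joint weights per task
#'
#' `W_joint = |max(ROM_sa) - min(ROM_sa)| / |max(ROM_phys) - min(ROM_phys)|
#' * 100%`, where the normative range pools all age-matched normative
#' trajectories for the task and joint. Weights are additionally normalized
#' within each task to sum to 1 (`w_norm`) for the final task score.
#'
#' @param dataset Long-format kinematics (normative rows are used).
#' @param physiological_rom Named list of `c(min, max)` per joint
#'   (default [physiological_rom()]).
#' @param age_bin Optional decade bin to pool; default pools all normative
#'   subjects.
#' @return A `data.frame` with columns `task`, `joint`, `w_pct`, `w_norm`.
#' @export
joint_weights <- function(dataset, physiological_rom = rsbci::physiological_rom(),
                          age_bin = NULL) {
  d <- dataset[dataset$group == "normative", , drop = FALSE]
  if (!is.null(age_bin)) d <- d[.age_bin(d$age) == age_bin, , drop = FALSE]
  if (nrow(d) == 0) stop("no normative trajectories", call. = FALSE)
  cells <- unique(d[, c("task", "joint")])
  w_pct <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    lim <- physiological_rom[[cells$joint[i]]]
    if (is.null(lim))
      stop("no physiological ROM for joint ", cells$joint[i], call. = FALSE)
    phys <- abs(lim[2] - lim[1])
    if (phys == 0) stop("zero physiological range", call. = FALSE)
    ang <- d$angle_deg[d$task == cells$task[i] & d$joint == cells$joint[i]]
    w_pct[i] <- abs(max(ang) - min(ang)) / phys * 100
  }
  out <- data.frame(cells, w_pct = w_pct, stringsAsFactors = FALSE)
  out$w_norm <- NA_real_
  for (task in unique(out$task)) {
    sel <- out$task == task
    out$w_norm[sel] <- out$w_pct[sel] / sum(out$w_pct[sel])
  }
  rownames(out) <- NULL
  out
}

#' Default correspondence between ability tasks and intervention ADLs
#'
#' A synthetic, editable movement-similarity mapping between the six
#' upper-limb ability-database tasks and the six activities of daily living
#' of the intervention; ships as YAML in `inst/extdata/task_adl_map.yaml`.
#'
#' @return Named character vector: ability task -> ADL description.
#' @export
task_adl_map <- function() {
  path <- system.file("extdata", "task_adl_map.yaml", package = "rsbci")
  if (nzchar(path)) {
    unlist(yaml::read_yaml(path))
  } else {
    c(towel_fold_toward = "using two hands to move a towel",
      towel_fold_sideways = "picking up a small block with two fingers",
      forward_reach = "moving an object upwards to a cabinet",
      lateral_transfer = "scanning goods",
      hand_to_mouth = "performing an eating action",
      key_turn = "pouring water into a cup")
  }
}

#' Screen, score and rank rehabilitation tasks for a patient
#'
#' A task does not need rehabilitation only if the patient's DSS for ALL of
#' its joints lies within the 95% normative interval. For flagged tasks,
#' each joint's z-score `(DSS_p - mean_norm) / sd_norm` is combined into the
#' final task score `FS_task = sum_joint w_norm * z_joint`; higher scores
#' mean larger deviation from normative movement and higher priority.
#' Flagged tasks are ranked by descending final score and the top
#' `max_tasks` (default 4) are selected and mapped to their intervention
#' ADLs; flagged tasks beyond the cap are listed as unselected overflow.
#'
#' @param patient_dss [compute_dss()] rows for one patient.
#' @param intervals [normative_interval()] table.
#' @param weights [joint_weights()] table.
#' @param adl_map Named task -> ADL mapping (default [task_adl_map()]).
#' @param max_tasks Maximum number of tasks selected for the regime.
#' @param expected_tasks Optional task set that must be fully scored (e.g.
#'   [ability_tasks()]); a missing task or joint score is an error.
#' @return A list of class `task_scorecard`: `scorecard` (`data.frame` with
#'   `task`, `needs_rehab`, `fs`, `rank`, `selected`, `adl`) and
#'   `joint_detail` (`task`, `joint`, `dss`, `lower`, `upper`, `in_interval`,
#'   `z`, `w_norm`).
#' @export
rank_tasks <- function(patient_dss, intervals, weights,
                       adl_map = task_adl_map(), max_tasks = 4,
                       expected_tasks = NULL) {
  if (length(unique(patient_dss$subject_id)) != 1)
    stop("`patient_dss` must contain exactly one patient", call. = FALSE)
  if (!is.null(expected_tasks)) {
    miss_t <- setdiff(expected_tasks, unique(patient_dss$task))
    if (length(miss_t) > 0)
      stop("missing task score(s): ", paste(miss_t, collapse = ", "),
           call. = FALSE)
  }
  d <- merge(patient_dss, intervals, by = c("task", "joint"))
  d <- merge(d, weights[, c("task", "joint", "w_norm")],
             by = c("task", "joint"))
  tasks <- unique(patient_dss$task)
  missing <- setdiff(
    paste(patient_dss$task, patient_dss$joint),
    paste(d$task, d$joint))
  if (length(missing) > 0)
    stop("missing interval/weight for: ", paste(missing, collapse = "; "),
         call. = FALSE)
  d$in_interval <- d$dss >= d$lower & d$dss <= d$upper
  d$z <- (d$dss - d$mean) / d$sd
  card <- data.frame(task = tasks, stringsAsFactors = FALSE)
  card$needs_rehab <- vapply(tasks, function(tk)
    !all(d$in_interval[d$task == tk]), logical(1))
  card$fs <- vapply(tasks, function(tk) {
    sel <- d$task == tk
    sum(d$w_norm[sel] * d$z[sel])
  }, numeric(1))
  card$rank <- NA_integer_
  flagged <- which(card$needs_rehab)
  ord <- flagged[order(-card$fs[flagged])]
  card$rank[ord] <- seq_along(ord)
  card$selected <- !is.na(card$rank) & card$rank <= max_tasks
  card$adl <- unname(adl_map[card$task])
  card <- card[order(is.na(card$rank), card$rank), , drop = FALSE]
  rownames(card) <- NULL
  structure(list(
    scorecard = card,
    joint_detail = d[, c("task", "joint", "dss", "lower", "upper",
                         "in_interval", "z", "w_norm")]
  ), class = "task_scorecard")
}

#' @export
print.task_scorecard <- function(x, ...) {
  sel <- x$scorecard[x$scorecard$selected, , drop = FALSE]
  cat(sprintf("<task_scorecard> %d/%d tasks flagged, %d selected\n",
              sum(x$scorecard$needs_rehab), nrow(x$scorecard), nrow(sel)))
  if (nrow(sel)) print(sel[, c("rank", "task", "fs", "adl")], row.names = FALSE)
  invisible(x)
}

#' One-call personalization for a patient
#'
#' Convenience wrapper chaining [summarize_trajectories()], [compute_dss()],
#' [normative_interval()], [joint_weights()] and [rank_tasks()] for a single
#' patient against the normative subjects in `dataset`.
#'
#' @param dataset Long-format kinematics with normative subjects and the
#'   patient.
#' @param patient_id Subject id of the patient (default: first subject with
#'   `group == "patient"`).
#' @param level Interval coverage.
#' @param ... Passed to [rank_tasks()].
#' @return A `task_scorecard`.
#' @export
personalize <- function(dataset, patient_id = NULL, level = 0.95, ...) {
  if (is.null(patient_id)) {
    patient_id <- unique(dataset$subject_id[dataset$group == "patient"])[1]
    if (is.na(patient_id)) stop("no patient in dataset", call. = FALSE)
  }
  summary <- summarize_trajectories(dataset)
  dss <- compute_dss(summary)
  intervals <- normative_interval(dss, level)
  weights <- joint_weights(dataset)
  rank_tasks(dss[dss$subject_id == patient_id, , drop = FALSE],
             intervals, weights,
             expected_tasks = intersect(ability_tasks(), unique(dataset$task)),
             ...)
}
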