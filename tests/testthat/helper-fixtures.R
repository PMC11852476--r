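# Shared fixtures and independent oracles for the test suite.

# Small desk-scale session protocol.
tiny_protocol <- function(n_trials = 8, labels = c("left", "right"),
                          sync_mode = "synchronized", ...) {
  protocol_spec(n_blocks = 1, trials_per_block = n_trials, labels = labels,
                sync_mode = sync_mode, ...)
}

default_montage <- build_montage()

# Brute-force DTW oracle: exhaustive enumeration of all monotone warping
# paths with steps (1,0), (0,1), (1,1). Exponential; only for length <= 6.
dtw_brute <- function(a, b) {
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1 && j == 1) return(c0)
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    c0 + best
  }
  rec(length(a), length(b))
}

# Circular summary statistics for respiratory phases.
circ_resultant <- function(phase) {
  sqrt(mean(cos(phase))^2 + mean(sin(phase))^2)
}
circ_sd <- function(phase) sqrt(-2 * log(circ_resultant(phase)))
# Rayleigh uniformity test p-value (large-sample approximation).
rayleigh_p <- function(phase) {
  n <- length(phase)
  z <- n * circ_resultant(phase)^2
  exp(-z) * (1 + (2 * z - z^2) / (4 * n))
}

# A tiny two-class gaussian feature set with a controllable class separation.
make_features <- function(n_per_class = 50, p = 10, delta = 0, seed = 1) {
  set.seed(seed)
  x <- rbind(
    matrix(rnorm(n_per_class * p), n_per_class, p),
    matrix(rnorm(n_per_class * p, mean = delta), n_per_class, p)
  )
  list(x = x, labels = rep(c("left", "right"), each = n_per_class))
}

# Long-format kinematics built from explicit per-repetition trajectories:
# traj_list is a named list subject -> list(task -> list(joint -> matrix of
# repetitions in rows)).
kin_from_trajectories <- function(traj_list, groups, ages) {
  out <- list()
  for (sid in names(traj_list)) {
    for (task in names(traj_list[[sid]])) {
      for (joint in names(traj_list[[sid]][[task]])) {
        reps <- traj_list[[sid]][[task]][[joint]]
        if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
        for (r in seq_len(nrow(reps))) {
          out[[length(out) + 1]] <- data.frame(
            subject_id = sid, group = groups[[sid]], age = ages[[sid]],
            task = task, joint = joint, repetition = r,
            sample_idx = seq_len(ncol(reps)), angle_deg = reps[r, ],
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, out)
}
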