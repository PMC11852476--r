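test_that("trajectory summaries average resampled repetitions", {
  ramp <- seq(0, 50, length.out = 60)
  kin <- kin_from_trajectories(
    list(N1 = list(forward_reach = list(shoulder_flexion =
      rbind(ramp, ramp + 1, ramp + 2)))),
    groups = c(N1 = "normative"), ages = c(N1 = 60))
  s <- summarize_trajectories(kin)
  expect_equal(s$meta$n_reps, 3)
  # mean of ramps with offsets {0, 1, 2} is the ramp shifted by 1
  expect_equal(s$mean_traj[1, ], resample_trajectory(ramp) + 1,
               tolerance = 1e-12)
  # one repetition: the summary is that repetition resampled
  kin1 <- kin_from_trajectories(
    list(N1 = list(forward_reach = list(shoulder_flexion = ramp))),
    groups = c(N1 = "normative"), ages = c(N1 = 60))
  s1 <- summarize_trajectories(kin1)
  expect_equal(s1$mean_traj[1, ], resample_trajectory(ramp))
  # two identical repetitions equal either one
  kin2 <- kin_from_trajectories(
    list(N1 = list(forward_reach = list(shoulder_flexion = rbind(ramp, ramp)))),
    groups = c(N1 = "normative"), ages = c(N1 = 60))
  expect_equal(summarize_trajectories(kin2)$mean_traj[1, ],
               resample_trajectory(ramp))
  expect_error(summarize_trajectories(kin[0, ]), "empty")
  expect_error(resample_trajectory(3), "shorter")
})

test_that("dynamic time warping matches exhaustive path enumeration", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
  set.seed(31)
  for (i in 1:60) {
    a <- round(rnorm(sample(1:6, 1)), 2)
    b <- round(rnorm(sample(1:6, 1)), 2)
    expect_equal(dtw_distance(a, b), dtw_brute(a, b), tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a), tolerance = 1e-12)
  }
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
})

test_that("DSS scores use leave-one-out references for normative subjects", {
  const <- function(v) rep(v, 50)
  kin <- kin_from_trajectories(
    list(N1 = list(key_turn = list(forearm_pronation = const(0))),
         N2 = list(key_turn = list(forearm_pronation = const(0))),
         N3 = list(key_turn = list(forearm_pronation = const(3)))),
    groups = c(N1 = "normative", N2 = "normative", N3 = "normative"),
    ages = c(N1 = 60, N2 = 62, N3 = 64))
  dss <- compute_dss(kin)
  # subject 3 (constant 3 deg) against the mean of the others (0 deg):
  # 101 aligned points x 3 deg
  expect_equal(dss$dss[dss$subject_id == "N3"], 101 * 3)
  expect_equal(dss$dss[dss$subject_id == "N1"],
               101 * 1.5)  # reference mean(0, 3) = 1.5
  expect_true(all(dss$loo))

  # a patient identical to the pooled reference scores zero
  kin_p <- rbind(kin, kin_from_trajectories(
    list(P1 = list(key_turn = list(forearm_pronation = const(1)))),
    groups = c(P1 = "patient"), ages = c(P1 = 63)))
  dss_p <- compute_dss(kin_p, subjects = "P1")
  expect_equal(dss_p$dss, 0)
  expect_false(dss_p$loo)

  # no age-matched normative subjects names the decade bin
  kin_young <- rbind(kin, kin_from_trajectories(
    list(P2 = list(key_turn = list(forearm_pronation = const(1)))),
    groups = c(P2 = "patient"), ages = c(P2 = 30)))
  expect_error(compute_dss(kin_young, subjects = "P2"), "bin 3")
})

test_that("normative intervals follow the parametric rule", {
  iv <- normative_interval(c(1, 2, 3))
  expect_equal(iv$mean, 2)
  expect_equal(iv$sd, 1)
  expect_equal(iv$lower, 0.04, tolerance = 1e-3)
  expect_equal(iv$upper, 3.96, tolerance = 1e-3)
  # zero spread collapses the interval
  iv0 <- normative_interval(c(5, 5, 5))
  expect_equal(iv0$lower, 5)
  expect_equal(iv0$upper, 5)
  # the lower bound never goes below zero (DTW costs are non-negative)
  ivc <- normative_interval(c(0.1, 0.2, 0.3))
  expect_gte(ivc$lower, 0)
  expect_error(normative_interval(c(1, 2)), "at least 3")
})

test_that("joint weights are the normative-to-physiological ROM ratio", {
  tr <- seq(10, 60, length.out = 40)  # excursion 10-60 degrees
  kin <- kin_from_trajectories(
    list(N1 = list(forward_reach = list(
      shoulder_flexion = tr, elbow_flexion = tr))),
    groups = c(N1 = "normative"), ages = c(N1 = 60))
  rom <- list(shoulder_flexion = c(0, 100), elbow_flexion = c(0, 100))
  w <- joint_weights(kin, rom)
  expect_equal(w$w_pct, c(50, 50))
  expect_equal(w$w_norm, c(0.5, 0.5))
  # excursion equal to the physiological range scores 100%
  w2 <- joint_weights(kin, list(shoulder_flexion = c(10, 60),
                                elbow_flexion = c(10, 60)))
  expect_equal(w2$w_pct, c(100, 100))
  expect_error(joint_weights(kin, list(shoulder_flexion = c(5, 5),
                                       elbow_flexion = c(0, 1))),
               "zero physiological range")
})

test_that("task ranking screens by interval membership and weights z-scores", {
  tasks <- ability_tasks()
  # minimal hand-built inputs: one task with two joints, weights 0.6/0.4 and
  # z-scores 2/5 must produce FS = 3.2
  mk <- function(task, joint, dss) data.frame(
    subject_id = "P1", group = "patient", age = 60, task = task,
    joint = joint, dss = dss, loo = FALSE, stringsAsFactors = FALSE)
  patient <- rbind(mk("forward_reach", "shoulder_flexion", 30),
                   mk("forward_reach", "elbow_flexion", 60))
  iv <- data.frame(task = "forward_reach",
                   joint = c("shoulder_flexion", "elbow_flexion"),
                   n = 5, mean = c(10, 10), sd = c(10, 10),
                   lower = c(0, 0), upper = c(29.6, 29.6))
  w <- data.frame(task = "forward_reach",
                  joint = c("shoulder_flexion", "elbow_flexion"),
                  w_pct = c(60, 40), w_norm = c(0.6, 0.4))
  card <- rank_tasks(patient, iv, w)
  expect_true(card$scorecard$needs_rehab[1])
  expect_equal(card$scorecard$fs[1], 0.6 * 2 + 0.4 * 5)
  expect_equal(card$scorecard$rank[1], 1L)

  # final score is invariant to joint ordering
  card_rev <- rank_tasks(patient[2:1, ], iv, w)
  expect_equal(card_rev$scorecard$fs, card$scorecard$fs)

  # six tasks, five flagged: exactly four selected, one overflow
  patient6 <- do.call(rbind, lapply(seq_along(tasks), function(i)
    mk(tasks[i], "shoulder_flexion", c(100, 80, 60, 40, 30, 5)[i])))
  iv6 <- data.frame(task = tasks, joint = "shoulder_flexion", n = 5,
                    mean = 10, sd = 5, lower = 0.2, upper = 19.8)
  w6 <- data.frame(task = tasks, joint = "shoulder_flexion",
                   w_pct = 50, w_norm = 1)
  card6 <- rank_tasks(patient6, iv6, w6)
  expect_equal(sum(card6$scorecard$needs_rehab), 5)
  expect_equal(sum(card6$scorecard$selected), 4)
  flagged <- card6$scorecard[card6$scorecard$needs_rehab, ]
  expect_equal(flagged$task[order(flagged$rank)],
               tasks[order(-c(100, 80, 60, 40, 30, 5))][1:5])
  overflow <- flagged[!flagged$selected, ]
  expect_equal(nrow(overflow), 1)
  expect_equal(overflow$task, "hand_to_mouth")

  # a patient inside every interval selects nothing
  patient_ok <- do.call(rbind, lapply(tasks, function(tk)
    mk(tk, "shoulder_flexion", 10)))
  card_ok <- rank_tasks(patient_ok, iv6, w6)
  expect_equal(sum(card_ok$scorecard$selected), 0)
  expect_error(rank_tasks(patient6[-1, ], iv6, w6,
                          expected_tasks = tasks), "missing task")
})

test_that("impaired tasks surface in the personalized ranking", {
  hits <- 0
  for (s in 1:10) {
    kin <- gen_kinematic_cohort(
      n_normative = 6, n_reps = 3, n_patients = 1, n_samples = 60,
      seed = 500 + s,
      impairment_profile = c(forward_reach = 0.7, key_turn = 0.5))
    card <- personalize(kin)$scorecard
    top2 <- card$task[!is.na(card$rank) & card$rank <= 2]
    hits <- hits + setequal(top2, c("forward_reach", "key_turn"))
  }
  expect_gte(hits, 8)
})
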