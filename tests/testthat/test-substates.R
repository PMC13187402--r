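test_that("kinematics satisfy the derivative and baseline identities", {
  traj <- matrix(3, 20, 2)
  kin <- compute_kinematics(traj)
  expect_equal(kin$speed, matrix(0, 19, 2), ignore_attr = TRUE)
  expect_equal(kin$displacement, matrix(0, 20, 2), ignore_attr = TRUE)

  ramp <- matrix(0.5 * (0:19), 20, 1)
  kin2 <- compute_kinematics(ramp, dt = 0.25)
  expect_equal(kin2$speed, matrix(2, 19, 1), ignore_attr = TRUE)

  x <- with_seed(1, matrix(runif(40), 20, 2))
  kin3 <- compute_kinematics(x)
  expect_equal(kin3$displacement[1, ], c(0, 0), ignore_attr = TRUE)
  # telescoping: displacement equals the cumulative sum of differences
  expect_equal(kin3$displacement[-1, ], apply(diff(x), 2, cumsum),
               ignore_attr = TRUE)

  expect_error(compute_kinematics(x, dt = 0), "positive")
  expect_error(compute_kinematics(x[1, , drop = FALSE]), "2 bins")
})

test_that("dtw distance equals the exhaustive path oracle", {
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)),
               fx_dtw_oracle(c(0, 1, 2), c(0, 2)))

  for (s in 1:10) {
    n <- with_seed(s, sample(2:6, 1))
    m <- with_seed(s + 10, sample(2:6, 1))
    x <- with_seed(s + 20, matrix(runif(n * 2), n, 2))
    y <- with_seed(s + 30, matrix(runif(m * 2), m, 2))
    expect_equal(dtw_distance(x, y), fx_dtw_oracle(x, y), tolerance = 1e-10)
    expect_equal(dtw_distance(x, y), dtw_distance(y, x))
  }
  expect_error(dtw_distance(numeric(0), 1), "non-empty")
  expect_error(dtw_distance(matrix(1, 2, 2), matrix(1, 2, 3)), "channel")
})

test_that("segmentation recovers planted kinematic regimes", {
  fx <- fx_kin_planted(n_trials = 12, seed = 1)
  seq <- segment_substates(fx$kin, c = 3, window = 10, stride = 5, seed = 1)

  expect_setequal(unique(unlist(seq$labels)),
                  c("relaxed", "sustain", "transition"))
  expect_true(all(lengths(seq$labels) == 100))

  # labelling rule: ascending mean speed maps to relaxed < sustain < transition
  cs <- seq$cluster_speed[c("relaxed", "sustain", "transition")]
  expect_true(all(diff(cs) > 0))

  expect_gte(fx_mean_ari(seq, fx$planted), 0.6)

  # per-trial speed summary recovers the ordering
  tab <- substate_speed_summary(seq, fx$kin)
  m <- tapply(tab$mean_speed, tab$substate, mean, na.rm = TRUE)
  expect_gt(m["transition"], m["sustain"])
  expect_gt(m["sustain"], m["relaxed"])
})

test_that("degenerate single-regime input is flagged", {
  # motionless trials: every window carries the same (zero) kinematics
  kin <- lapply(1:3, function(i) compute_kinematics(matrix(2, 50, 2)))
  names(kin) <- paste0("t", 1:3)
  expect_warning(seq <- segment_substates(kin, c = 2, window = 10,
                                          stride = 5, seed = 1),
                 "degenerate")
  expect_lte(seq$silhouette, 0)
})

test_that("silhouette-based c-selection finds the planted regime count", {
  fx <- fx_kin_arc(n_trials = 12, seed = 2)
  sel <- select_c(fx$kin, c_range = 2:4, seed = 2)
  expect_equal(sel$chosen_c, 3)
  expect_true(all(sel$table$silhouette >= -1 & sel$table$silhouette <= 1,
                  na.rm = TRUE))

  # two planted regimes: flat rest, then an oscillation whose period
  # matches the window stride so same-regime windows look alike
  kin2 <- with_seed(3, lapply(1:8, function(i) {
    slow <- rep(0, 50)
    fast <- 0.3 * sin(2 * pi * (0:49) / 5)
    traj <- matrix(c(slow, fast) + rnorm(100, 0, 0.002), 100, 1)
    compute_kinematics(traj)
  }))
  names(kin2) <- paste0("t", 1:8)
  # non-overlapping windows aligned with the regime boundary
  sel2 <- select_c(kin2, c_range = 2:4, window = 10, stride = 10, seed = 3)
  expect_equal(sel2$chosen_c, 2)
})

test_that("speed summaries handle degenerate trials", {
  seq1 <- structure(list(labels = list(t1 = rep("sustain", 20)),
                         cluster_speed = c(relaxed = 0, sustain = 1,
                                           transition = 2)),
                    class = "substate_sequence")
  kin1 <- list(t1 = compute_kinematics(with_seed(4, matrix(runif(40), 20, 2))))
  tab <- substate_speed_summary(seq1, kin1)
  expect_equal(tab$mean_speed[tab$substate == "sustain"],
               mean(rowMeans(abs(kin1$t1$speed))))
  expect_true(all(is.na(tab$mean_speed[tab$substate != "sustain"])))

  kin0 <- list(t1 = compute_kinematics(matrix(1, 20, 2)))
  tab0 <- substate_speed_summary(seq1, kin0)
  expect_equal(tab0$mean_speed[tab0$substate == "sustain"], 0)
})

test_that("transition entropy matches hand-computed values", {
  expect_equal(transition_entropy(rep("sustain", 10)), 0)

  # uniform cycle over all six ordered transitions reaches the maximum
  cyc <- c("relaxed", "sustain", "transition", "relaxed", "transition",
           "sustain", "relaxed")
  # 6 changes, all distinct: r->s, s->t, t->r, r->t, t->s, s->r
  expect_equal(transition_entropy(cyc), 1)

  seq5 <- c("relaxed", "transition", "sustain", "transition", "relaxed")
  expect_equal(transition_entropy(seq5), 2 / log2(6))

  expect_error(transition_entropy(c("relaxed", "excited")), "label")
})

test_that("entropy is invariant to run lengths", {
  for (s in 1:20) {
    n <- 12
    labels <- with_seed(s, sample(c("relaxed", "sustain", "transition"),
                                  n, TRUE))
    reps <- with_seed(s + 100, sample(1:4, n, TRUE))
    expect_equal(transition_entropy(rep(labels, times = reps)),
                 transition_entropy(labels))
  }
})

test_that("randomized schedules carry more entropy than fixed ones", {
  # fixed schedule: one relaxed->transition->sustain arc per trial;
  # randomized: substates revisited in random order
  diffs <- vapply(1:20, function(s) {
    fixed <- rep(c("relaxed", "transition", "sustain"), times = c(5, 5, 10))
    rand <- with_seed(s, sample(rep(c("relaxed", "sustain", "transition"),
                                    times = c(6, 7, 7))))
    transition_entropy(rand) - transition_entropy(fixed)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_true(stats::t.test(diffs)$p.value < 0.01)
})

test_that("segmentation is equivariant to trial order", {
  fx <- fx_kin_planted(n_trials = 6, seed = 5)
  seq_fwd <- segment_substates(fx$kin, c = 3, seed = 7)
  seq_rev <- segment_substates(rev(fx$kin), c = 3, seed = 7)
  expect_equal(seq_rev$labels[names(fx$kin)], seq_fwd$labels[names(fx$kin)])
})
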