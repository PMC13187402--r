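# Shared fixtures, all generated in code at test time.

# small planted-rank ground truth
fx_gt <- function(k = 3, noise_sd = 0.05, seed = 1, ...) {
  make_ground_truth(k, n_aus = 18, n_bins = 100, seed = seed,
                    noise_sd = noise_sd, ...)
}

# homogeneous mixing map (every emotion/condition cell the same gains)
fx_equal_mixing <- function(k = 3, gain = rep(1, k)) {
  mix <- list()
  for (e in c("angry", "happy", "sad"))
    for (co in c("expression_only", "emotive_speech"))
      mix[[paste(e, co, sep = ".")]] <- gain
  mix
}

# small stacked matrix from the default generator
fx_stacked <- function(k = 3, n_subjects = 4, noise_sd = 0.05, seed = 1) {
  gt <- fx_gt(k, noise_sd = noise_sd, seed = seed)
  trials <- make_dataset(gt, n_subjects = n_subjects, trials_per_cell = 1,
                         seed = seed + 1)
  list(gt = gt, sm = stack_trials(preprocess_trials(trials)))
}

# planted-regime kinematic fixture: trajectories straight from the ground
# truth's warped bases with log-normal trial gains and small additive noise
fx_kin_planted <- function(n_trials = 12, seed = 1, gain_sd = 0.15,
                           traj_noise = 0.002, gt = fx_gt(seed = seed)) {
  B <- gt$temporal_bases
  kin <- with_seed(seed + 500, lapply(seq_len(n_trials), function(i) {
    g <- exp(stats::rnorm(gt$k_true, 0, gain_sd))
    traj <- pmax(B %*% diag(g, gt$k_true) +
                   matrix(stats::rnorm(length(B), 0, traj_noise),
                          nrow(B), ncol(B)), 0)
    compute_kinematics(traj)
  }))
  names(kin) <- paste0("t", seq_len(n_trials))
  sched <- gt$substate_schedule
  planted <- character(gt$n_bins)
  for (i in seq_len(nrow(sched)))
    planted[sched$start[i]:sched$end[i]] <- sched$label[i]
  list(kin = kin, planted = planted, gt = gt)
}

# single-arc three-regime kinematic fixture: each trial has exactly one
# relaxed (flat), one transition (raised-cosine rise) and one sustain
# (gentle oscillation at the apex) segment, so the planted regime count is
# unambiguous
fx_kin_arc <- function(n_trials = 12, seed = 1, gain_sd = 0.15,
                       traj_noise = 0.002) {
  kin <- with_seed(seed + 900, lapply(seq_len(n_trials), function(i) {
    g <- exp(stats::rnorm(3, 0, gain_sd))
    u_t <- (1:30) / 30
    u_s <- (1:45) / 45
    traj <- sapply(1:3, function(c_i) {
      g[c_i] * c(rep(0, 25), (1 - cos(pi * u_t)) / 2,
                 1 - 0.15 * (1 - cos(2 * pi * u_s + 0.5 * c_i)) / 2 +
                   0.15 * (1 - cos(0.5 * c_i)) / 2)
    })
    compute_kinematics(pmax(traj + matrix(stats::rnorm(300, 0, traj_noise),
                                          100, 3), 0))
  }))
  names(kin) <- paste0("t", seq_len(n_trials))
  list(kin = kin,
       planted = rep(c("relaxed", "transition", "sustain"), c(25, 30, 45)))
}

# brute-force DTW oracle: enumerate all monotone warping paths recursively
fx_dtw_oracle <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  lc <- function(i, j) sqrt(sum((x[i, ] - y[j, ])^2))
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(lc(1, 1))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    lc(i, j) + best
  }
  rec(nrow(x), nrow(y))
}

# two-sided Fisher exact oracle: enumerate all 2x2 tables with the observed
# margins, summing the hypergeometric mass of tables no more probable than
# the observed one
fx_fisher_oracle <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  mass <- vapply(lo:hi, function(a)
    stats::dhyper(a, r1, r2, c1), numeric(1))
  obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(mass[mass <= obs * (1 + 1e-7)])
}

# mean adjusted Rand index of recovered labels against the planted schedule
fx_mean_ari <- function(seq, planted) {
  mean(vapply(seq$labels, function(l)
    mclust::adjustedRandIndex(l, planted), numeric(1)))
}
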