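test_that("multiplicative updates stay non-negative with a monotone objective", {
  for (s in 1:5) {
    M <- with_seed(s, matrix(runif(40 * 6), 40, 6))
    fit <- nmf_fit(M, k = 3, seed = s, max_iter = 200)
    expect_true(all(fit$S >= 0))
    expect_true(all(fit$T >= 0))
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * tr[1]))
  }
  expect_error(nmf_fit(matrix(c(-1, 1, 1, 1), 2, 2), 1), "negative")
  expect_error(nmf_fit(matrix(1, 4, 3), 4), "channel")
})

test_that("an exact-rank matrix is reconstructed almost perfectly", {
  gt <- make_ground_truth(3, n_aus = 12, n_bins = 50, seed = 2, noise_sd = 0)
  trials <- make_dataset(gt, 2, 1, seed = 2, n_frames = 100)
  sm <- stack_trials(preprocess_trials(trials, n_bins = 50), n_bins = 50)
  fit <- nmf_fit(sm, 3, seed = 1, max_iter = 2000, tol = 1e-9)
  expect_lt(fit$rss / sum(sm$M^2), 1e-4)

  # reconstruction error comparable to the SVD optimum (which is ~0 here);
  # multiplicative updates have a slow pointwise tail, so the elementwise
  # bound is looser than the RSS one
  sv <- svd(sm$M)
  rss_svd <- sum((sm$M - sv$u[, 1:3] %*% (sv$d[1:3] * t(sv$v[, 1:3])))^2)
  expect_lt((fit$rss - rss_svd) / sum(sm$M^2), 1e-4)
  R <- reconstruct(fit)
  expect_lt(max(abs(R - sm$M)) / diff(range(sm$M)), 5e-3)
  expect_gte(fit$evar, 0)
  expect_lte(fit$evar, 1)
})

test_that("reconstruction is bilinear in the factors", {
  M <- with_seed(9, matrix(runif(30 * 5), 30, 5))
  fit <- nmf_fit(M, 2, seed = 9, max_iter = 100)
  z <- fit; z$T <- z$T * 0
  expect_equal(reconstruct(z), matrix(0, 30, 5), ignore_attr = TRUE)

  # rescaling (T D, D^-1 S) leaves the reconstruction unchanged
  d <- c(2, 0.5)
  sc <- fit
  sc$T <- fit$T %*% diag(d)
  sc$S <- diag(1 / d) %*% fit$S
  expect_equal(reconstruct(sc), reconstruct(fit), tolerance = 1e-12)
})

test_that("consensus metrics separate structure from noise", {
  # noise-free block structure: perfectly stable co-assignment
  st <- fx_stacked(k = 3, noise_sd = 0, seed = 4)
  cm <- consensus_metrics(st$sm, 3, n_runs = 5, seed = 1, max_iter = 300)
  expect_equal(cm$cophenetic, 1.0, tolerance = 1e-9)
  expect_gt(cm$silhouette, 0.9)

  # i.i.d. noise: markedly less stable (paired comparison, 3 seeds)
  worse <- vapply(1:3, function(s) {
    Mn <- with_seed(s, matrix(runif(600 * 12), 600, 12))
    cmn <- consensus_metrics(Mn, 3, n_runs = 5, seed = s, max_iter = 150)
    cmn$cophenetic
  }, numeric(1))
  expect_true(all(worse < 0.999))
  expect_lt(mean(worse), cm$cophenetic)

  expect_error(consensus_metrics(st$sm, 25, n_runs = 2), "channel")
})

test_that("block shuffling permutes blocks but preserves values", {
  st <- fx_stacked(seed = 5)
  sm <- st$sm

  # single block: identity within each trial
  same <- block_shuffle(sm, block_len = 100, seed = 1)
  expect_equal(same$M, sm$M)

  shuf <- block_shuffle(sm, block_len = 10, seed = 1)
  expect_false(identical(shuf$M, sm$M))
  for (id in sm$trial_ids[1:3]) {
    rows <- sm$index$trial_id == id
    for (j in c(1, 9)) {
      expect_equal(sort(shuf$M[rows, j]), sort(sm$M[rows, j]))
    }
  }
  expect_error(block_shuffle(sm, 0), "block_len")
  expect_error(block_shuffle(sm, 101), "n_bins")

  # shuffling reduces smooth temporal structure (lag-1 autocorrelation)
  ac1 <- function(m, idx) {
    mean(vapply(unique(idx$trial_id), function(id) {
      rows <- idx$trial_id == id
      mean(vapply(seq_len(ncol(m)), function(j) {
        x <- m[rows, j]
        if (stats::sd(x) == 0) return(0)
        abs(stats::cor(x[-1], x[-length(x)]))
      }, numeric(1)))
    }, numeric(1)))
  }
  drops <- vapply(1:5, function(s) {
    sh <- block_shuffle(sm, block_len = 5, seed = s)
    ac1(sm$M, sm$index) - ac1(sh$M, sh$index)
  }, numeric(1))
  expect_true(all(drops > 0))
})

test_that("rank selection recovers a planted rank and rejects pure noise", {
  st2 <- fx_stacked(k = 2, seed = 6)
  sel2 <- select_k(st2$sm, k_range = 2:5, n_runs = 6, n_null = 3, seed = 1,
                   max_iter = 250)
  expect_equal(sel2$chosen_k, 2)
  expect_true(all(diff(sel2$table$rss) <= 1e-6 * sel2$table$rss[1]))
  expect_true(all(sel2$table$cophenetic >= -1 & sel2$table$cophenetic <= 1))

  # pure noise: explained variance no better than the block-shuffled null
  noise <- with_seed(8, matrix(runif(1200 * 12), 1200, 12))
  smn <- structure(list(M = noise,
                        index = data.frame(trial_id = rep(sprintf("t%02d", 1:12),
                                                          each = 100),
                                           bin = rep(1:100, 12)),
                        n_bins = 100L,
                        trial_ids = sprintf("t%02d", 1:12),
                        meta = data.frame(trial_id = sprintf("t%02d", 1:12))),
                   class = "stacked_matrix")
  seln <- select_k(smn, k_range = 2:4, n_runs = 4, n_null = 3, seed = 2,
                   max_iter = 150)
  expect_true(all(abs(seln$table$excess_evar) < 0.05))
})

test_that("NNLS projection is optimal and channel-checked", {
  st <- fx_stacked(seed = 7)
  fit <- nmf_fit(st$sm, 3, seed = 3, max_iter = 400)
  W <- nmf_project(fit, st$sm)
  expect_true(all(W >= 0))
  rss_proj <- sum((st$sm$M - W %*% fit$S)^2)
  expect_lte(rss_proj, fit$rss + 1e-6)

  # zero row -> zero weights
  z <- matrix(0, 1, 18)
  expect_equal(nmf_project(fit, z), matrix(0, 1, 3), ignore_attr = TRUE)

  # a scaled copy of one near-orthogonal S row projects onto that component
  S <- diag(3) %x% matrix(1, 1, 2)  # 3 x 6 disjoint blocks
  mock <- fit
  mock$S <- S
  mock$k <- 3L
  w <- nmf_project(mock, 5 * S[2, , drop = FALSE])
  expect_gt(w[2], 0)
  expect_equal(w[c(1, 3)], c(0, 0), ignore_attr = TRUE)

  expect_error(nmf_project(fit, matrix(1, 2, 5)), "schema")
})

test_that("trajectories reshape stacked weights and average groups", {
  T_mat <- matrix(runif(20 * 2), 20, 2)
  index <- data.frame(trial_id = rep(c("a", "b"), each = 10),
                      bin = rep(1:10, 2))
  tr <- trajectories(T_mat, index)
  expect_equal(tr$trials$a, T_mat[1:10, ], ignore_attr = TRUE)

  # averaging two identical trials returns the same curve
  T2 <- rbind(T_mat[1:10, ], T_mat[1:10, ])
  tr2 <- trajectories(T2, index, groups = c(a = "g", b = "g"))
  expect_equal(tr2$group_means$g, T_mat[1:10, ], ignore_attr = TRUE)

  expect_error(trajectories(T_mat, index[1:5, ]), "index")
})

test_that("noise-free planted loadings are recovered after matching", {
  gt <- make_ground_truth(3, n_aus = 18, n_bins = 60, seed = 10,
                          noise_sd = 0)
  trials <- make_dataset(gt, 3, 1, seed = 10, n_frames = 120)
  sm <- stack_trials(preprocess_trials(trials, n_bins = 60), n_bins = 60)
  fit <- nmf_fit(sm, 3, seed = 2, max_iter = 1500, tol = 1e-8)
  cors <- stats::cor(t(gt$S_true), t(fit$S))
  matched <- numeric(3); used <- integer(0)
  for (i in 1:3) {
    j <- which.max(replace(cors[i, ], used, -2))
    matched[i] <- cors[i, j]; used <- c(used, j)
  }
  expect_gte(min(matched), 0.9)
})
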