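# separable 3-class scores with controllable noise
fx_scores <- function(n_per_class, sd = 0.3, seed = 1) {
  centers <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  lab <- rep(c("angry", "happy", "sad"), each = n_per_class)
  X <- with_seed(seed, {
    do.call(rbind, lapply(1:3, function(i)
      matrix(rnorm(n_per_class * 3, 0, sd), n_per_class, 3) +
        matrix(centers[i, ], n_per_class, 3, byrow = TRUE)))
  })
  list(scores = X, labels = lab)
}

test_that("the stratified split reproduces the 183/61/45 arithmetic", {
  labels <- rep(c("angry", "happy", "sad"), each = 76)
  ids <- sprintf("v%03d", seq_along(labels))
  sp <- split_train_test(labels, frac = 0.8, seed = 1, ids = ids)
  expect_length(sp$train, 183)
  expect_length(sp$test, 45)
  tl <- labels[match(sp$train, ids)]
  expect_equal(unname(table(tl)), rep(61L, 3), ignore_attr = TRUE)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)

  expect_identical(sp, split_train_test(labels, 0.8, seed = 1, ids = ids))
  expect_warning(split_train_test(labels, 1.0, seed = 1, ids = ids), "empty")
  expect_error(split_train_test(c("a", "b", "b"), 0.8), "2 trials")
})

test_that("tuned forests separate separable scores and fail on shuffles", {
  d <- fx_scores(20, sd = 0.2, seed = 2)
  clf <- train_classifier(d$scores, d$labels, seed = 3, cv_folds = 5)
  expect_gte(max(clf$cv_table$balanced_accuracy), 0.95)

  # same seed, same predictions
  clf2 <- train_classifier(d$scores, d$labels, seed = 3, cv_folds = 5)
  expect_identical(stats::predict(clf$model, d$scores),
                   stats::predict(clf2$model, d$scores))

  # label-shuffled training: chance-level CV balanced accuracy
  baccs <- vapply(1:5, function(s) {
    shuffled <- with_seed(s, sample(d$labels))
    c2 <- train_classifier(d$scores, shuffled, seed = s, cv_folds = 3,
                           grid = data.frame(mtry = 1, nodesize = 5,
                                             ntree = 150))
    max(c2$cv_table$balanced_accuracy)
  }, numeric(1))
  expect_true(all(baccs >= 0.2 & baccs <= 0.5))

  expect_error(train_classifier(d$scores, rep("a", 60), seed = 1),
               "two classes")
})

test_that("evaluation fills the report with coherent metrics", {
  d <- fx_scores(20, sd = 0.2, seed = 4)
  te <- fx_scores(15, sd = 0.2, seed = 5)
  clf <- train_classifier(d$scores, d$labels, seed = 6, cv_folds = 3)
  rep <- evaluate(clf, te$scores, te$labels)

  expect_equal(sum(rep$confusion), 45)
  expect_equal(unname(rowSums(rep$confusion)), rep(15, 3), ignore_attr = TRUE)
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / 45)
  expect_equal(rep$no_information_rate, 15 / 45)
  expect_lte(rep$kappa, 1)
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))

  # perfect predictions on clean data
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$kappa, 1)
  expect_equal(unname(rep$balanced_accuracy_per_class), rep(1, 3),
               ignore_attr = TRUE)

  expect_error(evaluate(clf, te$scores, rep("fear", 45)), "label")
})

test_that("a constant classifier scores at chance with zero kappa", {
  # degenerate training: features carry no signal, forest predicts ~1 class
  lab <- rep(c("angry", "happy", "sad"), each = 10)
  X <- matrix(0, 30, 3)
  X[1:10, 1] <- 1e-9
  truth <- factor(lab)
  pred <- rep("angry", 30)
  confusion <- table(factor(lab, levels(truth)), factor(pred, levels(truth)))
  acc <- sum(diag(confusion)) / 30
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / 30^2
  expect_equal(acc, 1 / 3)
  expect_equal((acc - p_e) / (1 - p_e), 0)
})

test_that("accuracy equals the confusion trace for random confusions", {
  for (s in 1:10) {
    n <- 60
    truth <- with_seed(s, sample(c("angry", "happy", "sad"), n, TRUE))
    pred <- with_seed(s + 50, sample(c("angry", "happy", "sad"), n, TRUE))
    confusion <- table(factor(truth), factor(pred))
    expect_equal(mean(truth == pred), sum(diag(confusion)) / n)
  }
})

test_that("binomial significance is exact and monotone", {
  expect_equal(binomial_significance(10, 10, 0.5), 0.5^10)
  expect_equal(binomial_significance(0, 45, 1 / 3), 1)

  # brute-force mass summation oracle
  oracle <- sum(vapply(41:45, function(k)
    choose(45, k) * (1 / 3)^k * (2 / 3)^(45 - k), numeric(1)))
  expect_equal(binomial_significance(41, 45, 1 / 3), oracle,
               tolerance = 1e-12)

  p <- vapply(0:45, binomial_significance, numeric(1), n = 45, p0 = 1 / 3)
  expect_true(all(diff(p) < 0))
  expect_error(binomial_significance(1, 10, 1.5), "p0")
})

test_that("permutation significance brackets the binomial answer", {
  d <- fx_scores(20, sd = 0.2, seed = 7)
  te <- fx_scores(12, sd = 0.2, seed = 8)
  clf <- train_classifier(d$scores, d$labels, seed = 9, cv_folds = 3)

  # perfect separation: minimum attainable p
  p_min <- permutation_significance(clf, te$scores, te$labels,
                                    n_perm = 500, seed = 1)
  expect_equal(p_min, 1 / 501)

  # noisy case: permutation and binomial p agree within Monte-Carlo error
  te2 <- fx_scores(12, sd = 1.6, seed = 10)
  rep2 <- evaluate(clf, te2$scores, te2$labels)
  p_perm <- permutation_significance(clf, te2$scores, te2$labels,
                                     n_perm = 2000, seed = 2)
  expect_lt(abs(p_perm - rep2$p_binomial), 0.12)

  expect_error(permutation_significance(clf, te$scores, te$labels, 50), "100")
})

test_that("pairwise Fisher tests match the hypergeometric enumeration oracle", {
  confusion <- matrix(c(15, 0, 0, 0, 15, 0, 0, 0, 15), 3, 3,
                      dimnames = list(c("a", "h", "s"), c("a", "h", "s")))
  fp <- fisher_pairwise(confusion)
  expect_equal(nrow(fp), 3)
  for (i in 1:3) {
    pr <- c(match(fp$class_a[i], rownames(confusion)),
            match(fp$class_b[i], rownames(confusion)))
    tab <- confusion[pr, pr]
    expect_equal(fp$p_raw[i], fx_fisher_oracle(tab), tolerance = 1e-10)
  }
  expect_true(all(fp$p_corrected >= fp$p_raw))

  # no association
  flat <- matrix(5, 2, 2)
  expect_equal(stats::fisher.test(flat)$p.value, 1)
  uni <- matrix(5, 3, 3)
  expect_true(all(fisher_pairwise(uni)$p_corrected == 1))

  # random small tables vs oracle
  for (s in 1:20) {
    tab <- with_seed(s, matrix(rpois(4, 4), 2, 2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(stats::fisher.test(tab)$p.value, fx_fisher_oracle(tab),
                 tolerance = 1e-10)
  }

  empty <- matrix(c(3, 1, 0, 2, 4, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  w <- capture_warnings(fp0 <- fisher_pairwise(empty))
  expect_true(any(grepl("margin", w)))
  expect_true(any(fp0$p_raw == 1))
})

test_that("grouped cross-validation honours LOSO/LOPO mechanics", {
  d <- fx_scores(12, sd = 0.2, seed = 11)
  groups <- rep(1:6, times = 6)
  cv <- grouped_cross_validate(d$scores, d$labels, groups, "LOSO", seed = 1)
  expect_length(cv$per_group, 6)
  expect_equal(cv$mean_accuracy, 1)
  expect_equal(cv$baseline, 1 / 3)

  # labels independent of scores: near-chance accuracy
  accs <- vapply(1:5, function(s) {
    lab <- with_seed(s, sample(d$labels))
    grouped_cross_validate(d$scores, lab, groups, "LOPO", seed = s,
                           ntree = 100)$mean_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 1 / 3), 0.15)

  two <- grouped_cross_validate(d$scores, d$labels, rep(1:2, 18), "LOPO",
                                seed = 2)
  expect_length(two$per_group, 2)
  expect_error(grouped_cross_validate(d$scores, d$labels, rep(1, 36)),
               "2 groups")
})
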