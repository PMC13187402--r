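# Emotion classification on PCA scores: stratified splitting, random-forest
# training with small-grid CV tuning, held-out evaluation with exact
# binomial / permutation / Fisher significance machinery, and grouped
# cross-validation (leave-one-stimulus-out / leave-one-participant-out).

#' Stratified train/test split
#'
#' Splits trials into training and testing sets per class, with the per-class
#' training count equal to round-half-up of `frac` times the class size
#' (76 trials per class at `frac = 0.8` give exactly 61 train / 15 test).
#' The split happens before any model fitting so downstream stages never see
#' test data.
#'
#' @param labels Class label per trial (the stratification variable), or a
#'   list of `au_trial` objects whose `emotion` is used.
#' @param frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @param ids Optional trial identifiers; defaults to the trial ids (for
#'   `au_trial` input) or indices.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_train_test <- function(labels, frac = 0.8, seed = 1L, ids = NULL) {
  if (is.list(labels) && length(labels) > 0 && inherits(labels[[1]], "au_trial")) {
    ids <- ids %||% vapply(labels, function(tr) tr$trial_id, "")
    labels <- vapply(labels, function(tr) tr$emotion, "")
  }
  labels <- as.character(labels)
  ids <- ids %||% seq_along(labels)
  if (frac < 0 || frac > 1) stop("`frac` must be in [0, 1]", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L))
    stop("every class needs at least 2 trials to split", call. = FALSE)
  with_seed(seed, {
    train <- unlist(lapply(names(counts), function(cl) {
      members <- ids[labels == cl]
      n_tr <- round_half_up(frac * length(members))
      sample(members, n_tr)
    }), use.names = FALSE)
    test <- setdiff(ids, train)
    if (length(test) == 0L) warning("empty test set (frac = 1)")
    list(train = train, test = test)
  })
}

.balanced_accuracy <- function(truth, pred) {
  mean(vapply(unique(truth), function(cl)
    mean(pred[truth == cl] == cl), numeric(1)))
}

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Train a tuned random-forest classifier
#'
#' Fits an ensemble of seeded, bootstrap-trained decision trees with
#' per-split feature subsampling, tuning `mtry`, `nodesize` and `ntree`
#' over a small grid by stratified k-fold cross-validation maximising
#' balanced accuracy, then refits on all training data at the best setting.
#'
#' @param scores Numeric matrix of predictors (trials x dimensions).
#' @param labels Class labels.
#' @param seed Integer seed.
#' @param cv_folds Folds for the tuning CV (default 5).
#' @param grid Optional data frame with columns `mtry`, `nodesize`, `ntree`.
#' @return An object of class `fexdyn_classifier`: list with `model`
#'   (randomForest), `cv_table`, `best`, `levels`.
#' @export
train_classifier <- function(scores, labels, seed = 1L, cv_folds = 5L,
                             grid = NULL) {
  scores <- as.matrix(scores)
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("need at least two classes to train", call. = FALSE)
  if (min(table(labels)) < cv_folds)
    stop("need at least `cv_folds` samples per class", call. = FALSE)
  p <- ncol(scores)
  if (is.null(grid))
    grid <- expand.grid(
      mtry = unique(pmax(1L, c(1L, floor(sqrt(p)), p))),
      nodesize = c(1L, 5L, 10L),
      ntree = c(250L, 500L))

  with_seed(seed, {
    fold <- .stratified_folds(labels, cv_folds)
    cv_bacc <- vapply(seq_len(nrow(grid)), function(g) {
      accs <- vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        fit <- randomForest::randomForest(
          scores[tr, , drop = FALSE], labels[tr],
          mtry = min(grid$mtry[g], p), nodesize = grid$nodesize[g],
          ntree = grid$ntree[g])
        pred <- stats::predict(fit, scores[!tr, , drop = FALSE])
        .balanced_accuracy(as.character(labels[!tr]), as.character(pred))
      }, numeric(1))
      mean(accs)
    }, numeric(1))
    cv_table <- cbind(grid, balanced_accuracy = cv_bacc)
    best <- cv_table[order(-cv_table$balanced_accuracy,
                           cv_table$ntree, cv_table$mtry)[1], ]
    model <- randomForest::randomForest(
      scores, labels, mtry = min(best$mtry, p),
      nodesize = best$nodesize, ntree = best$ntree)
    structure(list(model = model, cv_table = cv_table, best = best,
                   levels = levels(labels), seed = as.integer(seed)),
              class = "fexdyn_classifier")
  })
}

#' @export
print.fexdyn_classifier <- function(x, ...) {
  cat(sprintf("Random-forest emotion classifier (%s); best CV balanced accuracy %.3f\n",
              paste(x$levels, collapse = "/"),
              max(x$cv_table$balanced_accuracy)))
  invisible(x)
}

# one-vs-rest AUC from class-probability estimates (Mann-Whitney statistic)
.auc_ovr <- function(truth, prob_class) {
  pos <- prob_class[truth]
  neg <- prob_class[!truth]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Evaluate a classifier on held-out data
#'
#' Computes the full held-out report: confusion matrix (rows = truth),
#' accuracy, overall and per-class balanced accuracy, Cohen's kappa,
#' one-vs-rest AUC from class-probability (vote-fraction) estimates, the
#' no-information rate, an exact binomial p-value against it, and
#' Bonferroni-corrected pairwise Fisher exact tests on the confusion matrix.
#'
#' @param clf A `fexdyn_classifier`.
#' @param test_scores Predictor matrix for the test trials.
#' @param test_labels True labels.
#' @return An object of class `classifier_report`.
#' @export
evaluate <- function(clf, test_scores, test_labels) {
  stopifnot(inherits(clf, "fexdyn_classifier"))
  test_scores <- as.matrix(test_scores)
  if (nrow(test_scores) == 0L) stop("test set is empty", call. = FALSE)
  truth <- as.character(test_labels)
  if (!all(truth %in% clf$levels))
    stop("label error: test set contains labels unseen in training",
         call. = FALSE)
  lev <- clf$levels
  pred <- as.character(stats::predict(clf$model, test_scores))
  prob <- stats::predict(clf$model, test_scores, type = "prob")

  confusion <- table(factor(truth, lev), factor(pred, lev))
  n <- length(truth)
  accuracy <- sum(diag(confusion)) / n

  recall <- vapply(lev, function(cl)
    if (sum(truth == cl) == 0) NA_real_ else mean(pred[truth == cl] == cl),
    numeric(1))
  spec <- vapply(lev, function(cl)
    if (sum(truth != cl) == 0) NA_real_ else mean(pred[truth != cl] != cl),
    numeric(1))
  bal_per_class <- (recall + spec) / 2
  balanced_accuracy <- mean(recall, na.rm = TRUE)

  p_e <- sum(vapply(lev, function(cl) mean(truth == cl) * mean(pred == cl),
                    numeric(1)))
  kappa <- if (p_e == 1) 1 else (accuracy - p_e) / (1 - p_e)

  auc <- vapply(lev, function(cl) .auc_ovr(truth == cl, prob[, cl]), numeric(1))
  nir <- max(table(factor(truth, lev))) / n
  p_binom <- binomial_significance(sum(pred == truth), n, nir)
  fisher <- fisher_pairwise(confusion)

  structure(list(confusion = confusion, accuracy = accuracy,
                 balanced_accuracy = balanced_accuracy,
                 balanced_accuracy_per_class = bal_per_class,
                 recall = recall, kappa = kappa, auc = auc,
                 mean_auc = mean(auc, na.rm = TRUE),
                 no_information_rate = nir, p_binomial = p_binom,
                 fisher_pairwise = fisher, predictions = pred,
                 probabilities = prob),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("ACC = %.2f [Bal.Acc. = %.2f], Cohen's kappa = %.2f, mean AUC = %.2f\n",
              x$accuracy, x$balanced_accuracy, x$kappa, x$mean_auc))
  cat(sprintf("no-information rate = %.3f, binomial p = %.3g\n",
              x$no_information_rate, x$p_binomial))
  print(x$confusion)
  invisible(x)
}

#' Exact binomial significance of a classification accuracy
#'
#' Upper-tail exact binomial probability `P(X >= n_correct | n, p0)` of
#' observing at least the achieved number of correct test predictions under
#' chance-level accuracy `p0` (the no-information rate).
#'
#' @param n_correct Number of correct predictions.
#' @param n Test-set size.
#' @param p0 Chance accuracy, in (0, 1).
#' @return The p-value.
#' @export
#' @examples
#' binomial_significance(10, 10, 0.5)  # (1/2)^10
binomial_significance <- function(n_correct, n, p0) {
  if (p0 <= 0 || p0 >= 1) stop("`p0` must be in (0, 1)", call. = FALSE)
  if (n_correct < 0 || n_correct > n)
    stop("`n_correct` must be in [0, n]", call. = FALSE)
  stats::pbinom(n_correct - 1, n, p0, lower.tail = FALSE)
}

#' Permutation significance of a classification accuracy
#'
#' Compares the observed test accuracy against accuracies obtained by
#' shuffling the test labels, using the add-one estimator
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`.
#'
#' @param clf A `fexdyn_classifier`.
#' @param test_scores,test_labels Held-out data.
#' @param n_perm Number of label shuffles (default 1000, minimum 100).
#' @param seed Integer seed.
#' @return The permutation p-value.
#' @export
permutation_significance <- function(clf, test_scores, test_labels,
                                     n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("`n_perm` must be at least 100", call. = FALSE)
  truth <- as.character(test_labels)
  pred <- as.character(stats::predict(clf$model, as.matrix(test_scores)))
  obs <- mean(pred == truth)
  with_seed(seed, {
    null_acc <- vapply(seq_len(n_perm), function(i)
      mean(pred == sample(truth)), numeric(1))
    (1 + sum(null_acc >= obs)) / (n_perm + 1)
  })
}

#' Pairwise Fisher exact tests on a confusion matrix
#'
#' For every unordered class pair, restricts the confusion matrix to the
#' 2x2 sub-table of trials truly in either class and predicted as either
#' class, runs a two-sided Fisher exact test, and Bonferroni-corrects
#' across the pairs.
#'
#' @param confusion Square confusion matrix of non-negative counts
#'   (rows = truth, cols = predicted, same class order).
#' @return Data frame with `class_a`, `class_b`, `p_raw`, `p_corrected`.
#' @export
fisher_pairwise <- function(confusion) {
  confusion <- as.matrix(confusion)
  lev <- rownames(confusion) %||% paste0("class", seq_len(nrow(confusion)))
  pairs <- utils::combn(seq_along(lev), 2)
  res <- apply(pairs, 2, function(pr) {
    tab <- confusion[pr, pr]
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning("empty margin in 2x2 sub-table; p set to 1")
      1
    } else stats::fisher.test(tab)$p.value
  })
  data.frame(class_a = lev[pairs[1, ]], class_b = lev[pairs[2, ]],
             p_raw = res, p_corrected = pmin(1, res * ncol(pairs)),
             stringsAsFactors = FALSE)
}

#' Grouped cross-validation
#'
#' Leave-one-group-out evaluation: iteratively holds out every group
#' (stimulus for LOSO, participant for LOPO), trains on the remainder and
#' predicts the held-out group. The empirical-chance baseline is the
#' majority-class rate of the full label set.
#'
#' @param scores Predictor matrix.
#' @param labels Class labels.
#' @param groups Group id per row (>= 2 distinct groups).
#' @param scheme `"LOSO"` or `"LOPO"` (label only; the mechanics are the
#'   grouping).
#' @param seed Integer seed.
#' @param ntree Trees per forest (no inner tuning).
#' @return List with `per_group` accuracies, `mean_accuracy`, `baseline`,
#'   `scheme`.
#' @export
grouped_cross_validate <- function(scores, labels, groups,
                                   scheme = c("LOSO", "LOPO"), seed = 1L,
                                   ntree = 250L) {
  scheme <- match.arg(scheme)
  scores <- as.matrix(scores)
  labels <- factor(labels)
  groups <- as.character(groups)
  gs <- unique(groups)
  if (length(gs) < 2L) stop("need at least 2 groups", call. = FALSE)
  with_seed(seed, {
    acc <- vapply(gs, function(g) {
      tr <- groups != g
      fit <- randomForest::randomForest(scores[tr, , drop = FALSE],
                                        droplevels(labels[tr]), ntree = ntree)
      pred <- as.character(stats::predict(fit, scores[!tr, , drop = FALSE]))
      mean(pred == as.character(labels[!tr]))
    }, numeric(1))
    list(per_group = acc, mean_accuracy = mean(acc),
         baseline = max(table(labels)) / length(labels), scheme = scheme)
  })
}
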