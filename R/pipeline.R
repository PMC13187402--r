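# End-to-end orchestration: structured configuration, per-stage derived
# seeds, artifact logging, and the run_pipeline driver enforcing the
# train/test firewall (split before any fitting; every later stage fits on
# training trials only and applies to test trials).

#' Build a pipeline configuration
#'
#' Nested key-value configuration for [run_pipeline()]. Every stochastic
#' stage's seed is derived from the single master seed with
#' [derive_seed()], so reruns with the same master seed are reproducible
#' and adding a stage never perturbs the others.
#'
#' @param output_dir Directory for run artifacts.
#' @param manifest Optional path to a dataset manifest TSV; when `NULL` a
#'   synthetic dataset is generated.
#' @param synthetic List of generator settings (`k_true`, `n_aus`,
#'   `n_bins`, `n_subjects`, `trials_per_cell`, `noise_sd`, `n_frames`).
#' @param preprocessing List: `window` (smoothing frames), `n_bins`,
#'   `confidence_threshold`.
#' @param decomposition List: `k_range`, `n_runs`, `n_null`, `block_len`,
#'   `max_iter`.
#' @param features List: `n_pca` (`NULL` = number of NMF components).
#' @param classification List: `frac`, `cv_folds`, `n_perm`.
#' @param substates List: `c`, `window`, `stride`, `max_trials` (cap on
#'   trials entering the DTW clustering).
#' @param seed Master seed.
#' @return An object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(output_dir = tempfile("fexdyn_run_"),
                            manifest = NULL,
                            synthetic = list(),
                            preprocessing = list(),
                            decomposition = list(),
                            features = list(),
                            classification = list(),
                            substates = list(),
                            seed = 1L) {
  merge_defaults <- function(user, defaults) {
    for (nm in names(user)) defaults[[nm]] <- user[[nm]]
    defaults
  }
  cfg <- list(
    paths = list(output_dir = output_dir, manifest = manifest),
    synthetic = merge_defaults(synthetic, list(
      k_true = 3L, n_aus = 18L, n_bins = 100L, n_subjects = 6L,
      trials_per_cell = 2L, noise_sd = 0.05, n_frames = 240L,
      mixing_scale = 1)),
    preprocessing = merge_defaults(preprocessing, list(
      window = 3L, n_bins = 100L, confidence_threshold = 0.90)),
    decomposition = merge_defaults(decomposition, list(
      k_range = 2:6, n_runs = 10L, n_null = 5L, block_len = 10L,
      max_iter = 500L)),
    features = merge_defaults(features, list(n_pca = NULL)),
    classification = merge_defaults(classification, list(
      frac = 0.8, cv_folds = 5L, n_perm = 1000L)),
    substates = merge_defaults(substates, list(
      c = 3L, window = 10L, stride = 5L, max_trials = 24L)),
    seed = as.integer(seed))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("fexdyn pipeline configuration (master seed", x$seed, ")\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

.stage_log <- function(dir, stage, msg) {
  line <- sprintf("[%s] %-12s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE)
}

.write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, preprocessing, the stratified split,
#' decomposition with rank selection on the training matrix, NNLS
#' projection of the test matrix, feature extraction, train-fitted PCA,
#' classifier training and held-out evaluation, substate segmentation, and
#' the mixed-model characterisation, writing every intermediate artifact
#' plus a JSON run manifest and a plain-text report into the output
#' directory. Test trials never influence rank selection, the NMF fit, the
#' PCA scaler or the classifier.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the run directory and the main stage
#'   results (`selection`, `model`, `report`, `substates`, `lmm`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir <- config$paths$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- lapply(stats::setNames(nm = c(
    "simulate", "split", "decompose", "classify", "permute", "substates")),
    function(s) derive_seed(config$seed, s))
  jsonlite::write_json(list(package = "fexdyn",
                            version = as.character(utils::packageVersion("fexdyn")),
                            master_seed = config$seed, stage_seeds = seeds,
                            config = unclass(config)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  # 1. simulate or ingest ----------------------------------------------
  if (is.null(config$paths$manifest)) {
    sy <- config$synthetic
    gt <- make_ground_truth(sy$k_true, sy$n_aus, sy$n_bins,
                            seed = seeds$simulate, noise_sd = sy$noise_sd,
                            mixing_scale = sy$mixing_scale)
    trials <- make_dataset(gt, sy$n_subjects, sy$trials_per_cell,
                           seed = seeds$simulate, n_frames = sy$n_frames)
    .stage_log(dir, "simulate", sprintf("%d synthetic trials (k_true = %d)",
                                        length(trials), sy$k_true))
  } else {
    trials <- read_dataset(config$paths$manifest)
    gt <- NULL
    .stage_log(dir, "ingest", sprintf("%d trials from %s", length(trials),
                                      config$paths$manifest))
  }

  # 2. preprocess -------------------------------------------------------
  pp <- config$preprocessing
  trials <- filter_by_confidence(trials, pp$confidence_threshold)
  trials <- preprocess_trials(trials, window = pp$window, n_bins = pp$n_bins)
  sm <- stack_trials(trials, n_bins = pp$n_bins)
  .write_tsv(cbind(sm$index, sm$M), file.path(dir, "stacked_matrix.tsv"))
  .stage_log(dir, "preprocess", sprintf("stacked matrix %d x %d",
                                        nrow(sm$M), ncol(sm$M)))

  # 3. split (before any fitting) --------------------------------------
  emo <- stats::setNames(sm$meta$emotion, sm$meta$trial_id)
  split <- split_train_test(emo, frac = config$classification$frac,
                            seed = seeds$split, ids = sm$meta$trial_id)
  .write_tsv(data.frame(trial_id = c(split$train, split$test),
                        role = rep(c("train", "test"),
                                   c(length(split$train), length(split$test)))),
             file.path(dir, "split.tsv"))
  sm_train <- subset_stacked(sm, split$train)
  sm_test <- subset_stacked(sm, split$test)
  .stage_log(dir, "split", sprintf("%d train / %d test trials",
                                   length(split$train), length(split$test)))

  # 4. decompose on training data only ---------------------------------
  dc <- config$decomposition
  selection <- select_k(sm_train, k_range = dc$k_range, n_runs = dc$n_runs,
                        n_null = dc$n_null, block_len = dc$block_len,
                        seed = seeds$decompose, max_iter = dc$max_iter)
  k <- selection$chosen_k
  .write_tsv(selection$table, file.path(dir, "k_selection.tsv"))
  model <- nmf_fit(sm_train, k, seed = seeds$decompose,
                   max_iter = 2000L)
  .write_tsv(model$S, file.path(dir, "nmf_S.tsv"))
  .write_tsv(model$T, file.path(dir, "nmf_T_train.tsv"))
  .stage_log(dir, "decompose", sprintf("chosen k = %d, evar = %.3f",
                                       k, model$evar))

  # 5. project the test set --------------------------------------------
  T_test <- nmf_project(model, sm_test)
  .write_tsv(T_test, file.path(dir, "nmf_T_test.tsv"))
  .stage_log(dir, "project", sprintf("projected %d test rows", nrow(T_test)))

  # 6. features + train-fitted PCA -------------------------------------
  traj_train <- trajectories(model$T, sm_train$index)$trials
  traj_test <- trajectories(T_test, sm_test$index)$trials
  ft_train <- feature_table(traj_train)
  ft_test <- feature_table(traj_test)
  n_pca <- config$features$n_pca %||% k
  pca <- fit_feature_pca(ft_train, n_pca)
  sc_train <- apply_feature_pca(pca, ft_train)
  sc_test <- apply_feature_pca(pca, ft_test)
  .write_tsv(cbind(trial_id = rownames(ft_train), as.data.frame(sc_train)),
             file.path(dir, "pca_scores_train.tsv"))
  .write_tsv(cbind(trial_id = rownames(ft_test), as.data.frame(sc_test)),
             file.path(dir, "pca_scores_test.tsv"))
  .stage_log(dir, "features", sprintf("%d features -> %d PCs (%.0f%% var)",
                                      ncol(ft_train), n_pca,
                                      100 * sum(pca$var_explained)))

  # 7. classify ---------------------------------------------------------
  lab_train <- emo[rownames(sc_train)]
  lab_test <- emo[rownames(sc_test)]
  clf <- train_classifier(sc_train, lab_train, seed = seeds$classify,
                          cv_folds = config$classification$cv_folds)
  report <- evaluate(clf, sc_test, lab_test)
  report$p_permutation <- permutation_significance(
    clf, sc_test, lab_test, n_perm = config$classification$n_perm,
    seed = seeds$permute)
  .write_tsv(as.data.frame.matrix(report$confusion),
             file.path(dir, "confusion.tsv"))
  .stage_log(dir, "classify",
             sprintf("ACC = %.2f, Bal.Acc. = %.2f, kappa = %.2f, p = %.3g",
                     report$accuracy, report$balanced_accuracy, report$kappa,
                     report$p_binomial))

  # 8. substates --------------------------------------------------------
  sb <- config$substates
  all_traj <- c(traj_train, traj_test)
  sub_ids <- names(all_traj)
  if (length(sub_ids) > sb$max_trials)
    sub_ids <- with_seed(seeds$substates,
                         sort(sample(sub_ids, sb$max_trials)))
  kin <- lapply(all_traj[sub_ids], compute_kinematics)
  seq <- segment_substates(kin, c = sb$c, window = sb$window,
                           stride = sb$stride, seed = seeds$substates)
  speed_tab <- substate_speed_summary(seq, kin)
  ent <- transition_entropy(seq)
  .write_tsv(speed_tab, file.path(dir, "substate_speed.tsv"))
  .write_tsv(data.frame(trial = names(ent), entropy = ent),
             file.path(dir, "substate_entropy.tsv"))
  .stage_log(dir, "substates",
             sprintf("%d trials segmented; cluster speeds %s",
                     length(sub_ids),
                     paste(sprintf("%s = %.3g", names(seq$cluster_speed),
                                   seq$cluster_speed), collapse = ", ")))

  # 9. stats -------------------------------------------------------------
  meta <- sm$meta[match(speed_tab$trial, sm$meta$trial_id), ]
  long <- data.frame(trial = speed_tab$trial, subject = meta$subject_id,
                     emotion = meta$emotion, condition = meta$condition,
                     substate = speed_tab$substate,
                     value = speed_tab$mean_speed)
  long <- long[is.finite(long$value), ]
  lmm <- tryCatch(
    withCallingHandlers(fit_substate_lmm(long, "speed"),
                        warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (!is.null(lmm)) {
    .write_tsv(cbind(effect = rownames(lmm$anova), lmm$anova),
               file.path(dir, "lmm_speed_anova.tsv"))
    .stage_log(dir, "stats", sprintf(
      "speed LMM: random structure %s, marginal R2 = %.2f",
      lmm$random_structure, lmm$r2["marginal"]))
  } else .stage_log(dir, "stats", "speed LMM skipped (degenerate input)")

  # 10. report ----------------------------------------------------------
  summary <- list(
    n_trials = length(trials), chosen_k = k, evar = model$evar,
    accuracy = report$accuracy, balanced_accuracy = report$balanced_accuracy,
    kappa = report$kappa, no_information_rate = report$no_information_rate,
    p_binomial = report$p_binomial, p_permutation = report$p_permutation,
    cluster_speed = as.list(seq$cluster_speed),
    mean_entropy = mean(ent),
    lmm_marginal_r2 = if (!is.null(lmm)) unname(lmm$r2["marginal"]) else NA,
    lmm_conditional_r2 = if (!is.null(lmm)) unname(lmm$r2["conditional"]) else NA)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .stage_log(dir, "report", "run complete")

  invisible(list(dir = dir, ground_truth = gt, selection = selection,
                 model = model, report = report, substates = seq,
                 entropy = ent, lmm = lmm, summary = summary,
                 split = split))
}
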