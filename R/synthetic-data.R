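# Synthetic AU-trial generator: planted low-rank spatiotemporal structure,
# emotion-specific component mixing and kinematic substate schedules. The
# ground truth it returns is the oracle for every parameter-recovery test.

#' Construct the ground truth of a synthetic AU dataset
#'
#' Builds the generative structure the analysis pipeline assumes: a
#' block-structured non-negative spatial loading matrix over AU channels
#' (each component dominated by a disjoint subset of AUs with small
#' cross-loadings), smooth unit-peak temporal bases (one inverted-U, one
#' shifted inverted-U, the remainder bimodal), per-(emotion, condition)
#' non-negative mixing gains, and an ordered substate schedule of
#' relaxed / transition / sustain segments with distinct speed scales.
#'
#' @param k_true Number of planted spatiotemporal components.
#' @param n_aus Number of AU channels (default 18).
#' @param n_bins Number of time bins the temporal bases are defined on
#'   (default 100).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   applied at frame level (series truncated at 0 afterwards).
#' @param mixing Optional named list mapping `"<emotion>.<condition>"` to a
#'   non-negative gain vector of length `k_true`; a separable default is
#'   generated when `NULL`.
#' @param mixing_scale Multiplier on the gap between emphasised and
#'   background mixing gains; larger values make emotions easier to separate.
#' @return An object of class `fexdyn_ground_truth` with elements
#'   `S_true` (`k_true` x `n_aus`), `temporal_bases` (`n_bins` x `k_true`,
#'   unit peak), `mixing`, `substate_schedule` (data frame with columns
#'   `label`, `start`, `end`, `speed`), `phase` (per-bin warped phase),
#'   `noise_sd`, `seed`.
#' @export
#' @examples
#' gt <- make_ground_truth(3, n_aus = 18, n_bins = 100, seed = 1)
#' dim(gt$S_true)
make_ground_truth <- function(k_true, n_aus = 18L, n_bins = 100L, seed = 1L,
                              noise_sd = 0.05, mixing = NULL,
                              mixing_scale = 1) {
  assert_count(k_true, "k_true")
  assert_count(n_aus, "n_aus")
  assert_count(n_bins, "n_bins")
  if (n_aus < k_true) stop("`n_aus` must be at least `k_true`", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)

  with_seed(seed, {
    au_names <- sprintf("AU%02d_r", seq_len(n_aus))

    # block-structured loadings: contiguous AU blocks per component,
    # within-block loadings near 1, cross-loadings near 0
    block <- (seq_len(n_aus) - 1L) %/% ceiling(n_aus / k_true) + 1L
    block <- pmin(block, k_true)
    S_true <- matrix(stats::runif(k_true * n_aus, 0, 0.05), k_true, n_aus,
                     dimnames = list(paste0("C", seq_len(k_true)), au_names))
    for (a in seq_len(n_aus))
      S_true[block[a], a] <- stats::runif(1, 0.8, 1.2)

    # substate schedule: onset/offset transitions around a sustain plateau,
    # flanked by relaxed rest. Speed scales: transition > sustain > relaxed.
    seg_frac <- c(0.20, 0.20, 0.35, 0.15, 0.10)
    lab      <- c("relaxed", "transition", "sustain", "transition", "relaxed")
    speed    <- c(0.2, 2.5, 0.7, 2.5, 0.2)
    ends   <- round(cumsum(seg_frac) * n_bins)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    keep   <- ends >= starts
    schedule <- data.frame(label = lab[keep], start = starts[keep],
                           end = ends[keep], speed = speed[keep],
                           stringsAsFactors = FALSE)

    # warped phase: piecewise-linear in bin index with slope proportional to
    # the segment speed scale, normalised to [0, 1]
    rate <- numeric(n_bins)
    for (i in seq_len(nrow(schedule)))
      rate[schedule$start[i]:schedule$end[i]] <- schedule$speed[i]
    phase <- cumsum(rate)
    phase <- (phase - phase[1]) / (phase[n_bins] - phase[1])

    # temporal bases, unit peak, evaluated on the warped phase so that
    # bin-wise derivative magnitude follows the segment speed scales
    # widths chosen so the rising/falling flanks span the transition phase
    # intervals, the unimodal tops sit inside the sustain interval, and the
    # bimodal dip is traversed during sustain (movement while "holding")
    gauss <- function(u, mu, sd) exp(-0.5 * ((u - mu) / sd)^2)
    bases <- matrix(0, n_bins, k_true)
    for (c_i in seq_len(k_true)) {
      b <- if (c_i == 1L) gauss(phase, 0.55, 0.22)
      else if (c_i == 2L) gauss(phase, 0.45, 0.20)
      else gauss(phase, 0.45, 0.08) +
        0.9 * gauss(phase, 0.68, 0.08)
      bases[, c_i] <- b / max(b)
    }
    colnames(bases) <- paste0("C", seq_len(k_true))

    if (is.null(mixing)) {
      mixing <- list()
      for (e_i in seq_along(EMOTIONS)) {
        g <- rep(0.3, k_true)
        g[(e_i - 1L) %% k_true + 1L] <- 0.3 + 1.7 * mixing_scale
        if (k_true > 1L)
          g[e_i %% k_true + 1L] <- 0.3 + 0.8 * mixing_scale
        for (co in CONDITIONS) {
          gc <- if (co == "emotive_speech") g * 1.1 else g
          mixing[[paste(EMOTIONS[e_i], co, sep = ".")]] <- gc
        }
      }
    } else {
      bad <- vapply(mixing, function(g)
        length(g) != k_true || any(g < 0), logical(1))
      if (any(bad))
        stop("mixing gains must be non-negative vectors of length k_true",
             call. = FALSE)
    }

    structure(list(k_true = as.integer(k_true), n_aus = as.integer(n_aus),
                   n_bins = as.integer(n_bins), S_true = S_true,
                   temporal_bases = bases, phase = phase, mixing = mixing,
                   substate_schedule = schedule, noise_sd = noise_sd,
                   seed = as.integer(seed), au_names = au_names),
              class = "fexdyn_ground_truth")
  })
}

#' @export
print.fexdyn_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic AU ground truth: %d components, %d AUs, %d bins\n",
              x$k_true, x$n_aus, x$n_bins))
  cat(sprintf("  noise_sd = %g, %d mixing cells, schedule: %s\n",
              x$noise_sd, length(x$mixing),
              paste(x$substate_schedule$label, collapse = " > ")))
  invisible(x)
}

# bin-level noise-free trial series implied by a gain vector (n_bins x A)
.gt_bin_series <- function(gt, gain) {
  (gt$temporal_bases %*% diag(gain, nrow = gt$k_true)) %*% gt$S_true
}

#' Simulate a single AU trial
#'
#' Generates one trial's frame-level AU series as the mixture
#' `sum_c gain_c * base_c(phase) (x) S_true[c, ]`, where the phase warp
#' encodes the substate schedule, plus additive Gaussian noise truncated at
#' zero. Frame-level series are produced by linear interpolation of the
#' bin-level bases onto `n_frames` points.
#'
#' @param gt A `fexdyn_ground_truth`.
#' @param emotion,condition Labels present in `gt$mixing`.
#' @param subject_id Subject identifier stored in the trial.
#' @param n_frames Number of video frames (default 240).
#' @param seed Integer seed for the noise realisation.
#' @param gain Optional gain-vector override (e.g. subject-perturbed).
#' @param session Session number stored in the trial metadata.
#' @param frame_rate Nominal frame rate in Hz (metadata only).
#' @return An `au_trial` (see [read_openface_csv()] for the structure).
#' @export
simulate_trial <- function(gt, emotion, condition, subject_id = "s01",
                           n_frames = 240L, seed = 1L, gain = NULL,
                           session = 1L, frame_rate = 30) {
  stopifnot(inherits(gt, "fexdyn_ground_truth"))
  assert_count(n_frames, "n_frames")
  key <- paste(emotion, condition, sep = ".")
  if (is.null(gt$mixing[[key]]))
    stop(sprintf("unknown emotion/condition cell '%s'", key), call. = FALSE)
  gain <- gain %||% gt$mixing[[key]]

  with_seed(seed, {
    bins <- .gt_bin_series(gt, gain)
    # frame grid by linear interpolation of the bin-level series
    xb <- seq(0, 1, length.out = gt$n_bins)
    xf <- seq(0, 1, length.out = n_frames)
    series <- apply(bins, 2, function(col) stats::approx(xb, col, xout = xf)$y)
    series <- matrix(series, n_frames, gt$n_aus,
                     dimnames = list(NULL, gt$au_names))
    if (gt$noise_sd > 0)
      series <- series + matrix(stats::rnorm(length(series), 0, gt$noise_sd),
                                nrow(series), ncol(series))
    series[series < 0] <- 0
    confidence <- pmin(1, pmax(0, 0.97 + stats::rnorm(n_frames, 0, 0.01)))
    au_trial(
      trial_id = sprintf("%s_%s_%s_s%d", subject_id, emotion, condition, session),
      subject_id = subject_id, emotion = emotion, condition = condition,
      session = as.integer(session), series = series,
      frame_rate = frame_rate, confidence = confidence,
      success = rep(1L, n_frames))
  })
}

#' Simulate a balanced factorial AU dataset
#'
#' Crosses every emotion and condition in `gt$mixing` with `n_subjects`
#' subjects and `trials_per_cell` repeats, applying a log-normal
#' multiplicative subject-level perturbation to the mixing gains to emulate
#' between-subject idiosyncrasy.
#'
#' @param gt A `fexdyn_ground_truth`.
#' @param n_subjects Number of subjects (>= 1).
#' @param trials_per_cell Trials per emotion x condition x subject cell.
#' @param seed Integer seed.
#' @param subject_sd SD of the log-normal subject gain perturbation.
#' @param n_frames Frames per trial.
#' @return List of `au_trial` objects, balanced across cells.
#' @export
#' @examples
#' gt <- make_ground_truth(3, seed = 1)
#' trials <- make_dataset(gt, n_subjects = 2, trials_per_cell = 1, seed = 1)
#' length(trials)  # 2 subjects x 3 emotions x 2 conditions
make_dataset <- function(gt, n_subjects, trials_per_cell = 1L, seed = 1L,
                         subject_sd = 0.15, n_frames = 240L) {
  stopifnot(inherits(gt, "fexdyn_ground_truth"))
  assert_count(n_subjects, "n_subjects")
  assert_count(trials_per_cell, "trials_per_cell")

  cells <- strsplit(names(gt$mixing), ".", fixed = TRUE)
  emotions <- unique(vapply(cells, `[`, "", 1L))
  conditions <- unique(vapply(cells, `[`, "", 2L))

  with_seed(seed, {
    subj_gain <- lapply(seq_len(n_subjects), function(s)
      exp(stats::rnorm(gt$k_true, 0, subject_sd)))
    trial_seeds <- sample.int(2^30, n_subjects * length(emotions) *
                                length(conditions) * trials_per_cell)
    trials <- list(); i <- 0L
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("s%02d", s)
      for (e in emotions) for (co in conditions)
        for (r in seq_len(trials_per_cell)) {
          i <- i + 1L
          g <- gt$mixing[[paste(e, co, sep = ".")]] * subj_gain[[s]]
          tr <- simulate_trial(gt, e, co, subject_id = sid,
                               n_frames = n_frames, seed = trial_seeds[i],
                               gain = g, session = ((r - 1L) %% 2L) + 1L)
          tr$trial_id <- sprintf("%s_%s_%s_r%02d", sid, e, co, r)
          trials[[i]] <- tr
        }
    }
    trials
  })
}

#' Write a trial as an OpenFace-dialect CSV
#'
#' Emits the column layout produced by OpenFace's AU pipeline: `frame`,
#' `timestamp`, `confidence`, `success`, then one `AU<nn>_r` intensity
#' column per channel. Round-trips through [read_openface_csv()].
#'
#' @param trial An `au_trial` with at least one frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_openface_csv <- function(trial, path) {
  stopifnot(inherits(trial, "au_trial"))
  if (nrow(trial$series) < 1L)
    stop("trial has no frames", call. = FALSE)
  n <- nrow(trial$series)
  df <- data.frame(frame = seq_len(n),
                   timestamp = round((seq_len(n) - 1) / trial$frame_rate, 6),
                   confidence = round(trial$confidence, 6),
                   success = trial$success)
  aus <- as.data.frame(round(trial$series, 6))
  names(aus) <- colnames(trial$series)
  utils::write.csv(cbind(df, aus), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a dataset manifest
#'
#' Tab-separated manifest (`trial_id`, `subject_id`, `emotion`, `condition`,
#' `session`, `path`) alongside one OpenFace-dialect CSV per trial.
#'
#' @param trials List of `au_trial` objects.
#' @param dir Output directory (created if absent).
#' @return Path of the manifest TSV, invisibly.
#' @export
write_dataset <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(trials, function(tr) {
    p <- file.path(dir, paste0(tr$trial_id, ".csv"))
    write_openface_csv(tr, p)
    data.frame(trial_id = tr$trial_id, subject_id = tr$subject_id,
               emotion = tr$emotion, condition = tr$condition,
               session = tr$session, path = p, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(mp)
}
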