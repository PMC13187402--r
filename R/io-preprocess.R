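# Reading OpenFace-dialect AU timeseries and preparing them for
# decomposition: confidence filtering, moving-average smoothing, fixed-length
# temporal binning, and stacking into the NMF input matrix.

#' Construct an AU trial
#'
#' The pipeline's atomic input: one video's per-frame AU intensity series
#' (OpenFace 0-5 scale) with tracking metadata.
#'
#' @param trial_id,subject_id Identifiers.
#' @param emotion,condition Labels.
#' @param session Session number.
#' @param series Numeric `n_frames x A` matrix of non-negative AU intensities
#'   with `AU<nn>_r` column names.
#' @param frame_rate Frames per second.
#' @param confidence Per-frame tracking confidence in \[0, 1\].
#' @param success Per-frame tracking success flag (0/1).
#' @return An object of class `au_trial`.
#' @export
au_trial <- function(trial_id, subject_id = NA_character_,
                     emotion = NA_character_, condition = NA_character_,
                     session = 1L, series, frame_rate = 30,
                     confidence = rep(1, nrow(series)),
                     success = rep(1L, nrow(series))) {
  series <- as.matrix(series)
  if (any(series < 0)) stop("AU intensities must be non-negative", call. = FALSE)
  if (length(confidence) != nrow(series) || length(success) != nrow(series))
    stop("confidence/success length must match frame count", call. = FALSE)
  structure(list(trial_id = trial_id, subject_id = subject_id,
                 emotion = emotion, condition = condition,
                 session = as.integer(session), series = series,
                 frame_rate = frame_rate, confidence = as.numeric(confidence),
                 success = as.integer(success)),
            class = "au_trial")
}

#' @export
print.au_trial <- function(x, ...) {
  cat(sprintf("AU trial '%s': %d frames x %d AUs (%s, %s), mean confidence %.2f\n",
              x$trial_id, nrow(x$series), ncol(x$series),
              x$emotion, x$condition, mean(x$confidence)))
  invisible(x)
}

#' Read an OpenFace-dialect AU CSV
#'
#' Retains only the AU intensity (`_r`) columns, ordered by ascending AU
#' number, and attaches per-frame confidence and success. Frames flagged
#' `success = 0` are linearly interpolated from their neighbours so the
#' series has no missing frames.
#'
#' @param path CSV file path.
#' @param trial_id,subject_id,emotion,condition,session Optional metadata;
#'   `trial_id` defaults to the file name.
#' @return An `au_trial`.
#' @export
read_openface_csv <- function(path, trial_id = NULL,
                              subject_id = NA_character_,
                              emotion = NA_character_,
                              condition = NA_character_, session = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
  names(df) <- trimws(names(df))
  au_cols <- grep("^AU[0-9]+_r$", names(df), value = TRUE)
  if (length(au_cols) == 0L)
    stop(sprintf("format error: no AU intensity ('_r') columns in %s", path),
         call. = FALSE)
  au_cols <- au_cols[order(as.integer(sub("^AU([0-9]+)_r$", "\\1", au_cols)))]

  series <- matrix(NA_real_, nrow(df), length(au_cols),
                   dimnames = list(NULL, au_cols))
  for (j in seq_along(au_cols)) {
    raw <- df[[au_cols[j]]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "")
    if (length(bad) > 0L)
      stop(sprintf("parse error: non-numeric value in column %s, row %d of %s",
                   au_cols[j], bad[1], path), call. = FALSE)
    series[, j] <- val
  }

  n <- nrow(series)
  confidence <- if ("confidence" %in% names(df)) as.numeric(df$confidence) else rep(1, n)
  success <- if ("success" %in% names(df)) as.integer(df$success) else rep(1L, n)

  # interpolate tracking failures so the time grid stays regular
  lost <- which(success == 0L)
  if (length(lost) > 0L && length(lost) < n) {
    ok <- which(success != 0L)
    for (j in seq_len(ncol(series)))
      series[lost, j] <- stats::approx(ok, series[ok, j], xout = lost,
                                       rule = 2)$y
  }
  series[series < 0] <- 0
  frame_rate <- if ("timestamp" %in% names(df) && n > 1L) {
    dt <- stats::median(diff(df$timestamp))
    if (is.finite(dt) && dt > 0) 1 / dt else 30
  } else 30

  au_trial(trial_id = trial_id %||% sub("\\.csv$", "", basename(path)),
           subject_id = subject_id, emotion = emotion, condition = condition,
           session = session, series = series, frame_rate = frame_rate,
           confidence = confidence, success = success)
}

#' Read a dataset manifest
#'
#' Loads every trial listed in a TSV manifest written by [write_dataset()].
#'
#' @param manifest_path Path to a manifest TSV with columns `trial_id`,
#'   `subject_id`, `emotion`, `condition`, `session`, `path`.
#' @return List of `au_trial` objects.
#' @export
read_dataset <- function(manifest_path) {
  m <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(m)), function(i) {
    p <- m$path[i]
    if (!file.exists(p)) p <- file.path(dirname(manifest_path), basename(p))
    read_openface_csv(p, trial_id = m$trial_id[i], subject_id = m$subject_id[i],
                      emotion = m$emotion[i], condition = m$condition[i],
                      session = m$session[i])
  })
}

#' Filter trials by tracking quality
#'
#' Keeps trials whose tracking accuracy is strictly above the threshold
#' (reading "over 90%" literally). Accuracy is measured either as mean
#' per-frame confidence (default) or as the fraction of successful frames.
#'
#' @param trials Non-empty list of `au_trial` objects.
#' @param threshold Quality threshold (default 0.90).
#' @param statistic `"mean_confidence"` or `"success_rate"`.
#' @return The retained trials, in input order (possibly empty).
#' @export
filter_by_confidence <- function(trials, threshold = 0.90,
                                 statistic = c("mean_confidence",
                                               "success_rate")) {
  if (length(trials) == 0L) stop("`trials` must be non-empty", call. = FALSE)
  statistic <- match.arg(statistic)
  q <- vapply(trials, function(tr) {
    if (statistic == "mean_confidence") mean(tr$confidence)
    else mean(tr$success != 0L)
  }, numeric(1))
  keep <- q > threshold
  message(sprintf("filter_by_confidence: kept %d / %d trials (%s > %g)",
                  sum(keep), length(trials), statistic, threshold))
  trials[keep]
}

#' Moving-average smoothing
#'
#' Centered moving average per channel with the window truncated at the
#' series edges (no padding values invented), so the output has the input
#' length.
#'
#' @param series Numeric vector or `n x A` matrix.
#' @param window Odd window width in frames (default 3).
#' @return Smoothed series of the same shape.
#' @export
#' @examples
#' smooth_moving_average(c(0, 3, 0, 3, 0), window = 3)
smooth_moving_average <- function(series, window = 3L) {
  assert_count(window, "window")
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  vec <- is.null(dim(series))
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 1L) stop("series must have at least one frame", call. = FALSE)
  if (window == 1L || n == 1L) return(series)
  h <- (window - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  out <- apply(x, 2, function(col) {
    cs <- c(0, cumsum(col))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  out <- matrix(out, n, ncol(x), dimnames = dimnames(x))
  if (vec) drop(out) else out
}

#' Reduce a series to a fixed number of time bins
#'
#' Partitions the frames into `n_bins` contiguous, maximally equal groups
#' (sizes differing by at most one) and replaces each group by its mean.
#' Series shorter than `n_bins` are first linearly interpolated up to
#' `n_bins` points.
#'
#' @param series Numeric vector or `n x A` matrix.
#' @param n_bins Number of output bins (default 100).
#' @return A `n_bins x A` matrix (or vector).
#' @export
bin_to_fixed_length <- function(series, n_bins = 100L) {
  assert_count(n_bins, "n_bins")
  vec <- is.null(dim(series))
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 1L) stop("series must have at least one frame", call. = FALSE)
  if (n < n_bins) {
    xf <- seq(0, 1, length.out = n_bins)
    xo <- seq(0, 1, length.out = n)
    x <- apply(x, 2, function(col)
      if (n == 1L) rep(col, n_bins) else stats::approx(xo, col, xout = xf)$y)
    x <- matrix(x, n_bins, ncol(as.matrix(series)))
    n <- n_bins
  }
  grp <- floor((seq_len(n) - 1L) * n_bins / n) + 1L
  out <- apply(x, 2, function(col) tapply(col, grp, mean))
  out <- matrix(out, n_bins, ncol(x))
  colnames(out) <- colnames(as.matrix(series))
  if (vec) drop(out) else out
}

#' Preprocess a list of trials
#'
#' Applies moving-average smoothing then fixed-length binning to every
#' trial, returning trials whose series all have `n_bins` rows.
#'
#' @param trials List of `au_trial` objects.
#' @param window Smoothing window (odd; default 3 frames).
#' @param n_bins Bins per trial (default 100).
#' @return List of `au_trial` objects with binned series.
#' @export
preprocess_trials <- function(trials, window = 3L, n_bins = 100L) {
  lapply(trials, function(tr) {
    tr$series <- bin_to_fixed_length(
      smooth_moving_average(tr$series, window), n_bins)
    tr$confidence <- rep(mean(tr$confidence), n_bins)
    tr$success <- rep(1L, n_bins)
    tr
  })
}

#' Stack trials into the NMF input matrix
#'
#' Concatenates the binned AU series of every trial row-wise into a single
#' `(n_trials * n_bins) x A` non-negative matrix, with an index mapping each
#' row back to its (trial, bin).
#'
#' @param trials List of `au_trial` objects sharing the same AU channels.
#' @param n_bins Bins per trial; series not already of this length are
#'   binned with [bin_to_fixed_length()].
#' @return An object of class `stacked_matrix`: list with `M`, `index`
#'   (data frame `trial_id`, `bin`), `n_bins`, `trial_ids`, `meta`.
#' @export
stack_trials <- function(trials, n_bins = 100L) {
  if (length(trials) == 0L) stop("`trials` must be non-empty", call. = FALSE)
  chans <- lapply(trials, function(tr) colnames(tr$series))
  if (length(unique(vapply(chans, paste, "", collapse = ","))) != 1L)
    stop("schema error: trials have inconsistent AU channel sets", call. = FALSE)
  mats <- lapply(trials, function(tr) {
    s <- tr$series
    if (nrow(s) != n_bins) s <- bin_to_fixed_length(s, n_bins)
    s
  })
  M <- do.call(rbind, mats)
  ids <- vapply(trials, function(tr) tr$trial_id, "")
  index <- data.frame(trial_id = rep(ids, each = n_bins),
                      bin = rep(seq_len(n_bins), length(trials)),
                      stringsAsFactors = FALSE)
  meta <- data.frame(trial_id = ids,
                     subject_id = vapply(trials, function(tr) as.character(tr$subject_id), ""),
                     emotion = vapply(trials, function(tr) as.character(tr$emotion), ""),
                     condition = vapply(trials, function(tr) as.character(tr$condition), ""),
                     session = vapply(trials, function(tr) as.integer(tr$session), 1L),
                     stringsAsFactors = FALSE)
  structure(list(M = M, index = index, n_bins = as.integer(n_bins),
                 trial_ids = ids, meta = meta),
            class = "stacked_matrix")
}

#' @export
print.stacked_matrix <- function(x, ...) {
  cat(sprintf("Stacked AU matrix: %d trials x %d bins = %d rows, %d channels\n",
              length(x$trial_ids), x$n_bins, nrow(x$M), ncol(x$M)))
  invisible(x)
}

#' Unstack a stacked matrix back into per-trial series
#'
#' @param sm A `stacked_matrix`.
#' @return Named list of `n_bins x A` matrices, one per trial.
#' @export
unstack_trials <- function(sm) {
  stopifnot(inherits(sm, "stacked_matrix"))
  out <- lapply(sm$trial_ids, function(id) {
    rows <- which(sm$index$trial_id == id)
    sm$M[rows[order(sm$index$bin[rows])], , drop = FALSE]
  })
  names(out) <- sm$trial_ids
  out
}

#' Subset a stacked matrix by trial
#'
#' Restricts a `stacked_matrix` to the given trials (e.g. a training or
#' test split), preserving row order and the index/metadata structure.
#'
#' @param sm A `stacked_matrix`.
#' @param trial_ids Trial identifiers to keep.
#' @return A `stacked_matrix` over the selected trials.
#' @export
subset_stacked <- function(sm, trial_ids) {
  keep_rows <- sm$index$trial_id %in% trial_ids
  structure(list(M = sm$M[keep_rows, , drop = FALSE],
                 index = sm$index[keep_rows, , drop = FALSE],
                 n_bins = sm$n_bins,
                 trial_ids = sm$trial_ids[sm$trial_ids %in% trial_ids],
                 meta = sm$meta[sm$meta$trial_id %in% trial_ids, , drop = FALSE]),
            class = "stacked_matrix")
}
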