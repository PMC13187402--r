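# Interpretable timeseries features of component trajectories, and PCA
# summarisation fitted on training data only.

# prominence of a local maximum: height above the higher of the two valley
# minima separating it from higher ground (or the series ends)
.peak_count <- function(x, min_prom) {
  n <- length(x)
  if (n < 3L) return(0)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cnt <- 0
  for (i in idx) {
    left <- x[1:i]
    higher_l <- which(left > x[i])
    vmin_l <- if (length(higher_l)) min(x[max(higher_l):i]) else min(left)
    right <- x[i:n]
    higher_r <- which(right > x[i])
    vmin_r <- if (length(higher_r)) min(x[i:(i + min(higher_r) - 1)]) else min(right)
    if (x[i] - max(vmin_l, vmin_r) >= min_prom) cnt <- cnt + 1
  }
  cnt
}

.sample_entropy <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  r <- r_frac * stats::sd(x)
  if (!is.finite(r) || r == 0) return(NA_real_)
  count_matches <- function(mm) {
    n_t <- n - mm + 1L
    templ <- sapply(seq_len(mm), function(j) x[j:(j + n_t - 1L)])
    templ <- matrix(templ, n_t, mm)
    cnt <- 0L
    for (i in seq_len(n_t - 1L)) {
      d <- abs(sweep(templ[(i + 1L):n_t, , drop = FALSE], 2, templ[i, ]))
      cnt <- cnt + sum(apply(d, 1, max) <= r)
    }
    cnt
  }
  B <- count_matches(m)
  A <- count_matches(m + 1L)
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

.perm_entropy <- function(x, order = 3L) {
  n <- length(x)
  n_w <- n - order + 1L
  if (n_w < 1L) return(NA_real_)
  pats <- vapply(seq_len(n_w), function(i)
    paste(order(x[i:(i + order - 1L)]), collapse = ""), "")
  p <- table(pats) / n_w
  h <- -sum(p * log(p))
  h / log(factorial(order))
}

.spectrum <- function(x) {
  n <- length(x)
  P <- Mod(stats::fft(x - mean(x)))^2
  nf <- floor(n / 2)
  list(freq = (1:nf) / n, power = P[2:(nf + 1L)])
}

# The fixed default catalog of 38 per-component features. Each entry maps a
# numeric vector (one component trajectory over bins) to one number.
.FEATURES <- list(
  mean = function(x) mean(x),
  sd = function(x) stats::sd(x),
  min = function(x) min(x),
  max = function(x) max(x),
  range = function(x) diff(range(x)),
  median = function(x) stats::median(x),
  iqr = function(x) stats::IQR(x),
  auc = function(x) sum((x[-1] + x[-length(x)]) / 2),
  argmax_norm = function(x) (which.max(x) - 1) / (length(x) - 1),
  argmin_norm = function(x) (which.min(x) - 1) / (length(x) - 1),
  slope = function(x) {
    t <- seq_along(x) - 1
    stats::cov(t, x) / stats::var(t)
  },
  mean_abs_change = function(x) mean(abs(diff(x))),
  curvature_mean = function(x) mean(abs(diff(x, differences = 2))),
  curvature_max = function(x) max(abs(diff(x, differences = 2))),
  peak_count = function(x) .peak_count(x, 0.5 * stats::sd(x)),
  zero_crossings = function(x) {
    t <- seq_along(x) - 1
    res <- x - (mean(x) + (stats::cov(t, x) / stats::var(t)) * (t - mean(t)))
    s <- sign(res); s <- s[s != 0]
    sum(diff(s) != 0)
  },
  acf_lag1 = function(x) stats::acf(x, lag.max = 1, plot = FALSE,
                                    demean = TRUE)$acf[2],
  acf_lag5 = function(x) stats::acf(x, lag.max = 5, plot = FALSE,
                                    demean = TRUE)$acf[6],
  acf_first_zero = function(x) {
    a <- drop(stats::acf(x, lag.max = length(x) - 1L, plot = FALSE,
                         demean = TRUE)$acf)[-1]
    w <- which(a <= 0)
    if (length(w)) w[1] else NA_real_
  },
  sample_entropy = function(x) .sample_entropy(x),
  perm_entropy = function(x) .perm_entropy(x),
  spectral_centroid = function(x) {
    s <- .spectrum(x)
    if (sum(s$power) == 0) return(0)
    sum(s$freq * s$power) / sum(s$power)
  },
  spectral_entropy = function(x) {
    s <- .spectrum(x)
    if (sum(s$power) == 0) return(0)
    p <- s$power / sum(s$power); p <- p[p > 0]
    -sum(p * log(p)) / log(length(s$power))
  },
  lowband_power = function(x) {
    s <- .spectrum(x)
    if (sum(s$power) == 0) return(0)
    sum(s$power[s$freq < 0.1]) / sum(s$power)
  },
  cid = function(x) sqrt(sum(diff(x)^2)),
  time_rev_asym = function(x) {
    d <- diff(x)
    den <- mean(d^2)^1.5
    if (den == 0) 0 else mean(d^3) / den
  },
  longest_mono_run = function(x) {
    s <- sign(diff(x)); s[s == 0] <- NA
    r <- rle(s)
    runs <- r$lengths[!is.na(r$values)]
    if (length(runs)) max(runs) + 1 else 1
  },
  prop_above_mean = function(x) mean(x > mean(x)),
  skewness = function(x) e1071::skewness(x),
  kurtosis = function(x) e1071::kurtosis(x),
  rms = function(x) sqrt(mean(x^2)),
  crest = function(x) {
    r <- sqrt(mean(x^2))
    if (r == 0) 0 else max(abs(x)) / r
  },
  energy_first_half = function(x) {
    e <- sum(x^2)
    if (e == 0) 0 else sum(x[seq_len(length(x) %/% 2)]^2) / e
  },
  energy_second_half = function(x) {
    e <- sum(x^2)
    if (e == 0) 0 else sum(x[(length(x) %/% 2 + 1L):length(x)]^2) / e
  },
  hjorth_mobility = function(x) {
    v <- stats::var(x)
    if (v == 0) 0 else sqrt(stats::var(diff(x)) / v)
  },
  hjorth_complexity = function(x) {
    v1 <- stats::var(diff(x))
    v0 <- stats::var(x)
    if (v0 == 0 || v1 == 0) return(0)
    sqrt(stats::var(diff(x, differences = 2)) / v1) / sqrt(v1 / v0)
  },
  p10 = function(x) stats::quantile(x, 0.10, names = FALSE),
  p90 = function(x) stats::quantile(x, 0.90, names = FALSE)
)

#' The timeseries feature catalog
#'
#' Returns the fixed, versioned catalog of per-component trajectory
#' features: location and spread, shape (area, normalised peak location,
#' slope, curvature), complexity (sample and permutation entropy, CID,
#' time-reversal asymmetry), autocorrelation, spectral summaries, and
#' Hjorth parameters. Thirty-eight features per component.
#'
#' @return Named list of functions, each mapping a numeric vector to a
#'   single number. The list carries a `version` attribute.
#' @export
feature_catalog <- function() {
  structure(.FEATURES, version = "fexdyn-38-v1")
}

#' Extract timeseries features from a component trajectory
#'
#' Applies the feature catalog to every component column of a trajectory,
#' producing a named vector of `38 * k` features (`C<j>_<feature>`).
#' Features that are undefined on a given series (e.g. entropy of a
#' constant) are imputed with 0 and recorded in the `imputed` attribute.
#'
#' @param traj `n_bins x k` numeric matrix (n_bins >= 8).
#' @param catalog Feature catalog (default [feature_catalog()]).
#' @return Named numeric vector of length `length(catalog) * k`.
#' @export
extract_features <- function(traj, catalog = feature_catalog()) {
  traj <- as.matrix(traj)
  if (nrow(traj) < 8L)
    stop("trajectory must have at least 8 bins (entropy features undefined)",
         call. = FALSE)
  k <- ncol(traj)
  out <- numeric(0)
  for (j in seq_len(k)) {
    x <- traj[, j]
    v <- vapply(catalog, function(f) as.numeric(f(x))[1], numeric(1))
    names(v) <- paste0("C", j, "_", names(catalog))
    out <- c(out, v)
  }
  imputed <- !is.finite(out)
  out[imputed] <- 0
  attr(out, "imputed") <- names(out)[imputed]
  out
}

#' Build a feature table for a set of trials
#'
#' @param trajs Named list of per-trial `n_bins x k` trajectories (as from
#'   [trajectories()]).
#' @param catalog Feature catalog.
#' @return Numeric matrix, one row per trial, deterministic column order.
#' @export
feature_table <- function(trajs, catalog = feature_catalog()) {
  rows <- lapply(trajs, extract_features, catalog = catalog)
  tab <- do.call(rbind, rows)
  rownames(tab) <- names(trajs)
  tab
}

#' Fit a PCA summariser on training features
#'
#' Z-scores every feature using training statistics (constant columns are
#' centred and excluded from scaling), then computes principal components by
#' SVD of the standardised table. The number of retained dimensions equals
#' the number of NMF components, and the sign of each loading vector is
#' fixed by making its largest-magnitude entry positive.
#'
#' @param train Training feature matrix (trials x features).
#' @param n_components Number of PCs to retain.
#' @return An object of class `feature_pca`: `center`, `scale`, `loadings`
#'   (features x n_components), `var_explained`, `columns`.
#' @export
fit_feature_pca <- function(train, n_components) {
  train <- as.matrix(train)
  assert_count(n_components, "n_components")
  if (n_components > min(dim(train)))
    stop("`n_components` exceeds min(rows, cols)", call. = FALSE)
  if (nrow(train) <= n_components)
    stop("need more training rows than components", call. = FALSE)
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  const <- sdv < 1e-12
  if (any(const))
    message(sprintf("fit_feature_pca: %d constant feature column(s) zeroed",
                    sum(const)))
  sc <- ifelse(const, 1, sdv)
  Z <- sweep(sweep(train, 2, mu), 2, sc, "/")
  sv <- svd(Z)
  ve <- sv$d^2 / sum(sv$d^2)
  L <- sv$v[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(train)
  colnames(L) <- paste0("PC", seq_len(n_components))
  structure(list(center = mu, scale = sc, loadings = L,
                 var_explained = ve[seq_len(n_components)],
                 columns = colnames(train),
                 n_components = as.integer(n_components)),
            class = "feature_pca")
}

#' Apply a fitted feature PCA
#'
#' Transforms a feature table with the training scaler and loadings; the
#' test set never influences the fit.
#'
#' @param pca A `feature_pca`.
#' @param table Feature matrix with the same columns as the training table.
#' @return Score matrix (rows x n_components).
#' @export
apply_feature_pca <- function(pca, table) {
  stopifnot(inherits(pca, "feature_pca"))
  table <- as.matrix(table)
  if (is.null(colnames(table)) || !identical(colnames(table), pca$columns))
    stop("schema error: feature columns do not match the training table",
         call. = FALSE)
  Z <- sweep(sweep(table, 2, pca$center), 2, pca$scale, "/")
  Z %*% pca$loadings
}
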