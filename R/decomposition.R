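# Non-negative matrix factorization of the stacked AU matrix: multiplicative
# updates, consensus-based rank-selection metrics, a block-shuffle temporal
# null, and NNLS projection of held-out trials onto a trained spatial basis.

.as_M <- function(M) {
  if (inherits(M, "stacked_matrix")) M$M else as.matrix(M)
}

#' Fit an NMF model by multiplicative updates
#'
#' Factorises a non-negative matrix `M` as `M ~ M' = T S`, where the rows of
#' `T` carry the temporal weights of each (trial, bin) sample and the rows
#' of `S` carry the spatial AU activation weights of each component.
#' Lee-Seung multiplicative updates minimise the Frobenius loss
#' `||M - T S||_F^2` from non-negative random initialisation; the update
#' rule never produces negative entries and the objective is non-increasing.
#'
#' @param M A `stacked_matrix` or non-negative numeric matrix
#'   (samples x AU channels).
#' @param k Factorisation rank, `1 <= k <= ncol(M)`.
#' @param seed Integer seed for the random initialisation.
#' @param max_iter Maximum number of update sweeps.
#' @param tol Relative objective-change convergence threshold.
#' @return An object of class `fexdyn_nmf`: list with `k`, `S` (`k x A`),
#'   `T` (`rows x k`), `objective_trace`, `rss`, `evar`, `seed`, `n_iter`.
#' @export
#' @examples
#' M <- matrix(runif(200), 50, 4)
#' fit <- nmf_fit(M, k = 2, seed = 1)
#' fit$evar
nmf_fit <- function(M, k, seed = 1L, max_iter = 2000L, tol = 1e-6) {
  X <- .as_M(M)
  if (any(X < 0)) stop("domain error: M has negative entries", call. = FALSE)
  assert_count(k, "k")
  if (k > ncol(X)) stop("`k` cannot exceed the channel count", call. = FALSE)
  n <- nrow(X); A <- ncol(X)
  eps <- .Machine$double.eps

  with_seed(seed, {
    scale0 <- sqrt(mean(X) / max(k, 1))
    W <- matrix(stats::runif(n * k, eps, 1), n, k) * scale0  # temporal T
    H <- matrix(stats::runif(k * A, eps, 1), k, A) * scale0  # spatial S

    trace <- numeric(0)
    obj_prev <- Inf
    it <- 0L
    repeat {
      it <- it + 1L
      # T <- T * (M S') / (T S S')
      W <- W * (X %*% t(H)) / (W %*% (H %*% t(H)) + eps)
      # S <- S * (T' M) / (T' T S)
      H <- H * (t(W) %*% X) / ((t(W) %*% W) %*% H + eps)
      obj <- sum((X - W %*% H)^2)
      trace <- c(trace, obj)
      if (it >= max_iter) break
      if (is.finite(obj_prev) && obj_prev > 0 &&
          (obj_prev - obj) / obj_prev < tol) break
      obj_prev <- obj
    }
    rss <- trace[length(trace)]
    tss <- sum(X^2)
    dimnames(H) <- list(paste0("C", seq_len(k)), colnames(X))
    colnames(W) <- paste0("C", seq_len(k))
    structure(list(k = as.integer(k), S = H, T = W,
                   objective_trace = trace, rss = rss,
                   evar = 1 - rss / tss, seed = as.integer(seed),
                   n_iter = it),
              class = "fexdyn_nmf")
  })
}

#' @export
print.fexdyn_nmf <- function(x, ...) {
  cat(sprintf("NMF model: k = %d, %d samples x %d channels, %d iterations, evar = %.4f\n",
              x$k, nrow(x$T), ncol(x$S), x$n_iter, x$evar))
  invisible(x)
}

#' Reconstruct the approximated matrix
#'
#' @param model A fitted `fexdyn_nmf`.
#' @return The reconstruction `T %*% S`.
#' @export
reconstruct <- function(model) {
  stopifnot(inherits(model, "fexdyn_nmf"))
  model$T %*% model$S
}

#' Block-based time shuffling
#'
#' Builds a permutation null that destroys the coherent spatiotemporal
#' pattern while retaining short-range temporal ordering: within each trial
#' and each AU channel independently, the bin sequence is cut into
#' consecutive blocks of `block_len` bins (the last block may be shorter)
#' and the blocks are permuted uniformly at random. The multiset of values
#' per (trial, channel) is preserved exactly.
#'
#' @param M A `stacked_matrix`.
#' @param block_len Block length in bins, `1 <= block_len <= n_bins`
#'   (default 10).
#' @param seed Integer seed.
#' @return A shuffled `stacked_matrix` of identical shape.
#' @export
block_shuffle <- function(M, block_len = 10L, seed = 1L) {
  stopifnot(inherits(M, "stacked_matrix"))
  assert_count(block_len, "block_len")
  if (block_len > M$n_bins)
    stop("`block_len` cannot exceed n_bins", call. = FALSE)
  n_bins <- M$n_bins
  blk <- (seq_len(n_bins) - 1L) %/% block_len + 1L
  n_blk <- max(blk)
  out <- M
  with_seed(seed, {
    for (id in M$trial_ids) {
      rows <- which(M$index$trial_id == id)
      rows <- rows[order(M$index$bin[rows])]
      for (j in seq_len(ncol(M$M))) {
        perm <- sample.int(n_blk)
        new_order <- unlist(lapply(perm, function(b) which(blk == b)),
                            use.names = FALSE)
        out$M[rows, j] <- M$M[rows[new_order], j]
      }
    }
  })
  out
}

#' Consensus stability metrics for a given rank
#'
#' Refits the NMF `n_runs` times from different random initialisations,
#' assigns each AU channel to its dominant component (argmax over the
#' spatial weights), and builds the `A x A` consensus matrix of
#' co-assignment frequencies. The cophenetic coefficient is the correlation
#' between consensus distances (`1 - consensus`) and the cophenetic
#' distances of their average-linkage dendrogram; the silhouette is the mean
#' silhouette width of the k-way cut of that dendrogram under consensus
#' distance.
#'
#' @param M A `stacked_matrix` or non-negative matrix.
#' @param k Rank (must not exceed the channel count).
#' @param n_runs Number of random restarts (>= 2).
#' @param seed Integer seed.
#' @param max_iter,tol Passed to [nmf_fit()].
#' @return List with `silhouette`, `cophenetic`, `consensus` matrix, and the
#'   vector `rss`/`evar` over runs.
#' @export
consensus_metrics <- function(M, k, n_runs = 30L, seed = 1L,
                              max_iter = 500L, tol = 1e-5) {
  X <- .as_M(M)
  assert_count(n_runs, "n_runs", min = 2L)
  if (k > ncol(X)) stop("`k` cannot exceed the channel count", call. = FALSE)
  A <- ncol(X)
  run_seeds <- with_seed(seed, sample.int(2^30, n_runs))
  consensus <- matrix(0, A, A)
  rss <- evar <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- nmf_fit(X, k, seed = run_seeds[r], max_iter = max_iter, tol = tol)
    assign <- apply(fit$S, 2, which.max)
    consensus <- consensus + outer(assign, assign, "==")
    rss[r] <- fit$rss; evar[r] <- fit$evar
  }
  consensus <- consensus / n_runs
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  coph <- if (stats::sd(d) == 0) {
    1.0  # all restarts identical: consensus is a perfect partition
  } else {
    cc <- suppressWarnings(stats::cor(d, stats::cophenetic(hc)))
    if (is.na(cc)) 1.0 else cc
  }
  sil <- if (k < 2L || k >= A) {
    NA_real_
  } else {
    cut <- stats::cutree(hc, k = k)
    if (length(unique(cut)) < 2L) NA_real_
    else mean(cluster::silhouette(cut, d)[, "sil_width"])
  }
  list(silhouette = sil, cophenetic = coph, consensus = consensus,
       rss = rss, evar = evar)
}

#' Select the factorisation rank
#'
#' Evaluates each candidate rank on the observed matrix and on block-shuffled
#' null copies, then chooses the rank with the best mean rank across three
#' criteria: cophenetic coefficient (higher better), consensus silhouette
#' (higher better), and explained variance in excess of the null (higher
#' better). Ties break toward the smaller rank.
#'
#' @param M A `stacked_matrix`.
#' @param k_range Candidate ranks (default 2:6).
#' @param n_runs Restarts per rank for the consensus metrics.
#' @param n_null Number of block-shuffled null datasets.
#' @param block_len Block length for the shuffle (default 10 bins).
#' @param seed Integer seed.
#' @param max_iter,tol Passed to [nmf_fit()].
#' @return An object of class `k_selection`: list with `table` (per-k
#'   metrics on data and null) and `chosen_k`.
#' @export
select_k <- function(M, k_range = 2:6, n_runs = 10L, n_null = 5L,
                     block_len = 10L, seed = 1L, max_iter = 500L,
                     tol = 1e-5) {
  stopifnot(inherits(M, "stacked_matrix"))
  if (length(k_range) == 0L) stop("`k_range` must be non-empty", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  seeds <- with_seed(seed, sample.int(2^30, 2L + n_null))

  nulls <- lapply(seq_len(n_null), function(b)
    block_shuffle(M, block_len = block_len, seed = seeds[2L + b]))

  rows <- lapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    cm <- consensus_metrics(M, k, n_runs = n_runs,
                            seed = derive_seed(seeds[1], paste0("k", k)),
                            max_iter = max_iter, tol = tol)
    null_evar <- vapply(seq_len(n_null), function(b) {
      nmf_fit(nulls[[b]], k,
              seed = derive_seed(seeds[2], sprintf("null%d_k%d", b, k)),
              max_iter = max_iter, tol = tol)$evar
    }, numeric(1))
    data.frame(k = k, rss = min(cm$rss), evar = max(cm$evar),
               silhouette = cm$silhouette, cophenetic = cm$cophenetic,
               null_evar = mean(null_evar),
               excess_evar = max(cm$evar) - mean(null_evar))
  })
  tab <- do.call(rbind, rows)

  score <- rank(tab$cophenetic, ties.method = "average") +
    rank(ifelse(is.na(tab$silhouette), -Inf, tab$silhouette),
         ties.method = "average") +
    rank(tab$excess_evar, ties.method = "average")
  tab$mean_rank <- score / 3
  best <- order(-tab$mean_rank, tab$k)[1]
  structure(list(table = tab, chosen_k = tab$k[best]), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Rank selection over k =", paste(x$table$k, collapse = ", "), "\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' Project new data onto a trained spatial basis
#'
#' Holds the spatial weights `S` fixed and solves each new row's temporal
#' weights by non-negative least squares, the deterministic optimum per row.
#'
#' @param model A fitted `fexdyn_nmf`.
#' @param M_new A `stacked_matrix` or matrix with the same AU channels.
#' @return A `rows x k` non-negative temporal weight matrix.
#' @export
nmf_project <- function(model, M_new) {
  stopifnot(inherits(model, "fexdyn_nmf"))
  X <- .as_M(M_new)
  if (ncol(X) != ncol(model$S))
    stop("schema error: channel count does not match the trained model",
         call. = FALSE)
  St <- t(model$S)  # A x k
  W <- t(apply(X, 1, function(row) {
    if (all(row == 0)) rep(0, model$k)
    else pracma::lsqnonneg(St, row)$x
  }))
  W <- matrix(W, nrow(X), model$k)
  colnames(W) <- paste0("C", seq_len(model$k))
  W
}

#' Per-trial component trajectories
#'
#' Reshapes stacked temporal weights into one `n_bins x k` trajectory per
#' trial, optionally with bin-wise group means (e.g. per emotion).
#'
#' @param T_mat Stacked temporal weights (`rows x k`).
#' @param index Data frame with `trial_id` and `bin` covering every row.
#' @param groups Optional per-trial labels (named by trial id, or in trial
#'   order) for which bin-wise mean trajectories are also returned.
#' @return List with `trials` (named list of `n_bins x k` matrices) and,
#'   when `groups` is given, `group_means`.
#' @export
trajectories <- function(T_mat, index, groups = NULL) {
  T_mat <- as.matrix(T_mat)
  if (nrow(T_mat) != nrow(index))
    stop("index error: index does not cover all rows", call. = FALSE)
  ids <- unique(index$trial_id)
  trials <- lapply(ids, function(id) {
    rows <- which(index$trial_id == id)
    rows <- rows[order(index$bin[rows])]
    m <- T_mat[rows, , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  names(trials) <- ids
  out <- list(trials = trials)
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[ids]
    gl <- split(seq_along(ids), as.character(groups))
    out$group_means <- lapply(gl, function(ix)
      Reduce(`+`, trials[ix]) / length(ix))
  }
  out
}
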