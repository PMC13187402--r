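# Kinematic substates: speed and displacement of component trajectories,
# DTW-based clustering of overlapping windows into relaxed / sustain /
# transition substates, per-substate speed summaries and normalised
# transition entropy of the substate sequence.

#' Component kinematics
#'
#' Speed is the first derivative of the trajectory, approximated by the
#' bin-wise difference between consecutive values normalised by the bin
#' interval; displacement is the series differenced relative to its starting
#' value (baseline).
#'
#' @param traj `n_bins x k` component trajectory (n_bins >= 2).
#' @param dt Seconds per bin (> 0).
#' @return An object of class `kinematic_series`: `speed`
#'   (`(n_bins-1) x k`), `displacement` (`n_bins x k`, first row 0), `dt`.
#' @export
compute_kinematics <- function(traj, dt = 1) {
  traj <- as.matrix(traj)
  if (nrow(traj) < 2L) stop("need at least 2 bins", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  speed <- diff(traj) / dt
  displacement <- sweep(traj, 2, traj[1, ])
  structure(list(speed = speed, displacement = displacement, dt = dt),
            class = "kinematic_series")
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming DTW with the symmetric step pattern
#' (match / insert / delete), Euclidean local cost across channels and no
#' global window. Symmetric in its arguments.
#'
#' @param x,y Numeric vectors or `length x channels` matrices with the same
#'   channel count.
#' @return The cumulative alignment cost.
#' @export
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))
dtw_distance <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) == 0L || nrow(y) == 0L)
    stop("series must be non-empty", call. = FALSE)
  if (ncol(x) != ncol(y))
    stop("series must have the same channel count", call. = FALSE)
  n <- nrow(x); m <- nrow(y)
  # local cost: Euclidean distance across channels
  sq <- outer(rowSums(x^2), rep(1, m)) +
    outer(rep(1, n), rowSums(y^2)) - 2 * x %*% t(y)
  lc <- sqrt(pmax(sq, 0))
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1, 1] <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1L, j + 1L] <- lc[i, j] +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  D[n + 1L, m + 1L]
}

# overlapping window start indices covering 1..n
.window_starts <- function(n, window, stride) {
  starts <- seq(1L, max(1L, n - window + 1L), by = stride)
  if (starts[length(starts)] + window - 1L < n)
    starts <- c(starts, n - window + 1L)
  starts
}

# build pooled windows over the 2k channels (|speed|, displacement) of all
# trials; returns list(windows, map = data.frame(trial, start, end)).
# Channels are scaled by one global (pooled) SD per channel so that the
# speed and displacement families contribute comparably to the DTW cost;
# this is a single dataset-wide constant per channel, so between-window
# amplitude differences -- the discriminative absolute speed -- survive.
.make_windows <- function(kin_list, window, stride) {
  chans <- lapply(kin_list, function(kin)
    cbind(abs(kin$speed), kin$displacement[-1, , drop = FALSE]))
  pooled <- do.call(rbind, chans)
  scl <- apply(pooled, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  windows <- list(); map <- NULL
  for (ti in seq_along(chans)) {
    chan <- sweep(chans[[ti]], 2, scl, "/")
    n <- nrow(chan)
    if (window > n) stop("`window` exceeds the series length", call. = FALSE)
    for (s in .window_starts(n, window, stride)) {
      windows[[length(windows) + 1L]] <- chan[s:(s + window - 1L), , drop = FALSE]
      map <- rbind(map, data.frame(trial = ti, start = s, end = s + window - 1L))
    }
  }
  list(windows = windows, map = map)
}

.dtw_dist_matrix <- function(windows) {
  W <- length(windows)
  d <- matrix(0, W, W)
  for (i in seq_len(W - 1L)) for (j in (i + 1L):W)
    d[i, j] <- d[j, i] <- dtw_distance(windows[[i]], windows[[j]])
  d
}

# mean |speed| (averaged over components) per interval of a trial
.interval_speed <- function(kin) rowMeans(abs(kin$speed))

#' Segment trials into kinematic substates
#'
#' Cuts each trial into overlapping windows of the 2k kinematic channels
#' (absolute speed and displacement per component, not per-series
#' normalised: absolute speed is the discriminative signal), clusters the
#' pooled windows by k-medoids (PAM) under DTW distance, assigns each bin
#' the majority cluster over the windows covering it (ties to the earlier
#' window), and relabels clusters by ascending mean absolute speed as
#' relaxed < sustain < transition.
#'
#' @param kin_list List of `kinematic_series`, one per trial.
#' @param c Number of substates (default 3, >= 2).
#' @param window Window length in bins (default 10).
#' @param stride Window stride in bins (default 5).
#' @param seed Integer seed (PAM medoid build is deterministic; the seed
#'   fixes any sampling done by the backend).
#' @return An object of class `substate_sequence`: list with `labels`
#'   (per-trial character vectors over bins), `cluster_speed` (mean |speed|
#'   per substate label), `silhouette` (mean silhouette width), `c`,
#'   `window`, `stride`.
#' @export
segment_substates <- function(kin_list, c = 3L, window = 10L, stride = 5L,
                              seed = 1L) {
  assert_count(c, "c", min = 2L)
  assert_count(window, "window")
  assert_count(stride, "stride")
  wnd <- .make_windows(kin_list, window, stride)
  if (length(wnd$windows) <= c)
    stop("fewer windows than clusters", call. = FALSE)
  d <- .dtw_dist_matrix(wnd$windows)
  if (max(d) < 1e-10)
    warning("degenerate clustering: windows are (near-)identical")
  pam <- with_seed(seed, cluster::pam(stats::as.dist(d), k = c,
                                      cluster.only = FALSE))
  wcl <- pam$clustering
  sil <- mean(cluster::silhouette(wcl, stats::as.dist(d))[, "sil_width"])
  if (!is.finite(sil)) {
    warning("degenerate clustering: windows are (near-)identical")
    sil <- 0
  }

  # per-bin majority vote over covering windows (interval grid: n_bins - 1)
  labels_num <- vector("list", length(kin_list))
  for (ti in seq_along(kin_list)) {
    rows <- which(wnd$map$trial == ti)
    n_int <- nrow(kin_list[[ti]]$speed)
    lab <- integer(n_int)
    for (t in seq_len(n_int)) {
      cover <- rows[wnd$map$start[rows] <= t & wnd$map$end[rows] >= t]
      votes <- wcl[cover]
      tabv <- table(votes)
      winners <- as.integer(names(tabv)[tabv == max(tabv)])
      lab[t] <- if (length(winners) == 1L) winners
      else votes[match(TRUE, votes %in% winners)]  # earliest covering window
    }
    labels_num[[ti]] <- lab
  }

  # relabel clusters by ascending mean |speed|
  all_speed <- unlist(lapply(kin_list, .interval_speed))
  all_lab <- unlist(labels_num)
  cl_speed <- vapply(seq_len(c), function(cl)
    mean(all_speed[all_lab == cl]), numeric(1))
  cl_speed[!is.finite(cl_speed)] <- 0  # cluster never won a bin vote
  ord <- order(cl_speed)  # slowest first
  name_map <- character(c)
  name_map[ord] <- if (c == 2L) c("relaxed", "transition")
  else if (c == 3L) SUBSTATES
  else c("relaxed", paste0("sustain", seq_len(c - 2L)), "transition")

  labels <- lapply(seq_along(kin_list), function(ti) {
    lab <- name_map[labels_num[[ti]]]
    # bins = intervals + 1; the final bin inherits the last interval label
    c(lab, lab[length(lab)])
  })
  names(labels) <- names(kin_list) %||% paste0("trial", seq_along(kin_list))
  cs <- cl_speed[ord]
  names(cs) <- name_map[ord]
  structure(list(labels = labels, cluster_speed = cs, silhouette = sil,
                 c = as.integer(c), window = as.integer(window),
                 stride = as.integer(stride)),
            class = "substate_sequence")
}

#' Select the number of substates
#'
#' Clusters the pooled kinematic windows at each candidate `c` and reports
#' the mean silhouette width under DTW distance; the chosen `c` maximises
#' it.
#'
#' @param kin_list List of `kinematic_series`.
#' @param c_range Candidate substate counts (default 2:4).
#' @param window,stride,seed As in [segment_substates()].
#' @return List with `chosen_c` and a `table` (`c`, `silhouette`).
#' @export
select_c <- function(kin_list, c_range = 2:4, window = 10L, stride = 5L,
                     seed = 1L) {
  c_range <- sort(unique(as.integer(c_range)))
  wnd <- .make_windows(kin_list, window, stride)
  d <- stats::as.dist(.dtw_dist_matrix(wnd$windows))
  sil <- vapply(c_range, function(cc) {
    if (cc >= length(wnd$windows)) return(NA_real_)
    pam <- with_seed(seed, cluster::pam(d, k = cc, cluster.only = TRUE))
    s <- mean(cluster::silhouette(pam, d)[, "sil_width"])
    if (is.finite(s)) s else 0
  }, numeric(1))
  tab <- data.frame(c = c_range, silhouette = sil)
  list(chosen_c = c_range[which.max(sil)], table = tab)
}

#' Per-trial substate speed summary
#'
#' Mean absolute speed (averaged over components) within each substate's
#' bins; substates absent from a trial get `NA`.
#'
#' @param seq A `substate_sequence`.
#' @param kin_list The matching list of `kinematic_series`.
#' @return Data frame with one row per (trial, substate): `trial`,
#'   `substate`, `mean_speed`, `n_bins`.
#' @export
substate_speed_summary <- function(seq, kin_list) {
  stopifnot(inherits(seq, "substate_sequence"))
  states <- names(seq$cluster_speed)
  rows <- lapply(seq_along(kin_list), function(ti) {
    sp <- .interval_speed(kin_list[[ti]])
    lab <- seq$labels[[ti]][seq_along(sp)]  # interval-aligned labels
    data.frame(trial = names(seq$labels)[ti], substate = states,
               mean_speed = vapply(states, function(s)
                 if (any(lab == s)) mean(sp[lab == s]) else NA_real_,
                 numeric(1)),
               n_bins = vapply(states, function(s) sum(lab == s), numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalised transition entropy of a substate sequence
#'
#' Collapses consecutive repeats, counts the ordered state-change pairs
#' (s to s', s != s'), and computes the Shannon entropy of their
#' distribution in bits, normalised by the maximum theoretical entropy for a
#' system with the same number of substates, `log2(S * (S - 1))` with
#' `S = 3`. A sequence with no state changes has entropy 0. Duplicating
#' consecutive labels never changes the result.
#'
#' @param labels Character vector of per-bin substate labels (or a
#'   `substate_sequence`, in which case a per-trial vector is returned).
#' @param n_states Number of substates defining the normalisation
#'   (default 3).
#' @return Normalised entropy in \[0, 1\].
#' @export
#' @examples
#' transition_entropy(c("relaxed", "transition", "sustain",
#'                      "transition", "relaxed"))
transition_entropy <- function(labels, n_states = 3L) {
  if (inherits(labels, "substate_sequence"))
    return(vapply(labels$labels, transition_entropy, numeric(1),
                  n_states = n_states))
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("sequence must be non-empty", call. = FALSE)
  known <- if (n_states == 3L) SUBSTATES else NULL
  if (!is.null(known) && !all(labels %in% known))
    stop(sprintf("label error: unknown substate label(s): %s",
                 paste(setdiff(labels, known), collapse = ", ")),
         call. = FALSE)
  runs <- rle(labels)$values
  if (length(runs) < 2L) return(0)
  pairs <- paste(runs[-length(runs)], runs[-1], sep = "->")
  p <- table(pairs) / length(pairs)
  H <- -sum(p * log2(p))
  H_max <- log2(n_states * (n_states - 1))
  H / H_max
}
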