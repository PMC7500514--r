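#' Optimal 1-D k-median clustering of observation times
#'
#' Partitions a multiset of observation times into `k` contiguous clusters
#' minimizing the total L1 distance to the cluster medians, by exact dynamic
#' programming over sorted times (an optimal L1 partition is always
#' contiguous in sorted order). The representative of each cluster (the
#' `bin_values`) is the exact cluster median; the DP cost uses the lower
#' median, which attains the same (minimal) L1 cost.
#'
#' When `k` is `NULL` it is chosen as the smallest k whose optimal cost is
#' at most `cost_fraction` of the single-cluster cost (or cost 0), which
#' reproduces the "narrow bins" behaviour of time-window approaches without
#' committing to a fixed bin count.
#'
#' @param times numeric vector (multiset) of observation times in years.
#' @param k number of bins, or `NULL` to select automatically.
#' @param cost_fraction cost threshold for automatic selection of k.
#' @return an object of class `time_binning` with elements `k`,
#'   `bin_values` (sorted cluster medians), `assignment` (bin index per
#'   input time, original order), `cost`, and `cost_by_k` (optimal cost for
#'   each candidate k up to the chosen one).
#' @export
kmedian_bins <- function(times, k = NULL, cost_fraction = 0.01) {
  stopifnot(is.numeric(times), length(times) >= 1, all(is.finite(times)))
  ord <- order(times)
  x <- times[ord]
  n <- length(x)
  n_distinct <- length(unique(x))
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1) stop("k must be >= 1")
    if (k > n_distinct) {
      stop("k (", k, ") exceeds the number of distinct times (",
           n_distinct, ")")
    }
  }

  P <- c(0, cumsum(x))
  # L1 cost of segment s..e (1-based, inclusive) about its lower median
  seg_cost <- function(s, e) {
    m <- (s + e) %/% 2
    xm <- x[m]
    (P[e + 1] - P[m]) - xm * (e - m + 1) + xm * (m - s + 1) - (P[m + 1] - P[s])
  }

  kmax <- if (is.null(k)) n_distinct else k
  # dp[kk, e]: optimal cost of partitioning x[1..e] into kk clusters
  dp_prev <- vapply(seq_len(n), function(e) seg_cost(1, e), numeric(1))
  cost1 <- dp_prev[n]
  split_at <- vector("list", kmax) # split_at[[kk]][e] = start of last cluster
  split_at[[1]] <- rep(1L, n)
  cost_by_k <- numeric(0)
  cost_by_k[1] <- cost1

  pick_k <- function(kk, cost) {
    if (!is.null(k)) return(kk == k)
    cost <= cost_fraction * cost1 + 1e-12
  }

  kk <- 1L
  dp_cur <- dp_prev
  while (!pick_k(kk, dp_cur[n]) && kk < kmax) {
    kk <- kk + 1L
    dp_cur <- rep(Inf, n)
    arg <- rep(NA_integer_, n)
    for (e in kk:n) {
      s_cand <- kk:e
      costs <- dp_prev[s_cand - 1L] +
        vapply(s_cand, function(s) seg_cost(s, e), numeric(1))
      best <- which.min(costs)
      dp_cur[e] <- costs[best]
      arg[e] <- s_cand[best]
    }
    split_at[[kk]] <- arg
    cost_by_k[kk] <- dp_cur[n]
    dp_prev <- dp_cur
  }

  # backtrack cluster boundaries for the chosen kk
  starts <- integer(kk)
  e <- n
  for (j in kk:1) {
    starts[j] <- if (j == 1) 1L else split_at[[j]][e]
    e <- starts[j] - 1L
  }
  ends <- c(starts[-1] - 1L, n)
  bin_values <- vapply(seq_len(kk),
                       function(j) median(x[starts[j]:ends[j]]), numeric(1))
  if (anyDuplicated(bin_values)) {
    stop("degenerate clustering produced duplicate bin values")
  }
  assign_sorted <- rep(seq_len(kk), times = ends - starts + 1L)
  assignment <- integer(n)
  assignment[ord] <- assign_sorted

  structure(list(k = kk, bin_values = bin_values, assignment = assignment,
                 cost = cost_by_k[kk], cost_by_k = cost_by_k),
            class = "time_binning")
}

#' @export
print.time_binning <- function(x, ...) {
  cat("<time_binning> k = ", x$k, ", cost = ", signif(x$cost, 5),
      "\n  bins: ", paste(signif(x$bin_values, 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assign binned times to a cohort
#'
#' Adds a `time_bin` column to the cohort's observations: each observation
#' time is replaced, for latent-growth fitting only, by the nearest bin
#' value (ties go to the smaller bin). The exact `time_years` are retained
#' and remain what mixed-model fitting uses.
#'
#' @param cohort a [cohort()].
#' @param binning a `time_binning` from [kmedian_bins()].
#' @return the cohort with a `time_bin` observation column and the binning
#'   attached as attribute `"binning"`.
#' @export
assign_bins <- function(cohort, binning) {
  stopifnot(inherits(binning, "time_binning"))
  t <- cohort$observations$time_years
  bv <- binning$bin_values
  idx <- vapply(t, function(ti) which.min(abs(bv - ti)), integer(1))
  cohort$observations$time_bin <- bv[idx]
  attr(cohort, "binning") <- binning
  cohort
}
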