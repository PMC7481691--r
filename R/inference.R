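# Group-level inference on Fisher-z fidelity series: one-sample t tests,
# window averaging with FDR across windows, and the sign-flip cluster-based
# permutation test.

#' One-sample group t test with effect size
#'
#' Two-tailed one-sample Student t test of per-subject values against zero,
#' with Cohen's d (`mean / sd`).
#'
#' @param values Per-subject scalars (n >= 2, non-zero variance).
#' @param mu Null value (default 0).
#' @return List with `t`, `p`, `d`, `mean`, `n`, `df`.
#' @examples
#' group_ttest(c(1, 2, 3)) # t = 3.4641, d = 1
#' @export
group_ttest <- function(values, mu = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 subjects")
  if (stats::sd(values) == 0) stop("zero variance across subjects")
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), p = tt$p.value,
       d = (mean(values) - mu) / stats::sd(values),
       mean = mean(values), n = length(values), df = unname(tt$parameter))
}

#' Window-averaged group tests with FDR correction
#'
#' Averages each subject's series within each analysis window, runs a
#' one-sample t test per window, and adjusts the p values across the
#' supplied windows with the Benjamini-Hochberg false-discovery-rate
#' method.
#'
#' @param series Subjects x timepoints matrix (e.g. Fisher-z fidelities).
#' @param times Time axis (ms), length `ncol(series)`.
#' @param windows List of `c(start, end)` windows in ms (samples with
#'   `start <= t <= end` are included), optionally named.
#' @param mu Null value per subject mean (default 0).
#' @return Data frame with one row per window: `window`, `start`, `end`,
#'   `mean`, `t`, `df`, `p`, `p_fdr`, `d`.
#' @export
window_average_test <- function(series, times, windows, mu = 0) {
  series <- as.matrix(series)
  stopifnot(ncol(series) == length(times))
  if (!is.list(windows)) windows <- list(windows)
  nm <- names(windows) %||% paste0("window", seq_along(windows))
  rows <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    idx <- which(times >= w[1] & times <= w[2])
    if (length(idx) == 0L)
      stop("window [", w[1], ", ", w[2], "] contains no samples")
    res <- group_ttest(rowMeans(series[, idx, drop = FALSE]), mu = mu)
    data.frame(window = nm[i], start = w[1], end = w[2], mean = res$mean,
               t = res$t, df = res$df, p = res$p, d = res$d)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out[, c("window", "start", "end", "mean", "t", "df", "p", "p_fdr", "d")]
}

# Positive and negative supra-threshold clusters of a t series; returns a
# data.frame(start_idx, end_idx, sign, mass).
find_clusters <- function(tvals, threshold) {
  out <- list()
  for (sgn in c(1, -1)) {
    above <- if (sgn > 0) tvals > threshold else tvals < -threshold
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values)
    for (h in hit) {
      out[[length(out) + 1L]] <- data.frame(
        start_idx = starts[h], end_idx = ends[h], sign = sgn,
        mass = sum(tvals[starts[h]:ends[h]]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      sign = numeric(0), mass = numeric(0)))
  do.call(rbind, out)
}

# Max-|mass| signed cluster statistic of one t series (0 when no cluster).
# Allocation-free equivalent of find_clusters + which.max(abs(mass)), since
# this runs once per permutation iteration.
max_cluster_stat <- function(tvals, threshold) {
  best <- 0
  for (sgn in c(1, -1)) {
    above <- if (sgn > 0) tvals > threshold else tvals < -threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (h in which(r$values)) {
      m <- sum(tvals[starts[h]:ends[h]])
      if (abs(m) > abs(best)) best <- m
    }
  }
  best
}

#' Sign-flip cluster-based permutation test
#'
#' Nonparametric family-wise error control for a one-sample test over time.
#' Observed clusters are runs of contiguous timepoints whose one-sample t
#' value exceeds `threshold` (positive runs) or falls below `-threshold`
#' (negative runs), scored by the sum of t values in the run (cluster
#' mass). The null distribution is built by flipping the sign of each
#' subject's entire timecourse at random (`n_perm` iterations); each
#' iteration contributes the signed mass of its largest-|mass| cluster. A
#' cluster is significant when its |mass| is strictly larger than the
#' `1 - alpha/2` quantile of this (symmetric) null, i.e. the 97.5th
#' percentile at the default two-tailed alpha of 0.05.
#'
#' With the default `threshold = NULL` the cluster-forming threshold is the
#' two-tailed Student critical value `qt(1 - alpha/2, n - 1)` (2.045 for 30
#' subjects).
#'
#' @param series Subjects x timepoints matrix of Fisher-z fidelities (or
#'   accuracies minus chance).
#' @param times Optional time axis (ms) used to label clusters.
#' @param n_perm Number of sign-flip iterations (default 10000).
#' @param threshold Cluster-forming t threshold (`NULL`: analytic critical
#'   value).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `cluster_test`: data frame `clusters`
#'   (`start`, `end`, `start_idx`, `end_idx`, `sign`, `mass`, `p`,
#'   `significant`), the `critical` null quantile, `threshold`, `n_perm`,
#'   `seed`, and the observed per-timepoint `t` series.
#' @export
cluster_permutation <- function(series, times = NULL, n_perm = 10000,
                                threshold = NULL, alpha = 0.05, seed = NULL) {
  series <- as.matrix(series)
  n <- nrow(series); P <- ncol(series)
  stopifnot(n >= 2L)
  if (is.null(threshold)) threshold <- stats::qt(1 - alpha / 2, n - 1L)
  stopifnot(threshold > 0)
  if (is.null(times)) times <- seq_len(P)

  mean_obs <- colMeans(series)
  ssq <- colSums(series^2)
  sd_obs <- sqrt(pmax(0, (ssq - n * mean_obs^2) / (n - 1L)))
  t_obs <- mean_obs / (sd_obs / sqrt(n))
  t_obs[!is.finite(t_obs)] <- 0
  obs <- find_clusters(t_obs, threshold)

  null_stat <- with_seed(seed, {
    Sgn <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Mperm <- (Sgn %*% series) / n
    # sum of squares is sign-invariant, so the permuted sd comes cheap
    Vperm <- sweep(-n * Mperm^2, 2, ssq, "+") / (n - 1L)
    Tperm <- Mperm / sqrt(pmax(Vperm, 0) / n)
    Tperm[!is.finite(Tperm)] <- 0
    vapply(seq_len(n_perm), function(i) max_cluster_stat(Tperm[i, ], threshold),
           numeric(1))
  })
  critical <- stats::quantile(null_stat, 1 - alpha / 2, names = FALSE)
  if (nrow(obs) > 0L) {
    obs$p <- vapply(obs$mass, function(m)
      min(1, 2 * mean(null_stat >= abs(m))), numeric(1))
    obs$significant <- abs(obs$mass) > critical
    obs$start <- times[obs$start_idx]
    obs$end <- times[obs$end_idx]
    obs <- obs[order(obs$start_idx),
               c("start", "end", "start_idx", "end_idx", "sign", "mass",
                 "p", "significant")]
    rownames(obs) <- NULL
  } else {
    obs <- data.frame(start = numeric(0), end = numeric(0),
                      start_idx = integer(0), end_idx = integer(0),
                      sign = numeric(0), mass = numeric(0), p = numeric(0),
                      significant = logical(0))
  }
  structure(list(clusters = obs, critical = critical, threshold = threshold,
                 n_perm = n_perm, alpha = alpha, seed = seed, t = t_obs,
                 times = times,
                 null_quantiles = stats::quantile(null_stat,
                                                  c(0.025, 0.5, 0.975))),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat("Sign-flip cluster permutation test (", x$n_perm, " iterations, ",
      "threshold |t| > ", round(x$threshold, 3), ")\n", sep = "")
  if (nrow(x$clusters) == 0L) {
    cat("  no supra-threshold clusters\n")
  } else {
    print(format(x$clusters[, c("start", "end", "sign", "mass", "p",
                                "significant")], digits = 4),
          row.names = FALSE)
  }
  cat("  critical |mass| >", format(x$critical, digits = 4), "\n")
  invisible(x)
}
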