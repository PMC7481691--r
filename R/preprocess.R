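# Preprocessing: epoch cutting, baseline correction, median re-referencing,
# downsampling by bin averaging, 2-back epoch stitching, and gaze cleaning
# (Hampel outlier repair, missing-sample fill, smoothing).

#' Cut and/or correct epochs
#'
#' With a continuous recording (`electrodes x samples` matrix) plus event
#' onsets, cuts epochs spanning `[tmin, tmax)` ms around each onset; with an
#' already epoched `epoch_array`, uses it as is. In both cases each epoch is
#' then baseline corrected (the per-electrode mean over `baseline` is
#' subtracted) and, if `rereference = TRUE`, re-referenced to the median
#' across electrodes at every timepoint. Sample bins are half-open
#' `[t, t + dt)` with stimulus onset at t = 0.
#'
#' @param x Continuous matrix (electrodes x samples) or an `epoch_array`.
#' @param events A `trial_table` (onsets in ms) — required for continuous
#'   input.
#' @param srate Sampling rate in Hz (continuous input).
#' @param tmin,tmax Epoch bounds in ms, `tmin < 0 <= tmax`.
#' @param baseline Baseline window in ms, contained in `[tmin, 0]`, or
#'   `NULL` to skip.
#' @param rereference Re-reference to the across-electrode median?
#' @return An `epoch_array`.
#' @export
epoch_data <- function(x, events = NULL, srate = NULL, tmin = -200,
                       tmax = 3550, baseline = c(tmin, 0),
                       rereference = TRUE) {
  if (inherits(x, "epoch_array")) {
    e <- x
  } else {
    x <- as.matrix(x)
    stopifnot(!is.null(events), !is.null(srate), tmin < 0, tmax >= 0)
    dt <- 1000 / srate
    times <- seq(tmin, tmax - dt, by = dt)
    rel <- round(times / dt)
    on_smp <- round(events$onset / dt) + 1L
    lo <- on_smp + rel[1]
    hi <- on_smp + rel[length(rel)]
    bad <- which(lo < 1L | hi > ncol(x))
    if (length(bad))
      stop("events outside the recording span: trial(s) ",
           paste(bad, collapse = ", "))
    dat <- array(NA_real_, c(nrow(events), nrow(x), length(times)))
    for (i in seq_len(nrow(events)))
      dat[i, , ] <- x[, lo[i]:hi[i]]
    e <- new_epoch_array(dat, times, srate, events)
  }
  preprocess_epochs(e, baseline = baseline, rereference = rereference)
}

#' Baseline-correct and median re-reference epochs
#'
#' @param e An `epoch_array`.
#' @param baseline Baseline window `[start, end]` in ms (samples with
#'   `start <= t < end`... the window is half-open like all sample bins), or
#'   `NULL` to skip baseline correction.
#' @param rereference Subtract the across-electrode median per timepoint?
#' @return The corrected `epoch_array`.
#' @export
preprocess_epochs <- function(e, baseline = c(min(e$times), 0),
                              rereference = TRUE) {
  stopifnot(inherits(e, "epoch_array"))
  dat <- e$data
  d <- dim(dat)
  if (!is.null(baseline)) {
    bi <- which(e$times >= baseline[1] & e$times < baseline[2])
    if (length(bi) == 0L) stop("baseline window contains no samples")
    bl <- rowMeans(matrix(dat[, , bi, drop = FALSE], d[1] * d[2], length(bi)))
    dat <- dat - bl # recycles over the time dimension
  }
  if (rereference && d[2] > 1L) {
    # median across electrodes per (trial, timepoint), via one sort of the
    # (trial*time) x electrode matrix
    A <- matrix(aperm(dat, c(2, 1, 3)), d[2], d[1] * d[3])
    As <- matrix(A[order(col(A), A)], d[2], d[1] * d[3])
    k <- d[2]
    med <- if (k %% 2L == 1L) As[(k + 1L) %/% 2L, ]
           else (As[k %/% 2L, ] + As[k %/% 2L + 1L, ]) / 2
    dat <- dat - aperm(array(med, c(d[1], d[3], d[2])), c(1, 3, 2))
  } else if (rereference) {
    dat[] <- 0 # the median of a single electrode is the signal itself
  }
  e$data <- dat
  e
}

#' Downsample epochs by non-overlapping bin averaging
#'
#' Anti-aliases by averaging within consecutive non-overlapping bins of
#' `srate / target_hz` samples (the target must divide the source rate); a
#' trailing partial bin is dropped. The new time axis keeps the start time
#' of each bin (half-open bin convention).
#'
#' @param e An `epoch_array` (or `gaze_epochs`).
#' @param target_hz Target sampling rate.
#' @return The downsampled object (identity when `target_hz == srate`).
#' @export
downsample_epochs <- function(e, target_hz) {
  stopifnot(inherits(e, "epoch_array"), target_hz > 0)
  if (target_hz == e$srate) return(e)
  if (e$srate %% target_hz != 0)
    stop("target rate ", target_hz, " Hz does not divide the source rate ",
         e$srate, " Hz")
  f <- as.integer(e$srate / target_hz)
  S <- dim(e$data)[3]
  nb <- S %/% f
  d <- dim(e$data)
  flat <- matrix(e$data[, , seq_len(nb * f), drop = FALSE], d[1] * d[2], nb * f)
  binned <- 0
  for (j in seq_len(f)) binned <- binned + flat[, seq(j, nb * f, by = f),
                                                drop = FALSE]
  e$data <- array(binned / f, c(d[1], d[2], nb))
  e$times <- e$times[seq(1, nb * f, by = f)]
  e$srate <- target_hz
  e
}

#' Stitch adjacent 2-back epochs
#'
#' For each eligible item n, concatenates the epoch of item n with the
#' epoch of item n + 1 along time, recording the discontinuity index (the
#' two epochs are not continuous because only the first 2800 ms of each
#' jittered interstimulus interval is shared by all trials). Each block's
#' first item and last two items are excluded as anchors, so a 128-item
#' block yields 125 stitched records.
#'
#' @param e An `epoch_array` whose trials are ordered by block and
#'   position.
#' @return A `stitched_epochs` object (subclass of `epoch_array`); its
#'   `trials` carry `orientation` (item n), `orientation_prev` (n - 1) and
#'   `orientation_next` (n + 1); attributes `discontinuity` (first index of
#'   the second segment) and `segment` (segment id per timepoint).
#' @export
stitch_epochs <- function(e) {
  stopifnot(inherits(e, "epoch_array"))
  tt <- e$trials
  ord <- order(tt$block, tt$position)
  tt <- tt[ord, ]
  dat <- e$data[ord, , , drop = FALSE]
  S <- dim(dat)[3]
  recs <- list()
  meta <- list()
  for (b in unique(tt$block)) {
    bi <- which(tt$block == b)
    N <- length(bi)
    if (N < 4L)
      stop("block ", b, " has fewer than 4 items; cannot stitch")
    keep <- bi[2:(N - 2L)] # exclude first item and last two (anchors)
    recs[[as.character(b)]] <- cbind(
      matrix(dat[keep, , , drop = FALSE], length(keep) * dim(dat)[2], S),
      matrix(dat[keep + 1L, , , drop = FALSE], length(keep) * dim(dat)[2], S))
    meta[[as.character(b)]] <- data.frame(
      block = b, position = tt$position[keep],
      orientation = tt$orientation[keep],
      orientation_prev = tt$orientation[keep - 1L],
      orientation_next = tt$orientation[keep + 1L])
  }
  meta <- do.call(rbind, meta)
  n_out <- nrow(meta)
  m <- dim(dat)[2]
  flat <- do.call(rbind, recs)
  out_dat <- array(NA_real_, c(n_out, m, 2L * S))
  row0 <- 0L
  for (b in seq_along(recs)) {
    nb <- nrow(meta[meta$block == unique(meta$block)[b], ])
    out_dat[(row0 + 1L):(row0 + nb), , ] <- array(recs[[b]], c(nb, m, 2L * S))
    row0 <- row0 + nb
  }
  span <- S * 1000 / e$srate
  out <- new_epoch_array(out_dat, c(e$times, e$times + span), e$srate, meta,
                         electrodes = e$electrodes)
  class(out) <- c("stitched_epochs", class(out))
  attr(out, "discontinuity") <- S + 1L
  attr(out, "segment") <- rep(1:2, each = S)
  attr(out, "epoch_times") <- e$times
  out
}

#' Hampel outlier repair of a time series
#'
#' Sliding-window outlier repair: each sample deviating from the window
#' median by more than `n_mad` (scaled) median absolute deviations is
#' replaced by that window median. Running medians use shrinking windows at
#' the series edges.
#'
#' When the window is at least as long as the series, every window spans
#' the whole series and the filter reduces to repair against the global
#' median and MAD.
#'
#' @param x Numeric vector, no missing values.
#' @param half_window Half window length in samples.
#' @param n_mad Rejection threshold in MADs (default 3.5).
#' @param mad_scale Scale factor applied to the MAD; the default 1.4826
#'   makes it a consistent estimate of the Gaussian sd, set to 1 for the
#'   unscaled variant.
#' @return Repaired numeric vector.
#' @examples
#' hampel_filter(c(0, 0, 0, 100, 0, 0, 0), half_window = 3)
#' @export
hampel_filter <- function(x, half_window, n_mad = 3.5, mad_scale = 1.4826) {
  stopifnot(half_window >= 1, !anyNA(x))
  n <- length(x)
  if (n < 3L) return(x)
  k <- 2L * as.integer(half_window) + 1L
  if (k >= n) {
    med <- rep(stats::median(x), n)
    madv <- rep(stats::median(abs(x - med)) * mad_scale, n)
  } else {
    med <- stats::runmed(x, k, endrule = "median")
    madv <- stats::runmed(abs(x - med), k, endrule = "median") * mad_scale
  }
  dev <- abs(x - med)
  bad <- dev > n_mad * madv
  x[bad] <- med[bad]
  x
}

#' Clean epoched gaze-position data
#'
#' Per block: missing samples are replaced by the block's median
#' coordinates, outliers are repaired with a Hampel filter
#' ([hampel_filter()], half window 6 s, 3.5 MADs), traces are smoothed with
#' a 100 ms moving average, and the block's first trial is dropped (to
#' absorb any systematic timing inaccuracy at block start). When epochs
#' are shorter than the nominal Hampel window, the filter reduces to
#' repair against the epoch's global median and MAD (see
#' [hampel_filter()]).
#'
#' @param g A `gaze_epochs` object.
#' @param half_window_s Hampel half window in seconds (default 6).
#' @param n_mad Hampel threshold in MADs (default 3.5).
#' @param mad_scale MAD scale factor (see [hampel_filter()]).
#' @param smooth_ms Moving-average window (ms, default 100).
#' @param drop_first Drop each block's first trial?
#' @return The cleaned `gaze_epochs` (no missing samples).
#' @export
clean_gaze_epochs <- function(g, half_window_s = 6, n_mad = 3.5,
                              mad_scale = 1.4826, smooth_ms = 100,
                              drop_first = TRUE) {
  stopifnot(inherits(g, "gaze_epochs"))
  dat <- g$data
  blocks <- g$trials$block
  for (b in unique(blocks)) {
    bi <- which(blocks == b)
    for (co in 1:2) {
      seg <- dat[bi, co, , drop = FALSE]
      if (all(is.na(seg)))
        stop("block ", b, " coordinate ", c("x", "y")[co],
             " is entirely missing")
      bm <- stats::median(seg, na.rm = TRUE)
      seg[is.na(seg)] <- bm
      hw <- as.integer(half_window_s * g$srate)
      k_smooth <- max(1L, as.integer(round(smooth_ms * g$srate / 1000)))
      for (i in seq_along(bi)) {
        v <- hampel_filter(seg[i, 1, ], hw, n_mad, mad_scale)
        seg[i, 1, ] <- mov_avg(v, k_smooth)
      }
      dat[bi, co, ] <- seg
    }
  }
  g$data <- dat
  if (drop_first) {
    first <- !duplicated(blocks)
    keep <- !first
    g$data <- g$data[keep, , , drop = FALSE]
    g$trials <- g$trials[keep, ]
  }
  g
}
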