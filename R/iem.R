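# Inverted encoding model core: basis set over six orientation channels,
# least-squares weight estimation, model inversion, circular centering and
# reconstruction fidelity.

#' Construct an orientation channel basis set
#'
#' Models each orientation channel's tuning as a half-wave-rectified
#' sinusoid raised to a power (default 6): with the default `"half"` wrap
#' the response at circular orientation distance `d` (wrapped into
#' (-90, 90] degrees) is `max(0, cos(pi d / 180))^exponent`, which peaks at
#' 1 for the preferred orientation and falls to 0 at +/-90 degrees; here the
#' rectification is vacuous because the cosine is non-negative on that
#' range. The alternative `"full"` wrap treats the orientation axis as a
#' full 360-degree circle (differences wrapped into (-180, 180]) so the
#' rectification clips the far half of the circle to zero.
#'
#' @param orientations Channel centers in degrees (distinct modulo 180).
#' @param exponent Power applied to the rectified sinusoid.
#' @param wrap `"half"` (180-degree circular distance; default) or
#'   `"full"` (360-degree wrap).
#' @return An object of class `iem_basis`.
#' @examples
#' b <- make_basis()
#' basis_responses(b, c(10, 100))
#' @export
make_basis <- function(orientations = default_orientations(), exponent = 6,
                       wrap = c("half", "full")) {
  o <- check_orientations(orientations)
  wrap <- match.arg(wrap)
  K <- length(o)
  spacing <- if (K > 1) 180 / K else 180
  structure(list(centers = o, exponent = exponent, wrap = wrap,
                 spacing = spacing,
                 delta_grid = seq(-90, 90 - spacing, by = spacing)),
            class = "iem_basis")
}

#' @export
print.iem_basis <- function(x, ...) {
  cat("Orientation channel basis set\n")
  cat("  channels:", paste0(x$centers, "°", collapse = ", "), "\n")
  cat("  tuning:  rectified cos^", x$exponent, " (", x$wrap,
      "-circle wrap)\n", sep = "")
  invisible(x)
}

#' Predicted channel responses for a set of orientations
#'
#' @param basis An `iem_basis`.
#' @param orientations Stimulus orientations in degrees.
#' @return Matrix `C` of predicted responses, channels x trials.
#' @export
basis_responses <- function(basis, orientations) {
  stopifnot(inherits(basis, "iem_basis"))
  d <- outer(basis$centers, orientations, function(c, th) th - c)
  d <- if (basis$wrap == "half") wrap_ori(d) else ((d + 180) %% 360) - 180
  C <- pmax(0, cos(pi * d / 180))^basis$exponent
  dim(C) <- c(length(basis$centers), length(orientations))
  rownames(C) <- paste0("ch", basis$centers)
  C
}

#' Ideal centered tuning profile of a basis set
#'
#' The basis tuning function evaluated on the centered channel-offset grid
#' (for six channels: -90, -60, -30, 0, 30, 60 degrees), i.e. the profile a
#' perfect noiseless reconstruction would take after circular centering.
#'
#' @param basis An `iem_basis`.
#' @return Numeric vector of length equal to the number of channels.
#' @export
ideal_profile <- function(basis) {
  stopifnot(inherits(basis, "iem_basis"))
  d <- if (basis$wrap == "half") wrap_ori(basis$delta_grid) else basis$delta_grid
  as.numeric(pmax(0, cos(pi * d / 180))^basis$exponent)
}

#' Fit an inverted encoding model by least squares
#'
#' Estimates the electrodes x channels weight matrix W mapping predicted
#' channel responses to measured voltages, `B1 = W C1`, by least-squares
#' regression (`W = B1 C1' (C1 C1')^-1`, computed via a QR solve). The
#' fitted model can then be inverted with [predict.iem()] to reconstruct
#' channel responses from held-out data.
#'
#' @param B1 Training voltages, electrodes x trials.
#' @param orientations Stimulus orientation (degrees) per training trial.
#' @param basis An `iem_basis` (default: the six-channel set).
#' @param train_window Optional length-2 numeric recorded as metadata (ms).
#' @return An object of class `iem` with elements `W` (electrodes x
#'   channels), `basis`, `n_trials` and `train_window`.
#' @examples
#' b <- make_basis()
#' W <- matrix(rnorm(60 * 6), 60, 6)
#' th <- rep(default_orientations(), 20)
#' B <- W %*% basis_responses(b, th)
#' fit <- iem(B, th, b)
#' max(abs(coef(fit) - W))
#' @export
iem <- function(B1, orientations, basis = make_basis(), train_window = NULL) {
  B1 <- as.matrix(B1)
  stopifnot(ncol(B1) == length(orientations))
  C1 <- basis_responses(basis, orientations)
  qrC <- qr(t(C1))
  if (qrC$rank < nrow(C1)) {
    cover <- apply(C1, 1, function(r) max(abs(r)))
    bad <- rownames(C1)[cover < 1e-10]
    stop("channel prediction matrix is rank deficient; uncovered channels: ",
         if (length(bad)) paste(bad, collapse = ", ") else
           "(collinear channel predictions)")
  }
  W <- t(qr.coef(qrC, t(B1)))
  dimnames(W) <- list(rownames(B1), rownames(C1))
  structure(list(W = W, basis = basis, n_trials = ncol(B1),
                 train_window = train_window),
            class = "iem")
}

#' @export
print.iem <- function(x, ...) {
  cat("Inverted encoding model\n")
  cat("  electrodes:", nrow(x$W), "  channels:", ncol(x$W),
      "  training trials:", x$n_trials, "\n")
  if (!is.null(x$train_window))
    cat("  training window:", x$train_window[1], "-", x$train_window[2], "ms\n")
  invisible(x)
}

#' @export
coef.iem <- function(object, ...) object$W

#' Invert a fitted encoding model on new data
#'
#' Maps test voltages back into channel space,
#' `C2 = (W'W)^-1 W' B2` (a least-squares solve). With
#' `orientations` supplied the reconstructions are also circularly centered
#' on the true orientation via [center_responses()].
#'
#' @param object A fitted `iem`.
#' @param B2 Test voltages, electrodes x trials.
#' @param orientations Optional true orientations for centering.
#' @param ... Unused.
#' @return Channels x trials matrix of estimated channel responses
#'   (centered if `orientations` is given).
#' @export
predict.iem <- function(object, B2, orientations = NULL, ...) {
  B2 <- as.matrix(B2)
  stopifnot(nrow(B2) == nrow(object$W))
  qrW <- qr(object$W)
  if (qrW$rank < ncol(object$W))
    stop("estimated weight matrix is rank deficient; cannot invert")
  C2 <- qr.coef(qrW, B2)
  rownames(C2) <- colnames(object$W)
  if (!is.null(orientations))
    C2 <- center_responses(C2, orientations, object$basis)
  C2
}

#' Circularly center reconstructed channel responses
#'
#' Shifts each trial's channel-response vector so that the channel tuned to
#' the trial's true orientation lands on the 0-degree position of the
#' centered offset grid (index 4 of -90, -60, -30, 0, 30, 60 for six
#' channels).
#'
#' @param C2 Channels x trials matrix of reconstructed responses.
#' @param orientations True orientation per trial; each must equal a
#'   channel center.
#' @param basis The `iem_basis` defining channel centers.
#' @return Channels x trials matrix on the centered grid; rows are named by
#'   offset.
#' @export
center_responses <- function(C2, orientations, basis) {
  C2 <- as.matrix(C2)
  K <- length(basis$centers)
  stopifnot(nrow(C2) == K, ncol(C2) == length(orientations))
  idx <- match(orientations %% 180, basis$centers)
  if (anyNA(idx))
    stop("orientation(s) off the channel grid: ",
         paste(unique(orientations[is.na(idx)]), collapse = ", "))
  i0 <- which(basis$delta_grid == 0)
  out <- C2
  for (j in seq_len(ncol(C2))) {
    src <- ((seq_len(K) - i0 + idx[j] - 1L) %% K) + 1L
    out[, j] <- C2[src, j]
  }
  rownames(out) <- paste0("offset", basis$delta_grid)
  out
}

#' Reconstruction fidelity of a centered tuning profile
#'
#' Pearson correlation between a centered reconstructed channel-response
#' profile and the ideal basis profile ([ideal_profile()]), plus its Fisher
#' z transform (`atanh` with `r` clipped to |r| <= 1 - 1e-7). A
#' zero-variance profile has undefined fidelity and is returned as `NA`
#' with a warning.
#'
#' @param profile Centered channel-response vector (length = channels).
#' @param basis The `iem_basis`.
#' @return List with elements `r` and `z`.
#' @examples
#' b <- make_basis()
#' reconstruction_fidelity(ideal_profile(b), b)$r  # 1
#' @export
reconstruction_fidelity <- function(profile, basis) {
  p <- as.numeric(profile)
  ref <- ideal_profile(basis)
  stopifnot(length(p) == length(ref))
  if (stats::sd(p) == 0 || anyNA(p)) {
    warning("zero-variance or missing profile: fidelity undefined")
    return(list(r = NA_real_, z = NA_real_))
  }
  r <- stats::cor(p, ref)
  list(r = r, z = atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), r))))
}

# Average epoch voltages within a [start, end) ms window -> electrodes x trials.
window_average <- function(epochs, window_ms) {
  idx <- which(epochs$times >= window_ms[1] & epochs$times < window_ms[2])
  if (length(idx) == 0L) stop("window contains no samples")
  t(apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean))
}

#' Sliding-window leave-one-run-out IEM timecourse
#'
#' Trains and tests an IEM at each position of a window (default 100 ms)
#' slid in fixed steps (default 20 ms) across the epoch: voltages are
#' averaged within the window, the model is trained on all runs but one and
#' inverted on the held-out run (rotating over runs), reconstructions are
#' centered on each trial's orientation, averaged over trials, and scored
#' by [reconstruction_fidelity()]. Training and testing use the same time
#' window.
#'
#' @param epochs An `epoch_array` (see [simulate_eeg_epochs()],
#'   [preprocess_epochs()]); typically downsampled to 50 Hz first.
#' @param runs Run (block) label per trial; at least two distinct runs.
#' @param basis An `iem_basis`.
#' @param window_ms Averaging window length (ms).
#' @param step_ms Window step (ms); must be a multiple of the sample period.
#' @return List of class `iem_timecourse`: `time` (window start, ms), `r`,
#'   `z`, and `profiles` (windows x channels matrix of mean centered
#'   responses).
#' @export
iem_cv_timecourse <- function(epochs, runs, basis = make_basis(),
                              window_ms = 100, step_ms = 20) {
  stopifnot(inherits(epochs, "epoch_array"))
  runs <- as.factor(runs)
  if (nlevels(runs) < 2L)
    stop("leave-one-run-out cross-validation requires at least 2 runs")
  dt <- 1000 / epochs$srate
  if (step_ms %% dt != 0 || window_ms %% dt != 0)
    stop("window_ms and step_ms must be multiples of the sample period (",
         dt, " ms)")
  wlen <- as.integer(window_ms / dt)
  step <- as.integer(step_ms / dt)
  S <- length(epochs$times)
  if (wlen > S) stop("window longer than epoch")
  starts <- seq(1L, S - wlen + 1L, by = step)
  th <- epochs$trials$orientation
  K <- length(basis$centers)
  prof <- matrix(NA_real_, length(starts), K)
  r <- z <- numeric(length(starts))
  for (w in seq_along(starts)) {
    idx <- starts[w]:(starts[w] + wlen - 1L)
    Bw <- t(apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean))
    cent <- matrix(NA_real_, K, ncol(Bw))
    for (lev in levels(runs)) {
      te <- runs == lev
      fit <- iem(Bw[, !te, drop = FALSE], th[!te], basis)
      cent[, te] <- predict(fit, Bw[, te, drop = FALSE], orientations = th[te])
    }
    prof[w, ] <- rowMeans(cent)
    fid <- reconstruction_fidelity(prof[w, ], basis)
    r[w] <- fid$r; z[w] <- fid$z
  }
  structure(list(time = epochs$times[starts], r = r, z = z, profiles = prof,
                 window_ms = window_ms, step_ms = step_ms),
            class = "iem_timecourse")
}

#' Train on a fixed window, test on every timepoint of another task
#'
#' Trains a single IEM on training epochs averaged within a fixed window
#' (default 940-1040 ms, the early-delay window of the delayed-recognition
#' task), then inverts it at every timepoint of the test epochs. Channel
#' outputs are smoothed with a centered moving average (default 80 ms)
#' before centering; for stitched test arrays the two segments are smoothed
#' separately because they are not continuous in time. Test trials are
#' centered on the supplied labels, which lets the same epochs be probed
#' for the current item (n), the previous item (n - 1) or the next item
#' (n + 1).
#'
#' @param train_epochs Training `epoch_array` (e.g. delayed recognition).
#' @param test_epochs Test `epoch_array` or `stitched_epochs`.
#' @param labels Orientation label per test trial used for centering.
#' @param basis An `iem_basis`.
#' @param train_window_ms Training window, ms (half-open `[start, end)`).
#' @param smooth_ms Moving-average window for channel outputs (ms).
#' @return List of class `iem_timecourse` with per-timepoint `time`, `r`,
#'   `z`, mean centered `profiles`, and the fitted `model`.
#' @export
iem_test_timecourse <- function(train_epochs, test_epochs, labels,
                                basis = make_basis(),
                                train_window_ms = c(940, 1040),
                                smooth_ms = 80) {
  stopifnot(inherits(train_epochs, "epoch_array"),
            inherits(test_epochs, "epoch_array"))
  B1 <- window_average(train_epochs, train_window_ms)
  fit <- iem(B1, train_epochs$trials$orientation, basis,
             train_window = train_window_ms)
  tc <- iem_apply_timecourse(fit, test_epochs, labels, smooth_ms)
  tc$model <- fit
  tc
}

# Invert a fitted IEM at every timepoint of `test_epochs`; shared by the
# fixed-window path and by pipeline re-use of an already fitted model.
iem_apply_timecourse <- function(fit, test_epochs, labels, smooth_ms = 80) {
  dat <- test_epochs$data
  n <- dim(dat)[1]; m <- dim(dat)[2]; S <- dim(dat)[3]
  stopifnot(length(labels) == n)
  basis <- fit$basis
  K <- length(basis$centers)
  # one solve for all trials x timepoints
  Bflat <- matrix(aperm(dat, c(2, 1, 3)), m, n * S)
  Cflat <- predict(fit, Bflat)
  Carr <- array(Cflat, c(K, n, S))
  # smooth channel outputs along time, per segment for stitched arrays
  segs <- attr(test_epochs, "segment") %||% rep(1L, S)
  kw <- max(1L, as.integer(round(smooth_ms * test_epochs$srate / 1000)))
  if (kw > 1L) {
    for (sg in unique(segs)) {
      si <- which(segs == sg)
      Cs <- Carr[, , si, drop = FALSE]
      Cm <- matrix(aperm(Cs, c(3, 1, 2)), length(si), K * n)
      Cm <- apply(Cm, 2, mov_avg, k = kw)
      Carr[, , si] <- aperm(array(Cm, c(length(si), K, n)), c(2, 3, 1))
    }
  }
  # circular centering for all trials and timepoints in one gather
  idx <- match(labels %% 180, basis$centers)
  if (anyNA(idx))
    stop("label orientation(s) off the channel grid")
  i0 <- which(basis$delta_grid == 0)
  src <- outer(seq_len(K) - i0, idx - 1L, "+") %% K + 1L # K x n
  lin2d <- as.vector(src + (col(src) - 1L) * K)          # within one slice
  lin <- outer(lin2d, (seq_len(S) - 1L) * (K * n), "+")
  cent <- array(Carr[lin], c(K, n, S))
  prof <- t(matrix(colMeans(aperm(cent, c(2, 1, 3))), K, S)) # S x K
  # vectorized Pearson correlation of each profile with the ideal profile
  ref <- ideal_profile(basis)
  pm <- rowMeans(prof)
  num <- prof %*% ref - K * pm * mean(ref)
  den <- sqrt((rowSums(prof^2) - K * pm^2) * (sum(ref^2) - K * mean(ref)^2))
  r <- as.vector(num) / as.vector(den)
  r[!is.finite(r)] <- NA_real_
  z <- atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), r)))
  structure(list(time = test_epochs$times, r = r, z = z, profiles = prof,
                 smooth_ms = smooth_ms,
                 segment = attr(test_epochs, "segment")),
            class = "iem_timecourse")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.iem_timecourse <- function(x, ...) {
  cat("IEM reconstruction timecourse:", length(x$time), "timepoints, ",
      sprintf("fidelity r in [%.3f, %.3f]\n", min(x$r, na.rm = TRUE),
              max(x$r, na.rm = TRUE)))
  invisible(x)
}

#' Plot an IEM reconstruction timecourse
#'
#' @param x An `iem_timecourse`.
#' @param what `"fidelity"` (z over time) or `"profiles"` (channel-offset
#'   heatmap).
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.iem_timecourse <- function(x, what = c("fidelity", "profiles"), ...) {
  what <- match.arg(what)
  if (what == "fidelity") {
    plot(x$time, x$z, type = "l", xlab = "time (ms)",
         ylab = "fidelity (Fisher z)", ...)
    graphics::abline(h = 0, lty = 3)
  } else {
    graphics::image(x$time, seq_len(ncol(x$profiles)), x$profiles,
                    xlab = "time (ms)", ylab = "channel offset index", ...)
  }
  invisible(x)
}
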