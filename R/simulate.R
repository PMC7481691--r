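# Forward-model simulation of epoched EEG and gaze traces with a known
# priority-dependent representational state (perceptual / remapped / silent).

#' Ground-truth linear forward model
#'
#' Random electrodes x channels weight matrix `W` (full column rank almost
#' surely) plus the noise model: per-electrode Gaussian noise with lag-1
#' autocorrelation `ar`. `noise_sd` may be given directly, or calibrated at
#' simulation time from a target signal-to-noise ratio (`snr` = RMS of the
#' signal over RMS of the noise, per electrode, averaged over electrodes,
#' evaluated over the timepoints where the signal envelope is non-zero).
#'
#' @param n_electrodes Number of electrodes (default 60).
#' @param basis An `iem_basis` fixing the number of channels.
#' @param noise_sd Noise standard deviation (ignored when `snr` is given).
#' @param snr Optional target SNR; the study-condition preset is 0.15.
#' @param ar Lag-1 noise autocorrelation in [0, 1).
#' @param seed Integer seed or `NULL`.
#' @return Object of class `forward_model`.
#' @export
forward_model <- function(n_electrodes = 60, basis = make_basis(),
                          noise_sd = 1, snr = NULL, ar = 0.3, seed = NULL) {
  stopifnot(n_electrodes >= 1, noise_sd > 0, ar >= 0, ar < 1)
  K <- length(basis$centers)
  W <- with_seed(seed, matrix(stats::rnorm(n_electrodes * K), n_electrodes, K))
  rownames(W) <- sprintf("E%02d", seq_len(n_electrodes))
  colnames(W) <- paste0("ch", basis$centers)
  structure(list(W = W, noise_sd = noise_sd, snr = snr, ar = ar,
                 electrodes = rownames(W)),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat("Ground-truth forward model:", nrow(x$W), "electrodes x", ncol(x$W),
      "channels\n")
  if (!is.null(x$snr)) cat("  target SNR:", x$snr, "\n")
  else cat("  noise sd:", x$noise_sd, "\n")
  cat("  AR(1) noise coefficient:", x$ar, "\n")
  invisible(x)
}

#' Representational state schedule for an epoch
#'
#' Piecewise schedule of representational states across an epoch, for the
#' item presented in the epoch (`current`) and the item one position back
#' (`previous`). States: `perceptual` (pattern `W c(orientation)`),
#' `remapped` (channel responses circularly shifted by 90 degrees, the
#' hypothesized unprioritized-memory format) and `silent` (no signal). The
#' defaults mirror the hypothesized priority trajectory of each task:
#' \describe{
#'   \item{2back}{item n is perceptual from onset to 1150 ms, then remapped
#'     (unprioritized) for the rest of the epoch, while item n - 1 becomes
#'     perceptual (prioritized) from 1150 ms at gain 0.7.}
#'   \item{1back}{item n stays perceptual throughout (it is prioritized
#'     during its whole interstimulus interval).}
#'   \item{dr}{the sample is perceptual across the delay.}
#'   \item{localizer}{perceptual from onset to 500 ms, silent afterwards.}
#' }
#'
#' @param task One of `"2back"`, `"1back"`, `"dr"`, `"localizer"`.
#' @return Data frame of class `state_schedule` with columns `component`
#'   (`current`/`previous`), `start`, `end` (ms), `state`, `gain`.
#' @export
state_schedule <- function(task = c("2back", "1back", "dr", "localizer")) {
  task <- match.arg(task)
  rows <- switch(task,
    "2back" = data.frame(
      component = c("current", "current", "previous"),
      start = c(0, 1150, 1150), end = c(1150, 3550, 3550),
      state = c("perceptual", "remapped", "perceptual"),
      gain = c(1, 1, 0.7)),
    "1back" = data.frame(component = "current", start = 0, end = 3550,
                         state = "perceptual", gain = 1),
    "dr" = data.frame(component = "current", start = 0, end = 2750,
                      state = "perceptual", gain = 1),
    "localizer" = data.frame(component = "current", start = 0, end = 500,
                             state = "perceptual", gain = 1))
  class(rows) <- c("state_schedule", "data.frame")
  rows
}

#' Remap channel responses by a circular shift
#'
#' Circularly shifts the channel dimension of a channel-response matrix (or
#' profile vector) by `shift_deg` of orientation, which must be a multiple
#' of the channel spacing (30 degrees for the default six-channel set). A
#' 90-degree shift realizes the 'opposite' representational format of an
#' unprioritized item; a 0- or 180-degree shift is the identity
#' (orientation is 180-degree periodic). Energy is preserved.
#'
#' @param C Channels x trials matrix, or a channel profile vector.
#' @param shift_deg Shift in degrees of orientation.
#' @param spacing Channel spacing in degrees (default 30).
#' @return Shifted matrix or vector of the same shape.
#' @examples
#' b <- make_basis()
#' cor(ideal_profile(b), remap_channels(ideal_profile(b), 90))  # ~ -0.726
#' @export
remap_channels <- function(C, shift_deg, spacing = 30) {
  if (shift_deg %% spacing != 0)
    stop("shift_deg must be a multiple of the channel spacing (", spacing,
         " degrees)")
  k <- as.integer((shift_deg / spacing) %% (180 / spacing))
  if (is.matrix(C)) {
    K <- nrow(C)
    # new row i takes the response of the channel k positions back
    C[((seq_len(K) - 1L - k) %% K) + 1L, , drop = FALSE]
  } else {
    K <- length(C)
    C[((seq_len(K) - 1L - k) %% K) + 1L]
  }
}

new_epoch_array <- function(data, times, srate, trials, electrodes = NULL) {
  structure(list(data = data, times = times, srate = srate, trials = trials,
                 electrodes = electrodes %||% sprintf("E%02d", seq_len(dim(data)[2]))),
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("Epoch array:", d[1], "trials x", d[2], "electrodes x", d[3],
      "timepoints @", x$srate, "Hz,",
      sprintf("t = [%g, %g] ms\n", min(x$times), max(x$times) + 1000 / x$srate))
  invisible(x)
}

# Lag-1 autocorrelated Gaussian noise, stationary with marginal sd = sd,
# array n x m x S; the recursion is vectorized across series.
ar1_noise <- function(n, m, S, sd, ar) {
  x <- matrix(stats::rnorm(S * n * m, sd = sd), n * m, S)
  if (ar > 0 && S > 1L) {
    c2 <- sqrt(1 - ar^2)
    for (s in 2:S) x[, s] <- ar * x[, s - 1L] + c2 * x[, s]
  }
  array(x, c(n, m, S))
}

#' Simulate epoched multichannel EEG from the forward model
#'
#' For each trial and timepoint the signal is
#' `gain(state, t) * W_state %*% c(orientation) + noise`, where `W_state`
#' applies [remap_channels()] for the `remapped` state and zero gain for
#' `silent`; the `previous` component uses the orientation of the item one
#' position earlier in the block (absent for each block's first item).
#' Noise is lag-1 autocorrelated Gaussian, independent across electrodes.
#' When the forward model carries a target `snr`, the noise sd is
#' calibrated so that mean per-electrode RMS(signal)/RMS(noise) over the
#' non-silent timepoints equals it.
#'
#' @param trials A `trial_table` for the block(s).
#' @param fm A `forward_model`.
#' @param schedule A `state_schedule` (defaults to the schedule for
#'   `trials$task[1]`).
#' @param basis An `iem_basis` whose centers match the trial orientations.
#' @param srate Sampling rate of the emitted epochs (Hz).
#' @param tmin,tmax Epoch bounds relative to stimulus onset (ms).
#' @param seed Integer seed or `NULL`.
#' @return An `epoch_array` (trials x electrodes x timepoints, uV-scale
#'   arbitrary units) with the ground-truth model in attributes
#'   `forward_model` and `schedule`.
#' @export
simulate_eeg_epochs <- function(trials, fm, schedule = NULL,
                                basis = make_basis(), srate = 250,
                                tmin = -200, tmax = 3550, seed = NULL) {
  stopifnot(inherits(trials, "trial_table"), inherits(fm, "forward_model"))
  if (is.null(schedule)) schedule <- state_schedule(trials$task[1])
  if (!all(trials$orientation %% 180 %in% basis$centers))
    stop("trial orientations do not align with the basis channel centers")
  dt <- 1000 / srate
  times <- seq(tmin, tmax - dt, by = dt)
  S <- length(times)
  n <- nrow(trials)
  m <- nrow(fm$W)
  prev <- c(NA, trials$orientation[-n])
  prev[c(TRUE, trials$block[-1] != trials$block[-n])] <- NA

  sig <- array(0, c(n, m, S))
  active <- rep(FALSE, S)
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    if (row$state == "silent" || row$gain == 0) next
    idx <- which(times >= row$start & times < row$end)
    if (length(idx) == 0L) next
    active[idx] <- TRUE
    th <- if (row$component == "current") trials$orientation else prev
    keep <- !is.na(th)
    if (!any(keep)) next
    C <- basis_responses(basis, th[keep])
    if (row$state == "remapped") C <- remap_channels(C, 90, basis$spacing)
    M <- t(fm$W %*% C) * row$gain          # trials x electrodes
    add <- array(outer(as.vector(M), rep(1, length(idx))),
                 c(sum(keep), m, length(idx)))
    sig[keep, , idx] <- sig[keep, , idx] + add
  }

  noise_sd <- fm$noise_sd
  if (!is.null(fm$snr)) {
    rms_e <- sqrt(apply(sig[, , active, drop = FALSE]^2, 2, mean))
    noise_sd <- mean(rms_e) / fm$snr
    if (!is.finite(noise_sd) || noise_sd <= 0) noise_sd <- fm$noise_sd
  }
  eps <- with_seed(seed, ar1_noise(n, m, S, 1, fm$ar)) * noise_sd
  out <- new_epoch_array(sig + eps, times, srate, trials,
                         electrodes = fm$electrodes)
  attr(out, "forward_model") <- fm
  attr(out, "schedule") <- schedule
  attr(out, "noise_sd") <- noise_sd
  out
}

new_gaze_epochs <- function(data, times, srate, trials) {
  structure(list(data = data, times = times, srate = srate, trials = trials,
                 electrodes = c("x", "y")),
            class = c("gaze_epochs", "epoch_array"))
}

#' Simulate epoched 2-D gaze traces
#'
#' Per-trial horizontal/vertical gaze position in degrees of visual angle.
#' During `signal_window` the mean position is displaced from fixation by
#' `offset_dva` along a direction determined by the stimulus orientation
#' (the 180-degree orientation space is mapped onto 360 degrees of gaze
#' directions, so all six classes have distinct, equidistant means with a
#' shared covariance). Noise is a slow AR(1) drift plus white measurement
#' noise, shared across classes; spike outliers and missing samples are
#' injected at the stated rates.
#'
#' @param trials A `trial_table`.
#' @param offset_dva Class-mean displacement (degrees visual angle).
#' @param noise_sd Drift innovation scale is derived from this marginal sd.
#' @param drift_ar AR(1) coefficient of the drift at the simulation rate.
#' @param white_sd Additional white measurement noise sd.
#' @param signal_window Window (ms) during which the class mean is applied.
#' @param spike_rate,spike_sd Outlier probability per sample and amplitude.
#' @param missing_rate Probability a sample is missing (`NA`).
#' @param srate Sampling rate (Hz).
#' @param tmin,tmax Epoch bounds (ms).
#' @param label Orientation labels determining the class means (defaults to
#'   `trials$orientation`; pass the lagged orientation to put the previous
#'   item's signal in gaze instead).
#' @param seed Integer seed or `NULL`.
#' @return A `gaze_epochs` object (trials x 2 x timepoints).
#' @export
simulate_gaze_epochs <- function(trials, offset_dva = 0.15, noise_sd = 0.2,
                                 drift_ar = 0.99, white_sd = 0.05,
                                 signal_window = c(1150, 3150),
                                 spike_rate = 0.002, spike_sd = 3,
                                 missing_rate = 0.002, srate = 1000,
                                 tmin = -200, tmax = 3550,
                                 label = NULL, seed = NULL) {
  stopifnot(inherits(trials, "trial_table"),
            spike_rate >= 0, spike_rate < 1, missing_rate >= 0, missing_rate < 1)
  dt <- 1000 / srate
  times <- seq(tmin, tmax - dt, by = dt)
  S <- length(times)
  n <- nrow(trials)
  th <- label %||% trials$orientation
  ang <- 2 * th * pi / 180
  mu <- cbind(cos(ang), sin(ang)) * offset_dva
  win <- times >= signal_window[1] & times < signal_window[2]
  with_seed(seed, {
    dat <- array(0, c(n, 2, S))
    drift <- ar1_noise(n, 2, S, 1, drift_ar) * noise_sd
    white <- array(stats::rnorm(n * 2 * S, sd = white_sd), c(n, 2, S))
    dat <- drift + white
    dat[, 1, win] <- dat[, 1, win] + mu[, 1]
    dat[, 2, win] <- dat[, 2, win] + mu[, 2]
    if (spike_rate > 0) {
      sp <- which(stats::runif(length(dat)) < spike_rate)
      dat[sp] <- dat[sp] + stats::rnorm(length(sp), sd = spike_sd)
    }
    if (missing_rate > 0) {
      dat[stats::runif(length(dat)) < missing_rate] <- NA_real_
    }
    new_gaze_epochs(dat, times, srate, trials)
  })
}

#' Simulate a full synthetic session for one subject
#'
#' Generates trial tables, EEG epochs and gaze epochs for the requested
#' tasks under a single subject-level forward model, with child seeds split
#' deterministically per task via [child_seed()].
#'
#' @param seed Subject seed.
#' @param tasks Character vector among `"2back"`, `"1back"`, `"dr"`,
#'   `"localizer"`.
#' @param blocks Number of blocks per task (single number or named vector).
#' @param snr Target EEG signal-to-noise ratio (default preset 0.15).
#' @param eeg_srate,gaze_srate Simulation sampling rates (Hz).
#' @param gaze Logical: simulate gaze traces as well?
#' @param basis An `iem_basis`.
#' @param ... Passed on to [simulate_gaze_epochs()].
#' @return List of class `synthetic_session` with one element per task,
#'   each holding `trials`, `eeg` and optionally `gaze`, plus the
#'   ground-truth `forward_model` and the `seed`.
#' @export
simulate_session <- function(seed, tasks = c("dr", "2back"), blocks = 1,
                             snr = 0.15, eeg_srate = 250, gaze_srate = 1000,
                             gaze = FALSE, basis = make_basis(), ...) {
  if (length(blocks) == 1L) blocks <- stats::setNames(rep(blocks, length(tasks)), tasks)
  fm <- forward_model(60, basis, snr = snr, seed = child_seed(seed, 0, "fm"))
  out <- list(forward_model = fm, seed = seed)
  for (task in tasks) {
    tt <- do.call(rbind, lapply(seq_len(blocks[[task]]), function(b) {
      sd_b <- child_seed(seed, b, paste0("design_", task))
      switch(task,
        "2back" = generate_nback_sequence(basis$centers, 2L, 128L, sd_b, block = b),
        "1back" = generate_nback_sequence(basis$centers, 1L, 127L, sd_b, block = b),
        "dr" = generate_dr_block(basis$centers, sd_b, block = b),
        "localizer" = generate_localizer_block(basis$centers, sd_b, block = b))
    }))
    tt <- new_trial_table(tt)
    tmax <- switch(task, "dr" = 2750, "localizer" = 1000, 3550)
    ee <- simulate_eeg_epochs(tt, fm, basis = basis, srate = eeg_srate,
                              tmax = tmax,
                              seed = child_seed(seed, 0, paste0("eeg_", task)))
    el <- list(trials = tt, eeg = ee)
    if (gaze) {
      el$gaze <- simulate_gaze_epochs(tt, srate = gaze_srate, tmax = tmax,
                                      signal_window = if (task == "dr")
                                        c(1000, 2000) else c(1150, 3150),
                                      seed = child_seed(seed, 0, paste0("gaze_", task)),
                                      ...)
    }
    out[[task]] <- el
  }
  class(out) <- "synthetic_session"
  out
}
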