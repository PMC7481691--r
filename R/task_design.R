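# Task-design generators: 2-back / 1-back sequences, delayed recognition,
# functional localizer, and jittered interval sampling.

#' Default grating orientation set
#'
#' The six stimulus orientations used throughout: 10, 40, 70, 100, 130 and
#' 160 degrees, equally spaced (30 degrees) on the 180-degree orientation
#' circle, avoiding cardinal orientations.
#'
#' @return Numeric vector of six orientations in degrees.
#' @export
default_orientations <- function() c(10, 40, 70, 100, 130, 160)

check_orientations <- function(orientations) {
  stopifnot(is.numeric(orientations), length(orientations) >= 1L)
  o <- orientations %% 180
  if (anyDuplicated(o)) stop("orientations must be distinct modulo 180")
  o
}

#' Stimulus-match condition pool for the N-back tasks
#'
#' Each N-back block draws its items from a pool of (orientation, match
#' status) pairs with 7 'match' and 14 'non-match' entries per orientation
#' (126 pairs for the six-orientation set), so matches occur on one third of
#' the scoreable items.
#'
#' @param orientations Orientation set in degrees.
#' @param n_match Match entries per orientation (default 7).
#' @param n_nonmatch Non-match entries per orientation (default 14).
#' @return Data frame with columns `orientation`, `match_status` and
#'   `count` (multiplicity).
#' @export
condition_pool <- function(orientations = default_orientations(),
                           n_match = 7L, n_nonmatch = 14L) {
  o <- check_orientations(orientations)
  data.frame(
    orientation = rep(o, each = 2L),
    match_status = rep(c("match", "non-match"), length(o)),
    count = rep(c(n_match, n_nonmatch), length(o))
  )
}

new_trial_table <- function(df) {
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Generate a constrained N-back stimulus sequence
#'
#' Builds one block of a continuous-performance N-back task by constrained
#' sampling without replacement from the stimulus-match condition pool
#' ([condition_pool()]): the first `nback_level` warm-up items are drawn
#' uniformly from the orientation set (match status undefined, `NA`), and
#' each subsequent item is drawn from the remaining pool entries that are
#' feasible given the item `nback_level` positions back. A 'match' entry is
#' feasible only for the orientation presented `nback_level` items earlier;
#' its selection weight is `(K - 1)` times its remaining multiplicity so the
#' expected match rate stays at one third and lag-1 transitions between
#' orientations are uniform. No orientation may occur as a match more than
#' two consecutive times (counting consecutive match events, so a sequence
#' like "A B A C A" where A matches three times running is rejected). Dead
#' ends trigger a bounded restart.
#'
#' Inter-stimulus intervals are drawn per item from the 2800-3200 ms grid in
#' 50 ms steps; each item shows for 500 ms, followed by a 50 ms gap and a
#' 200 ms mask.
#'
#' @param orientations Orientation set in degrees.
#' @param nback_level N-back level (2 for 2-back, 1 for 1-back).
#' @param n_items Number of items in the block (128 for 2-back, 127 for
#'   1-back).
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @param max_restarts Bound on restart attempts before failing.
#' @param isi_range,isi_step Jitter grid for the post-mask interval (ms).
#' @param block,task Identifiers recorded on every row.
#' @return A `trial_table` data frame with one row per item: `position`
#'   (0-based), `orientation`, `match_status`, `onset`, `stim_ms`, `gap_ms`,
#'   `mask_ms`, `isi_ms`, `probe_orientation` (`NA` for N-back), `block`,
#'   `task`.
#' @examples
#' tt <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 1)
#' table(tt$match_status)
#' @export
generate_nback_sequence <- function(orientations = default_orientations(),
                                    nback_level, n_items, seed = NULL,
                                    max_restarts = 10000L,
                                    isi_range = c(2800, 3200), isi_step = 50,
                                    block = 1L, task = paste0(nback_level, "back")) {
  o <- check_orientations(orientations)
  nback_level <- as.integer(nback_level)
  n_items <- as.integer(n_items)
  stopifnot(nback_level >= 1L, n_items >= nback_level + 1L)
  K <- length(o)
  n_cond <- n_items - nback_level
  pool0 <- condition_pool(o)
  copies <- ceiling(n_cond / sum(pool0$count))

  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      match_left <- stats::setNames(rep(7L * copies, K), as.character(o))
      nm_left <- stats::setNames(rep(14L * copies, K), as.character(o))
      orient <- numeric(n_items)
      status <- rep(NA_character_, n_items)
      orient[seq_len(nback_level)] <- sample(o, nback_level, replace = TRUE)
      run_orient <- NA_real_ # orientation of the current run of match events
      run_len <- 0L
      ok <- TRUE
      for (i in (nback_level + 1L):n_items) {
        ref <- orient[i - nback_level]
        ref_key <- as.character(ref)
        cand_ori <- numeric(0)
        cand_sta <- character(0)
        cand_w <- numeric(0)
        match_allowed <- match_left[[ref_key]] > 0L &&
          !(run_len >= 2L && isTRUE(run_orient == ref))
        if (match_allowed) {
          cand_ori <- ref
          cand_sta <- "match"
          cand_w <- (K - 1) * match_left[[ref_key]]
        }
        for (th in o[o != ref]) {
          cnt <- nm_left[[as.character(th)]]
          if (cnt > 0L) {
            cand_ori <- c(cand_ori, th)
            cand_sta <- c(cand_sta, "non-match")
            cand_w <- c(cand_w, cnt)
          }
        }
        if (length(cand_ori) == 0L) { ok <- FALSE; break }
        j <- sample.int(length(cand_ori), 1L, prob = cand_w)
        orient[i] <- cand_ori[j]
        status[i] <- cand_sta[j]
        key <- as.character(cand_ori[j])
        if (cand_sta[j] == "match") {
          match_left[[key]] <- match_left[[key]] - 1L
          if (isTRUE(run_orient == cand_ori[j])) run_len <- run_len + 1L
          else { run_orient <- cand_ori[j]; run_len <- 1L }
        } else {
          nm_left[[key]] <- nm_left[[key]] - 1L
        }
      }
      if (ok) {
        isi <- sample_isi(isi_range[1], isi_range[2], isi_step, n = n_items)
        stim <- 500; gap <- 50; mask <- 200
        onset <- cumsum(c(0, (stim + gap + mask + isi)[-n_items]))
        return(new_trial_table(data.frame(
          position = 0:(n_items - 1L), orientation = orient,
          match_status = status, onset = onset, stim_ms = stim,
          gap_ms = gap, mask_ms = mask, isi_ms = isi,
          probe_orientation = NA_real_, block = block, task = task
        )))
      }
    }
    stop("could not satisfy the N-back pool/match constraints within ",
         max_restarts, " restarts (pool exhaustion dead end)")
  })
}

#' Generate one delayed-recognition block
#'
#' 72 sample-probe trials: each of the six orientations appears as the
#' sample on 12 trials, six paired with a matching probe and six with a
#' non-matching probe rotated 15 degrees clockwise or counterclockwise
#' (equiprobable), in randomized order. The sample shows for 500 ms,
#' followed by a 50 ms gap, a 200 ms mask, a 1500 ms delay and a 500 ms
#' probe; the intertrial interval is 300 ms of blank screen plus a fixation
#' period drawn from the 500-800 ms grid in 50 ms steps.
#'
#' @param orientations Orientation set (must have exactly six entries).
#' @param seed Integer seed or `NULL`.
#' @param block Block identifier.
#' @return A `trial_table` with probe information in `probe_orientation` and
#'   `match_status` giving the sample-probe relation.
#' @export
generate_dr_block <- function(orientations = default_orientations(),
                              seed = NULL, block = 1L) {
  o <- check_orientations(orientations)
  if (length(o) != 6L) stop("delayed recognition requires exactly 6 orientations")
  with_seed(seed, {
    samp <- rep(o, each = 12L)
    stat <- rep(rep(c("match", "non-match"), each = 6L), 6L)
    rot <- sample(c(-15, 15), 72L, replace = TRUE)
    probe <- ifelse(stat == "match", samp, (samp + rot) %% 180)
    ord <- sample.int(72L)
    samp <- samp[ord]; stat <- stat[ord]; probe <- probe[ord]
    fix <- sample_isi(500, 800, 50, n = 72L)
    stim <- 500; gap <- 50; mask <- 200; delay <- 1500; probe_ms <- 500
    resp <- 1500; blank <- 300
    dur <- stim + gap + mask + delay + probe_ms + resp + blank + fix
    onset <- cumsum(c(0, dur[-72L]))
    new_trial_table(data.frame(
      position = 0:71, orientation = samp, match_status = stat,
      onset = onset, stim_ms = stim, gap_ms = gap, mask_ms = mask,
      isi_ms = delay, probe_orientation = probe, block = block, task = "dr"
    ))
  })
}

#' Generate one functional-localizer block
#'
#' 120 passive-viewing trials (20 per orientation, shuffled), each grating
#' shown for 250 ms with a 750 ms intertrial interval while the subject
#' monitors the fixation dot for brief flickers; the number of flicker
#' events in the block is drawn uniformly from 8 to 12 and recorded in the
#' `n_flickers` attribute (flicker onset times in `flicker_onsets`).
#'
#' @param orientations Orientation set (must have exactly six entries).
#' @param seed Integer seed or `NULL`.
#' @param block Block identifier.
#' @return A `trial_table` of 120 rows with attributes `n_flickers` and
#'   `flicker_onsets`.
#' @export
generate_localizer_block <- function(orientations = default_orientations(),
                                     seed = NULL, block = 1L) {
  o <- check_orientations(orientations)
  if (length(o) != 6L) stop("the localizer requires exactly 6 orientations")
  with_seed(seed, {
    orient <- sample(rep(o, each = 20L))
    onset <- (0:119) * 1000
    tt <- new_trial_table(data.frame(
      position = 0:119, orientation = orient, match_status = NA_character_,
      onset = onset, stim_ms = 250, gap_ms = 0, mask_ms = 0, isi_ms = 750,
      probe_orientation = NA_real_, block = block, task = "localizer"
    ))
    n_fl <- sample(8:12, 1L)
    attr(tt, "n_flickers") <- n_fl
    attr(tt, "flicker_onsets") <- sort(stats::runif(n_fl, 0, 120000))
    tt
  })
}

#' Sample jittered durations from a uniform grid
#'
#' Draws durations uniformly from the grid `lo, lo + step, ..., hi`, the
#' convention used for all jittered intervals in the task designs (e.g. the
#' 2800-3200 ms post-mask interval, or the 500-800 ms intertrial fixation).
#'
#' @param lo_ms,hi_ms Grid endpoints in ms (`hi_ms - lo_ms` must be a
#'   multiple of `step_ms`).
#' @param step_ms Grid increment in ms.
#' @param n Number of draws.
#' @param seed Integer seed or `NULL` (draw from the current stream).
#' @return Numeric vector of `n` durations.
#' @export
sample_isi <- function(lo_ms, hi_ms, step_ms, n = 1L, seed = NULL) {
  stopifnot(is.numeric(lo_ms), is.numeric(hi_ms), is.numeric(step_ms),
            step_ms > 0, hi_ms >= lo_ms)
  if ((hi_ms - lo_ms) %% step_ms != 0)
    stop("invalid jitter grid: (hi_ms - lo_ms) is not a multiple of step_ms")
  grid <- seq(lo_ms, hi_ms, by = step_ms)
  with_seed(seed, grid[sample.int(length(grid), n, replace = TRUE)])
}

#' Recompute N-back match status from the orientation column
#'
#' @param orientation Orientation sequence in degrees.
#' @param nback_level N-back level.
#' @return Character vector of "match"/"non-match" with `NA` for the first
#'   `nback_level` warm-up items.
#' @export
nback_match_status <- function(orientation, nback_level) {
  n <- length(orientation)
  out <- rep(NA_character_, n)
  if (n > nback_level) {
    i <- (nback_level + 1L):n
    out[i] <- ifelse(orientation[i] == orientation[i - nback_level],
                     "match", "non-match")
  }
  out
}

#' Write / read a trial table as tab-separated values
#'
#' Serializes a `trial_table` with BIDS-events-like columns (`onset`,
#' `duration`, `trial_type`, `orientation`, `match_status`, `block`,
#' `task`, plus the remaining design columns), UTF-8, one row per record.
#'
#' @param x A `trial_table`.
#' @param path Output path.
#' @return `write_trial_table` returns `path` invisibly; `read_trial_table`
#'   returns a `trial_table`.
#' @export
write_trial_table <- function(x, path) {
  stopifnot(inherits(x, "trial_table"))
  df <- data.frame(
    onset = x$onset, duration = x$stim_ms, trial_type = "stimulus",
    orientation = x$orientation, match_status = x$match_status,
    block = x$block, task = x$task, position = x$position,
    gap_ms = x$gap_ms, mask_ms = x$mask_ms, isi_ms = x$isi_ms,
    probe_orientation = x$probe_orientation
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", na = "n/a")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.delim(path, na.strings = "n/a", fileEncoding = "UTF-8")
  new_trial_table(data.frame(
    position = df$position, orientation = df$orientation,
    match_status = df$match_status, onset = df$onset,
    stim_ms = df$duration, gap_ms = df$gap_ms, mask_ms = df$mask_ms,
    isi_ms = df$isi_ms, probe_orientation = df$probe_orientation,
    block = df$block, task = df$task
  ))
}
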