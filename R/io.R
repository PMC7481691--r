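# Plain-text interchange: epoch arrays as TSV with a JSON sidecar recording
# shape, sampling rate and time-zero convention.

#' Write / read an epoch array as TSV plus JSON sidecar
#'
#' The array is flattened to one row per (trial, electrode) with one column
#' per timepoint; the sidecar (`<path>.json`) records dimensions, electrode
#' labels, sampling rate and the time axis (ms relative to stimulus onset);
#' the trial table is stored alongside as `<path>.trials.tsv`.
#'
#' @param e An `epoch_array` (or `gaze_epochs`).
#' @param path Output TSV path.
#' @return `write_epoch_array` returns `path` invisibly;
#'   `read_epoch_array` returns the reconstructed object.
#' @export
write_epoch_array <- function(e, path) {
  stopifnot(inherits(e, "epoch_array"))
  d <- dim(e$data)
  flat <- matrix(aperm(e$data, c(2, 1, 3)), d[1] * d[2], d[3])
  df <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                   electrode = rep(e$electrodes, d[1]))
  utils::write.table(cbind(df, as.data.frame(flat)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  side <- list(n_trials = d[1], n_electrodes = d[2], n_times = d[3],
               srate = e$srate, times_ms = e$times,
               time_zero = "stimulus onset", electrodes = e$electrodes,
               class = class(e)[1])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write_trial_table(new_trial_table(e$trials), paste0(path, ".trials.tsv"))
  invisible(path)
}

#' @rdname write_epoch_array
#' @export
read_epoch_array <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tab <- utils::read.delim(path)
  flat <- as.matrix(tab[, -(1:2)])
  d <- c(side$n_trials, side$n_electrodes, side$n_times)
  dat <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
  trials <- read_trial_table(paste0(path, ".trials.tsv"))
  out <- new_epoch_array(dat, side$times_ms, side$srate, trials,
                         electrodes = side$electrodes)
  if (identical(side$class, "gaze_epochs")) class(out) <- c("gaze_epochs", class(out))
  out
}
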