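# End-to-end orchestration: simulate -> preprocess -> decode -> infer ->
# report, as one reproducible, configured run.

#' Build a pipeline run configuration
#'
#' The desk-scale defaults (20 synthetic subjects, one block per task, EEG
#' simulated at 100 Hz and analysed at 50 Hz, 2000 permutation iterations)
#' complete in minutes on one CPU; raise `n_subjects`, `blocks`,
#' `eeg_srate` and `n_perm` for full-scale runs. The analysis windows are
#' the hypothesis windows: the unprioritized-item (UMI) window 1150-3150 ms
#' after item n's onset, the prioritized-item (PMI) window 1150-3150 ms
#' after item n + 1's onset (4900-6900 ms on the stitched axis), and the
#' same window for the 1-back control.
#'
#' @param seed Master seed; per-subject and per-stage seeds are derived
#'   with [child_seed()].
#' @param n_subjects Number of simulated subjects.
#' @param blocks Blocks per task (named vector over `2back`, `1back`,
#'   `dr`).
#' @param snr EEG signal-to-noise preset (default 0.15).
#' @param eeg_srate,gaze_srate Simulation sampling rates (Hz).
#' @param analysis_srate Rate EEG is downsampled to before modelling (Hz).
#' @param train_window Training window on the delayed-recognition task
#'   (ms).
#' @param umi_window,pmi_window UMI / PMI analysis windows on the stitched
#'   time axis (ms).
#' @param n_perm Sign-flip iterations for the cluster test.
#' @param alpha Two-tailed significance level.
#' @param oneback,gaze,cluster,gaze_timecourse Stage switches.
#' @param remap Simulate the 90-degree remapped unprioritized state? Set
#'   `FALSE` for the no-remapping negative control (item n stays
#'   perceptual).
#' @param out_dir Optional directory for serialized intermediates.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_subjects = 20,
                            blocks = c("2back" = 1, "1back" = 1, dr = 1),
                            snr = 0.15, eeg_srate = 100, gaze_srate = 250,
                            analysis_srate = 50,
                            train_window = c(940, 1040),
                            umi_window = c(1150, 3150),
                            pmi_window = c(4900, 6900),
                            n_perm = 2000, alpha = 0.05, oneback = TRUE,
                            gaze = TRUE, cluster = TRUE,
                            gaze_timecourse = FALSE, remap = TRUE,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration: seed", x$seed, "|", x$n_subjects,
      "subjects |", "SNR", x$snr, "|", x$n_perm, "permutations\n")
  invisible(x)
}

# 2-back schedule variant without the remapped state (negative control).
schedule_no_remap <- function() {
  s <- state_schedule("2back")
  s$state[s$state == "remapped"] <- "perceptual"
  s
}

#' Run the full synthetic N-back IEM pipeline
#'
#' For every simulated subject: generate the task designs, simulate EEG
#' (and optionally gaze) from a subject-specific forward model, preprocess
#' (baseline correction, median re-reference, downsampling), train the
#' early-delay IEM on the delayed-recognition task (940-1040 ms window),
#' test it on every timepoint of the stitched 2-back epochs labelled by
#' item n, and (optionally) on the 1-back epochs and on gaze windows. At
#' the group level: window-averaged one-sample t tests of Fisher-z
#' fidelity (UMI and PMI windows, FDR-corrected across the two), the
#' 1-back control window, a sign-flip cluster permutation test over the
#' stitched timecourse, and gaze decoding accuracy tested against chance
#' (1/6).
#'
#' The three principal analyses on the synthetic sessions are: the UMI
#' window should show negative fidelity under the remap schedule, the PMI
#' window positive fidelity, and the 1-back window positive fidelity.
#'
#' @param config A `pipeline_config`.
#' @return Object of class `nback_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  basis <- make_basis()
  sched2 <- if (config$remap) state_schedule("2back") else schedule_no_remap()
  z2 <- NULL
  z1 <- NULL
  gaze_rows <- list()
  umi_sub <- pmi_sub <- ob_sub <- numeric(config$n_subjects)
  times2 <- NULL

  for (s in seq_len(config$n_subjects)) {
    sseed <- child_seed(config$seed, s, "subject")
    fm <- forward_model(60, basis, snr = config$snr,
                        seed = child_seed(sseed, 0, "fm"))
    # delayed recognition: training task
    dr_tt <- do.call(rbind, lapply(seq_len(config$blocks[["dr"]]), function(b)
      generate_dr_block(basis$centers, child_seed(sseed, b, "dr"), block = b)))
    dr_tt <- new_trial_table(dr_tt)
    dr <- simulate_eeg_epochs(dr_tt, fm, state_schedule("dr"), basis,
                              srate = config$eeg_srate, tmax = 2750,
                              seed = child_seed(sseed, 0, "dr_eeg"))
    dr <- downsample_epochs(preprocess_epochs(dr), config$analysis_srate)
    # 2-back: test task
    tb_tt <- do.call(rbind, lapply(seq_len(config$blocks[["2back"]]), function(b)
      generate_nback_sequence(basis$centers, 2L, 128L,
                              child_seed(sseed, b, "2back"), block = b)))
    tb_tt <- new_trial_table(tb_tt)
    tb <- simulate_eeg_epochs(tb_tt, fm, sched2, basis,
                              srate = config$eeg_srate,
                              seed = child_seed(sseed, 0, "2back_eeg"))
    tb <- downsample_epochs(preprocess_epochs(tb), config$analysis_srate)
    st <- stitch_epochs(tb)
    tc <- iem_test_timecourse(dr, st, st$trials$orientation, basis,
                              train_window_ms = config$train_window)
    if (is.null(z2)) {
      z2 <- matrix(NA_real_, config$n_subjects, length(tc$time))
      times2 <- tc$time
    }
    z2[s, ] <- tc$z
    umi_sub[s] <- mean(tc$z[times2 >= config$umi_window[1] &
                              times2 <= config$umi_window[2]])
    pmi_sub[s] <- mean(tc$z[times2 >= config$pmi_window[1] &
                              times2 <= config$pmi_window[2]])

    if (config$oneback) {
      ob_tt <- do.call(rbind, lapply(seq_len(config$blocks[["1back"]]), function(b)
        generate_nback_sequence(basis$centers, 1L, 127L,
                                child_seed(sseed, b, "1back"), block = b)))
      ob_tt <- new_trial_table(ob_tt)
      ob <- simulate_eeg_epochs(ob_tt, fm, state_schedule("1back"), basis,
                                srate = config$eeg_srate,
                                seed = child_seed(sseed, 0, "1back_eeg"))
      ob <- downsample_epochs(preprocess_epochs(ob), config$analysis_srate)
      tco <- iem_test_timecourse(dr, ob, ob$trials$orientation, basis,
                                 train_window_ms = config$train_window)
      if (is.null(z1)) z1 <- matrix(NA_real_, config$n_subjects,
                                    length(tco$time))
      z1[s, ] <- tco$z
      ob_sub[s] <- mean(tco$z[tco$time >= 1150 & tco$time <= 3150])
    }

    if (config$gaze) {
      gz <- simulate_gaze_epochs(tb_tt, srate = config$gaze_srate,
                                 seed = child_seed(sseed, 0, "gaze"))
      gz <- clean_gaze_epochs(gz)
      lab_n <- gz$trials$orientation
      prev <- c(NA, gz$trials$orientation[-nrow(gz$trials)])
      prev[c(TRUE, gz$trials$block[-1] != gz$trials$block[-nrow(gz$trials)])] <- NA
      runs <- if (config$blocks[["2back"]] > 1) gz$trials$block else
        pseudo_runs(lab_n)
      dec_n <- gaze_decode_cv(gz, lab_n, runs,
                              windows = list(stimulus = c(0, 500),
                                             isi = c(1150, 3150)),
                              timecourse = config$gaze_timecourse)
      dec_p <- gaze_decode_cv(gz, prev, if (config$blocks[["2back"]] > 1)
        gz$trials$block else pseudo_runs(prev), windows = list(isi = c(1150, 3150)),
        timecourse = FALSE)
      gaze_rows[[s]] <- data.frame(
        subject = s,
        target = c("item_n", "item_n", "item_n_minus_1"),
        window = c("stimulus", "isi", "isi"),
        accuracy = c(dec_n$windows$accuracy, dec_p$windows$accuracy))
    }
  }

  windows2 <- window_average_test(
    cbind(umi_sub, pmi_sub), c(1, 2),
    list(umi = c(1, 1), pmi = c(2, 2)))
  windows2$start <- c(config$umi_window[1], config$pmi_window[1])
  windows2$end <- c(config$umi_window[2], config$pmi_window[2])

  oneback_test <- if (config$oneback) group_ttest(ob_sub) else NULL
  clusters <- if (config$cluster)
    cluster_permutation(z2, times2, n_perm = config$n_perm,
                        alpha = config$alpha,
                        seed = child_seed(config$seed, 0, "perm")) else NULL
  gaze_group <- NULL
  if (config$gaze) {
    gdf <- do.call(rbind, gaze_rows)
    gaze_group <- do.call(rbind, lapply(
      split(gdf, paste(gdf$target, gdf$window, sep = ":")), function(d) {
        res <- group_ttest(d$accuracy, mu = 1 / 6)
        data.frame(target = d$target[1], window = d$window[1],
                   mean_accuracy = mean(d$accuracy), t = res$t, p = res$p,
                   d = res$d)
      }))
    gaze_group$p_fdr <- stats::p.adjust(gaze_group$p, method = "BH")
    rownames(gaze_group) <- NULL
  }

  report <- structure(list(
    config = config, times = times2, z_2back = z2, z_1back = z1,
    umi_subject = umi_sub, pmi_subject = pmi_sub,
    oneback_subject = if (config$oneback) ob_sub else NULL,
    windows_2back = windows2, oneback_test = oneback_test,
    clusters = clusters, gaze_subject = if (config$gaze)
      do.call(rbind, gaze_rows) else NULL,
    gaze_group = gaze_group), class = "nback_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.nback_report <- function(x, ...) {
  cat("N-back IEM pipeline report (", x$config$n_subjects,
      " synthetic subjects, seed ", x$config$seed, ")\n\n", sep = "")
  cat("2-back window tests (Fisher-z fidelity vs 0, FDR across windows):\n")
  print(format(x$windows_2back, digits = 4), row.names = FALSE)
  if (!is.null(x$oneback_test))
    cat(sprintf("\n1-back ISI window: mean z = %.4f, t(%d) = %.3f, p = %.4g\n",
                x$oneback_test$mean, x$oneback_test$df, x$oneback_test$t,
                x$oneback_test$p))
  if (!is.null(x$clusters)) {
    cat("\nCluster permutation over the stitched timecourse:\n")
    print(x$clusters)
  }
  if (!is.null(x$gaze_group)) {
    cat("\nGaze decoding vs chance (1/6):\n")
    print(format(x$gaze_group, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a pipeline report's intermediates
#'
#' Writes the subject-level fidelity series, window statistics, cluster
#' table, gaze accuracies, configuration snapshot and a manifest as
#' TSV/JSON under `dir`.
#'
#' @param report An `nback_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  z2 <- data.frame(subject = rep(seq_len(nrow(report$z_2back)),
                                 each = ncol(report$z_2back)),
                   time = rep(report$times, nrow(report$z_2back)),
                   z = as.vector(t(report$z_2back)))
  wt(z2, "z_2back.tsv")
  if (!is.null(report$z_1back)) {
    z1 <- data.frame(subject = rep(seq_len(nrow(report$z_1back)),
                                   each = ncol(report$z_1back)),
                     time = rep(seq_len(ncol(report$z_1back)),
                                nrow(report$z_1back)),
                     z = as.vector(t(report$z_1back)))
    wt(z1, "z_1back.tsv")
  }
  wt(report$windows_2back, "windows_2back.tsv")
  if (!is.null(report$clusters)) wt(report$clusters$clusters, "clusters.tsv")
  if (!is.null(report$gaze_subject)) wt(report$gaze_subject, "gaze_accuracy.tsv")
  cfg <- report$config
  cfg$out_dir <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(files = list.files(dir), package = "nbackiem")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Regenerate group-level results from serialized intermediates
#'
#' Re-reads the subject-level intermediates written by [write_report()] and
#' recomputes the group statistics without re-running simulation or
#' decoding; with the stored configuration (including the permutation
#' seed) the result is identical on repeat.
#'
#' @param dir A run directory produced with `out_dir` set.
#' @return A list with `windows_2back`, `clusters` and `gaze_group`.
#' @export
regenerate_report <- function(dir) {
  need <- c("z_2back.tsv", "config.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing intermediate file(s): ", paste(missing, collapse = ", "))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  z2l <- utils::read.delim(file.path(dir, "z_2back.tsv"))
  subj <- sort(unique(z2l$subject))
  times <- sort(unique(z2l$time))
  z2 <- matrix(NA_real_, length(subj), length(times))
  for (s in seq_along(subj)) {
    d <- z2l[z2l$subject == subj[s], ]
    z2[s, ] <- d$z[order(d$time)]
  }
  umi <- rowMeans(z2[, times >= cfg$umi_window[1] & times <= cfg$umi_window[2]])
  pmi <- rowMeans(z2[, times >= cfg$pmi_window[1] & times <= cfg$pmi_window[2]])
  windows2 <- window_average_test(cbind(umi, pmi), c(1, 2),
                                  list(umi = c(1, 1), pmi = c(2, 2)))
  windows2$start <- c(cfg$umi_window[1], cfg$pmi_window[1])
  windows2$end <- c(cfg$umi_window[2], cfg$pmi_window[2])
  clusters <- if (isTRUE(cfg$cluster))
    cluster_permutation(z2, times, n_perm = cfg$n_perm, alpha = cfg$alpha,
                        seed = child_seed(cfg$seed, 0, "perm")) else NULL
  gaze_group <- NULL
  gf <- file.path(dir, "gaze_accuracy.tsv")
  if (file.exists(gf)) {
    gdf <- utils::read.delim(gf)
    gaze_group <- do.call(rbind, lapply(
      split(gdf, paste(gdf$target, gdf$window, sep = ":")), function(d) {
        res <- group_ttest(d$accuracy, mu = 1 / 6)
        data.frame(target = d$target[1], window = d$window[1],
                   mean_accuracy = mean(d$accuracy), t = res$t, p = res$p,
                   d = res$d)
      }))
    gaze_group$p_fdr <- stats::p.adjust(gaze_group$p, method = "BH")
    rownames(gaze_group) <- NULL
  }
  list(windows_2back = windows2, clusters = clusters, gaze_group = gaze_group)
}
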