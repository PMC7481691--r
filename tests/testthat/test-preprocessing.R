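# Preprocessing: epoch cutting arithmetic, baseline correction, median
# re-referencing, downsampling, stitching and gaze cleaning.

test_that("a [-200, 3550) ms epoch at 50 Hz has 187 samples", {
  cont <- matrix(0, 3, 500)
  ev <- new_trial_table(data.frame(onset = c(1000, 5000), orientation = 10,
                                   block = 1))
  # at 50 Hz, 500 samples span 10000 ms
  ep <- epoch_data(cont, ev, srate = 50, rereference = FALSE)
  expect_equal(dim(ep$data), c(2L, 3L, 187L))
  expect_equal(ep$times[1], -200)
  expect_equal(ep$times[187], 3520)
  # events whose epochs leave the recording are rejected by trial index
  ev_bad <- new_trial_table(data.frame(onset = c(1000, 7900), orientation = 10,
                                       block = 1))
  expect_error(epoch_data(cont, ev_bad, srate = 50), "trial\\(s\\) 2")
})

test_that("epoch cutting extracts the right samples from a ramp", {
  cont <- rbind(seq_len(600), -seq_len(600)) # 2 electrodes, ramp signal
  ev <- new_trial_table(data.frame(onset = 2000, orientation = 10, block = 1))
  ep <- epoch_data(cont, ev, srate = 100, baseline = NULL,
                   rereference = FALSE)
  # onset 2000 ms at 100 Hz is sample 201; tmin -200 ms starts at sample 181
  expect_equal(dim(ep$data)[3], 375L)
  expect_equal(ep$data[1, 1, ], seq(181, length.out = 375))
  expect_equal(ep$data[1, 2, ], -seq(181, length.out = 375))
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- make_test_epochs(seed = 2)
  ep2 <- preprocess_epochs(ep, baseline = c(-200, 0), rereference = FALSE)
  bi <- ep$times >= -200 & ep$times < 0
  blm <- apply(ep2$data[, , bi, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(blm)), 1e-12)
  # correction subtracts a per-trial, per-electrode constant
  expect_equal(ep2$data[3, 4, ] - ep$data[3, 4, ],
               rep(ep2$data[3, 4, 1] - ep$data[3, 4, 1], 187))
  expect_error(preprocess_epochs(ep, baseline = c(-1000, -900)), "no samples")
})

test_that("median re-referencing matches the apply() oracle", {
  ep <- make_test_epochs(seed = 3) # 8 electrodes: even-count median
  ep2 <- preprocess_epochs(ep, baseline = NULL, rereference = TRUE)
  med <- apply(ep$data, c(1, 3), stats::median)
  for (e in c(1, 8))
    expect_equal(ep2$data[, e, ], ep$data[, e, ] - med)
  # after re-referencing the across-electrode median is zero everywhere
  expect_lt(max(abs(apply(ep2$data, c(1, 3), stats::median))), 1e-12)
})

test_that("downsampling averages non-overlapping bins and drops partial bins", {
  dat <- array(0, c(1, 1, 12))
  dat[1, 1, ] <- 1:12
  e <- structure(list(data = dat, times = seq(0, by = 4, length.out = 12),
                      srate = 250, trials = data.frame(orientation = 10,
                                                       block = 1),
                      electrodes = "E01"), class = "epoch_array")
  d <- downsample_epochs(e, 50) # factor 5: bins 1:5, 6:10; 11:12 dropped
  expect_equal(dim(d$data)[3], 2L)
  expect_equal(as.vector(d$data), c(3, 8))
  expect_equal(d$times, c(0, 20))
  expect_equal(d$srate, 50)
  expect_error(downsample_epochs(e, 60), "does not divide")
  expect_identical(downsample_epochs(e, 250), e)
})

test_that("a 100 ms moving average spreads an impulse over five 50 Hz samples", {
  x <- c(rep(0, 10), 1, rep(0, 10))
  y <- moving_average(x, 100, 50)
  expect_equal(sum(y > 0), 5L)
  expect_equal(max(y), 0.2)
  # windows truncate at the edges instead of padding
  expect_equal(moving_average(c(1, 0, 0, 0, 0), 100, 50)[1], 1 / 3)
})

test_that("stitching a 128-item block yields 125 two-epoch records", {
  ep <- with_seed(4, {
    tt <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 4)
    dat <- array(stats::rnorm(128 * 2 * 10), c(128, 2, 10))
    dat[, 1, 1] <- seq_len(128) # marker: trial index on electrode 1, sample 1
    structure(list(data = dat, times = seq(-200, by = 20, length.out = 10),
                   srate = 50, trials = tt, electrodes = c("E01", "E02")),
              class = "epoch_array")
  })
  st <- stitch_epochs(ep)
  expect_s3_class(st, "stitched_epochs")
  expect_equal(dim(st$data), c(125L, 2L, 20L))
  expect_equal(attr(st, "discontinuity"), 11L)
  expect_equal(attr(st, "segment"), rep(1:2, each = 10L))
  expect_equal(length(st$times), 20L)
  # record i holds item i+1 followed by item i+2 (first item excluded)
  expect_equal(st$data[, 1, 1], 2:126)
  expect_equal(st$data[, 1, 11], 3:127)
  expect_equal(st$trials$orientation, ep$trials$orientation[2:126])
  expect_equal(st$trials$orientation_prev, ep$trials$orientation[1:125])
  expect_equal(st$trials$orientation_next, ep$trials$orientation[3:127])
  tiny <- ep; tiny$trials <- ep$trials[1:3, ]; tiny$data <- ep$data[1:3, , , drop = FALSE]
  expect_error(stitch_epochs(tiny), "fewer than 4")
})

test_that("the Hampel filter repairs spikes and leaves clean traces alone", {
  expect_equal(hampel_filter(c(0, 0, 0, 100, 0, 0, 0), half_window = 3),
               rep(0, 7))
  # sliding-window path (window shorter than the series)
  x <- c(rep(0, 20), 50, rep(0, 20))
  expect_equal(hampel_filter(x, half_window = 5), rep(0, 41))
  # a linear trend passes through unchanged (every window median is the
  # center sample), and the repair is idempotent
  y <- seq(0, 10, length.out = 200)
  expect_equal(hampel_filter(y, half_window = 10), y)
  z <- hampel_filter(x, half_window = 5)
  expect_equal(hampel_filter(z, half_window = 5), z)
  expect_error(hampel_filter(c(1, NA, 3), half_window = 1), "anyNA")
})

test_that("gaze cleaning fills missing samples, removes spikes and drops first trials", {
  tt <- generate_nback_sequence(nback_level = 2, n_items = 16, seed = 9)
  g <- simulate_gaze_epochs(tt, srate = 50, spike_rate = 0.01, spike_sd = 30,
                            missing_rate = 0.01, seed = 9)
  expect_true(anyNA(g$data))
  gc <- clean_gaze_epochs(g)
  expect_false(anyNA(gc$data))
  expect_equal(nrow(gc$trials), 15L) # first trial of the block dropped
  expect_lt(max(abs(gc$data)), max(abs(g$data), na.rm = TRUE))
  # a block with one coordinate entirely missing is rejected
  g2 <- g
  g2$data[, 2, ] <- NA_real_
  expect_error(clean_gaze_epochs(g2), "entirely missing")
})
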