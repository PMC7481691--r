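# Synthetic session generator: remapping algebra, state schedules, forward
# simulation ground truth, SNR calibration and reproducibility.

test_that("channel remapping is a circular shift with the right identities", {
  p <- fix_ideal
  expect_equal(remap_channels(p, 0), p)
  expect_equal(remap_channels(p, 180), p) # orientation is 180-deg periodic
  expect_equal(remap_channels(remap_channels(p, 90), 90), p)
  expect_equal(sum(remap_channels(p, 90)^2), sum(p^2)) # energy preserved
  # matrix form shifts every column consistently with the vector form
  C <- basis_responses(fix_basis, c(10, 70))
  Cr <- remap_channels(C, 30)
  expect_equal(unname(Cr[, 1]), unname(remap_channels(C[, 1], 30)))
  expect_error(remap_channels(p, 45), "multiple of the channel spacing")
  # the remapped ideal profile anticorrelates with the ideal profile
  expect_equal(stats::cor(p, remap_channels(p, 90)), -0.7262, tolerance = 1e-4)
})

test_that("state schedules encode the hypothesized priority trajectories", {
  s2 <- state_schedule("2back")
  expect_equal(nrow(s2), 3L)
  cur <- s2[s2$component == "current", ]
  expect_equal(cur$state, c("perceptual", "remapped"))
  expect_equal(cur$start, c(0, 1150))
  expect_equal(cur$end, c(1150, 3550))
  prev <- s2[s2$component == "previous", ]
  expect_equal(prev$state, "perceptual")
  expect_equal(prev$gain, 0.7)
  expect_equal(state_schedule("1back")$state, "perceptual")
  expect_equal(state_schedule("dr")$end, 2750)
  expect_equal(state_schedule("localizer")$end, 500)
})

test_that("near-noiseless simulation reproduces the forward model exactly", {
  fm <- forward_model(30, fix_basis, noise_sd = 1e-10, ar = 0, seed = 5)
  tt <- generate_dr_block(seed = 5)
  ep <- simulate_eeg_epochs(tt, fm, state_schedule("dr"), fix_basis,
                            srate = 50, tmax = 2750, seed = 6)
  # at any delay timepoint, the voltages are W c(theta)
  C <- basis_responses(fix_basis, tt$orientation)
  idx <- which(ep$times == 1000)
  expect_equal(t(ep$data[, , idx]), unname(fm$W %*% C), tolerance = 1e-6)
  # pre-stimulus samples carry no signal
  pre <- which(ep$times < 0)
  expect_lt(max(abs(ep$data[, , pre])), 1e-8)
})

test_that("the 2-back schedule remaps item n and reinstates item n - 1", {
  fm <- forward_model(30, fix_basis, noise_sd = 1e-10, ar = 0, seed = 8)
  tt <- generate_nback_sequence(nback_level = 2, n_items = 12, seed = 8)
  ep <- simulate_eeg_epochs(tt, fm, state_schedule("2back"), fix_basis,
                            srate = 50, seed = 9)
  i_early <- which(ep$times == 500)
  i_late <- which(ep$times == 2000)
  C_cur <- basis_responses(fix_basis, tt$orientation)
  C_rem <- remap_channels(C_cur, 90)
  C_prev <- basis_responses(fix_basis, c(tt$orientation[1], # placeholder
                                         tt$orientation[-12]))
  # early window: item n perceptual only
  expect_equal(t(ep$data[, , i_early]), unname(fm$W %*% C_cur),
               tolerance = 1e-6)
  # late window: item n remapped plus item n - 1 perceptual at gain 0.7
  # (skip trial 1, whose previous item does not exist)
  late <- t(ep$data[-1, , i_late])
  expected <- fm$W %*% (C_rem[, -1] + 0.7 * C_prev[, -1])
  expect_equal(late, unname(expected), tolerance = 1e-6)
  # trial 1 late window has the remapped component only
  expect_equal(ep$data[1, , i_late], as.vector(fm$W %*% C_rem[, 1]),
               tolerance = 1e-6)
})

test_that("silent states produce no signal in the localizer", {
  fm <- forward_model(20, fix_basis, noise_sd = 1e-10, ar = 0, seed = 10)
  tt <- generate_localizer_block(seed = 10)
  ep <- simulate_eeg_epochs(tt, fm, state_schedule("localizer"), fix_basis,
                            srate = 50, tmax = 1000, seed = 11)
  on <- which(ep$times >= 0 & ep$times < 500)
  off <- which(ep$times >= 500)
  expect_gt(mean(abs(ep$data[, , on])), 0.1)
  expect_lt(max(abs(ep$data[, , off])), 1e-8)
})

test_that("the SNR preset calibrates the noise scale", {
  fm <- forward_model(30, fix_basis, snr = 0.15, ar = 0, seed = 12)
  tt <- generate_dr_block(seed = 12)
  ep <- simulate_eeg_epochs(tt, fm, state_schedule("dr"), fix_basis,
                            srate = 50, tmax = 2750, seed = 13)
  noise_sd <- attr(ep, "noise_sd")
  active <- ep$times >= 0 & ep$times < 2750
  C <- basis_responses(fix_basis, tt$orientation)
  sig_rms <- mean(sqrt(rowMeans((fm$W %*% C)^2))) # per-electrode RMS, averaged
  expect_equal(sig_rms / noise_sd, 0.15, tolerance = 1e-6)
  # doubling the target SNR halves the calibrated noise
  fm2 <- fm; fm2$snr <- 0.30
  ep2 <- simulate_eeg_epochs(tt, fm2, state_schedule("dr"), fix_basis,
                             srate = 50, tmax = 2750, seed = 13)
  expect_equal(attr(ep2, "noise_sd"), noise_sd / 2, tolerance = 1e-10)
})

test_that("simulation is bit-reproducible in the seed", {
  fm <- forward_model(10, fix_basis, noise_sd = 1, ar = 0.3, seed = 14)
  tt <- generate_nback_sequence(nback_level = 2, n_items = 8, seed = 14)
  a <- simulate_eeg_epochs(tt, fm, basis = fix_basis, srate = 50, seed = 15)
  b <- simulate_eeg_epochs(tt, fm, basis = fix_basis, srate = 50, seed = 15)
  c <- simulate_eeg_epochs(tt, fm, basis = fix_basis, srate = 50, seed = 16)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  s1 <- simulate_session(3, tasks = c("dr", "2back"), gaze = TRUE)
  s2 <- simulate_session(3, tasks = c("dr", "2back"), gaze = TRUE)
  expect_identical(s1$`2back`$eeg$data, s2$`2back`$eeg$data)
  expect_identical(s1$`2back`$gaze$data, s2$`2back`$gaze$data)
  expect_identical(s1$dr$trials, s2$dr$trials)
})

test_that("gaze simulation places class means on the doubled-angle circle", {
  tt <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 17)
  g <- simulate_gaze_epochs(tt, offset_dva = 2, noise_sd = 0.05,
                            white_sd = 0.01, spike_rate = 0,
                            missing_rate = 0, srate = 50, seed = 17)
  win <- g$times >= 1150 & g$times < 3150
  for (o in c(10, 100)) {
    i <- which(tt$orientation == o)
    mx <- mean(g$data[i, 1, win])
    my <- mean(g$data[i, 2, win])
    expect_equal(mx, 2 * cos(2 * o * pi / 180), tolerance = 0.05)
    expect_equal(my, 2 * sin(2 * o * pi / 180), tolerance = 0.05)
  }
  # outside the signal window the mean position is fixation
  pre <- g$times < 1000
  expect_lt(abs(mean(g$data[, 1, pre])), 0.05)
  # missing samples appear at roughly the requested rate
  g2 <- simulate_gaze_epochs(tt, missing_rate = 0.01, srate = 50, seed = 18)
  expect_equal(mean(is.na(g2$data)), 0.01, tolerance = 0.25)
})
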