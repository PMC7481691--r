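# Task-design generators: pool composition, sequence constraints,
# probe/localizer structure, jitter grids and serialization.

test_that("condition pool has 7 match and 14 non-match entries per orientation", {
  pool <- condition_pool()
  expect_equal(nrow(pool), 12L)
  expect_equal(sum(pool$count), 126L)
  for (o in default_orientations()) {
    expect_equal(pool$count[pool$orientation == o & pool$match_status == "match"], 7L)
    expect_equal(pool$count[pool$orientation == o & pool$match_status == "non-match"], 14L)
  }
})

test_that("a 2-back block has 128 items with exactly 42 matches", {
  tt <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 11)
  expect_s3_class(tt, "trial_table")
  expect_equal(nrow(tt), 128L)
  expect_equal(tt$position, 0:127)
  counts <- table(tt$match_status, useNA = "always")
  expect_equal(unname(counts[["match"]]), 42L)
  expect_equal(unname(counts[["non-match"]]), 84L)
  expect_equal(sum(is.na(tt$match_status)), 2L) # warm-up items
  expect_true(all(tt$orientation %in% default_orientations()))
})

test_that("recorded match status agrees with the orientation sequence", {
  for (s in 1:5) {
    tt2 <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = s)
    expect_equal(tt2$match_status, nback_match_status(tt2$orientation, 2L))
    tt1 <- generate_nback_sequence(nback_level = 1, n_items = 127, seed = s)
    expect_equal(tt1$match_status, nback_match_status(tt1$orientation, 1L))
    expect_equal(nrow(tt1), 127L)
    expect_equal(sum(tt1$match_status == "match", na.rm = TRUE), 42L)
  }
})

test_that("no orientation occurs as a match more than twice in a row", {
  for (s in 1:10) {
    tt <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = s)
    is_match <- which(!is.na(tt$match_status) & tt$match_status == "match")
    mo <- tt$orientation[is_match]
    # consecutive match events of the same orientation, regardless of the
    # positions separating them
    run <- rle(mo)
    expect_true(all(run$lengths <= 2L))
  }
})

test_that("ISI jitter stays on the 2800-3200 ms grid and onsets accumulate", {
  tt <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 4)
  expect_true(all(tt$isi_ms %in% seq(2800, 3200, by = 50)))
  soa <- tt$stim_ms + tt$gap_ms + tt$mask_ms + tt$isi_ms
  expect_equal(diff(tt$onset), soa[-128])
  expect_equal(tt$onset[1], 0)
  # the jitter-grid sampler rejects invalid grids
  expect_error(sample_isi(0, 95, 50), "grid")
  expect_true(all(sample_isi(500, 800, 50, n = 200, seed = 1) %in%
                    seq(500, 800, by = 50)))
})

test_that("lag-1 orientation transitions are uniform over many blocks", {
  tabs <- lapply(1:60, function(s)
    generate_nback_sequence(nback_level = 2, n_items = 128, seed = 1000 + s))
  pairs <- do.call(rbind, lapply(tabs, function(tt)
    cbind(tt$orientation[-128], tt$orientation[-1])))
  tab <- table(pairs[, 1], pairs[, 2])
  # chi-squared goodness of fit of each row against uniform next-orientation
  chisq <- sum((tab - rowSums(tab) / 6)^2 / (rowSums(tab) / 6))
  p <- stats::pchisq(chisq, df = 30, lower.tail = FALSE)
  expect_gt(p, 1e-4)
  # marginal orientation frequencies are uniform too
  marg <- table(unlist(lapply(tabs, `[[`, "orientation")))
  expect_lt(max(abs(marg / sum(marg) - 1 / 6)), 0.01)
})

test_that("delayed-recognition blocks pair each sample with +/-15 degree probes", {
  tt <- generate_dr_block(seed = 21)
  expect_equal(nrow(tt), 72L)
  expect_equal(as.integer(table(tt$orientation)), rep(12L, 6))
  for (o in default_orientations()) {
    sub <- tt[tt$orientation == o, ]
    expect_equal(sum(sub$match_status == "match"), 6L)
    expect_equal(sum(sub$match_status == "non-match"), 6L)
    expect_true(all(sub$probe_orientation[sub$match_status == "match"] == o))
    expect_true(all(sub$probe_orientation[sub$match_status == "non-match"] %in%
                      ((o + c(-15, 15)) %% 180)))
  }
  # wrap-around: a 10-degree sample probes at 25 or 175 degrees
  sub10 <- tt[tt$orientation == 10 & tt$match_status == "non-match", ]
  expect_true(all(sub10$probe_orientation %in% c(25, 175)))
})

test_that("localizer blocks have 20 trials per orientation and 8-12 flickers", {
  tt <- generate_localizer_block(seed = 8)
  expect_equal(nrow(tt), 120L)
  expect_equal(as.integer(table(tt$orientation)), rep(20L, 6))
  nf <- attr(tt, "n_flickers")
  expect_true(nf >= 8L && nf <= 12L)
  on <- attr(tt, "flicker_onsets")
  expect_equal(length(on), nf)
  expect_true(all(diff(on) >= 0))
  expect_true(all(on >= 0 & on <= 120000))
})

test_that("sequence generation is deterministic in the seed", {
  a <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 5)
  b <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 5)
  c <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a$orientation, c$orientation))
  # seeded generation does not disturb the caller's RNG stream
  set.seed(123); x1 <- stats::rnorm(1)
  set.seed(123)
  invisible(generate_nback_sequence(nback_level = 2, n_items = 128, seed = 5))
  expect_identical(stats::rnorm(1), x1)
})

test_that("trial tables survive a TSV round trip", {
  tt <- generate_nback_sequence(nback_level = 2, n_items = 128, seed = 2)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_trial_table(tt, path)
  back <- read_trial_table(path)
  expect_equal(back$orientation, tt$orientation)
  expect_equal(back$match_status, tt$match_status)
  expect_equal(back$onset, tt$onset)
  expect_equal(back$isi_ms, tt$isi_ms)
  expect_true(all(is.na(back$probe_orientation)))
})
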