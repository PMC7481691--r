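# Shared fixtures and oracles for the test suite. Everything here is cheap
# to build so each test file stays fast.

fix_basis <- make_basis()
fix_ideal <- ideal_profile(fix_basis)

# A small epoch_array with random voltages but a balanced full-rank design:
# n_per trials per orientation per run, at the analysis-rate epoch geometry
# (tmin = -200 ms, tmax = 3550 ms, half-open sample bins).
make_test_epochs <- function(n_per = 2L, runs = 2L, srate = 50,
                             tmin = -200, tmax = 3550, seed = 1) {
  dt <- 1000 / srate
  times <- seq(tmin, tmax - dt, by = dt)
  o <- default_orientations()
  trials <- data.frame(
    orientation = rep(rep(o, each = n_per), runs),
    block = rep(seq_len(runs), each = n_per * length(o)))
  trials$position <- stats::ave(seq_len(nrow(trials)), trials$block,
                                FUN = seq_along) - 1L
  n <- nrow(trials)
  m <- 8L
  dat <- with_seed(seed, array(stats::rnorm(n * m * length(times)),
                               c(n, m, length(times))))
  structure(list(data = dat, times = times, srate = srate, trials = trials,
                 electrodes = sprintf("E%02d", seq_len(m))),
            class = "epoch_array")
}

# Monte-Carlo Bayes accuracy for six equidistant class means on a circle of
# the given radius with isotropic Gaussian noise of the given sd. With equal
# isotropic covariances and a flat prior the Bayes rule is nearest-mean.
mc_bayes_rate <- function(radius, sd, n = 200000L, seed = 99) {
  ang <- 2 * default_orientations() * pi / 180
  mu <- cbind(cos(ang), sin(ang)) * radius
  with_seed(seed, {
    y <- sample.int(6L, n, replace = TRUE)
    X <- mu[y, ] + matrix(stats::rnorm(2 * n, sd = sd), n, 2)
    d2 <- vapply(1:6, function(k)
      (X[, 1] - mu[k, 1])^2 + (X[, 2] - mu[k, 2])^2, numeric(n))
    mean(max.col(-d2) == y)
  })
}

# Draw a labelled sample from the same six-class circular-mean model.
draw_circle_classes <- function(radius, sd, n, seed) {
  ang <- 2 * default_orientations() * pi / 180
  mu <- cbind(cos(ang), sin(ang)) * radius
  with_seed(seed, {
    y <- rep_len(1:6, n)
    X <- mu[y, ] + matrix(stats::rnorm(2 * n, sd = sd), n, 2)
    list(X = X, y = default_orientations()[y])
  })
}
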