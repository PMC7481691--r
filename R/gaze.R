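# Six-class probabilistic Gaussian classifier for 2-D gaze position with a
# shrinkage-regularized common covariance, and cross-validated decoding.

#' Fit a Gaussian gaze-position classifier
#'
#' Class-conditional Gaussian model with equal covariance and flat prior:
#' class means `mu_k` are the per-class feature means; the common
#' covariance `S` is the unweighted mean of the per-class sample
#' covariances (n - 1 denominator), regularized by shrinkage toward the
#' scaled identity, `S_shrunk = (1 - lambda) S + lambda (tr(S)/p) I`. The
#' linear discriminants are `a_k(x) = w_k' x + w_k0` with `w_k = S^-1 mu_k`
#' and, in the default `"plain"` form, `w_k0 = -mu_k' S^-1 mu_k`; the
#' `"half"` option uses the conventional quadratic offset
#' `-mu_k' S^-1 mu_k / 2`, which makes posteriors invariant to joint
#' translation of the data and means (the plain form is not; see the
#' package tests for the characterization).
#'
#' @param X Trials x 2 feature matrix (horizontal, vertical gaze).
#' @param y Class labels (one per trial; every class needs >= 2 samples).
#' @param lambda Shrinkage parameter between 0 and 1 (default 0.01).
#' @param offset `"plain"` (default) or `"half"` discriminant offset.
#' @return Object of class `gaze_lda` with `means`, `S`, `S_shrunk`,
#'   weights `W` (features x classes) and offsets `w0`.
#' @export
gaze_lda <- function(X, y, lambda = 0.01, offset = c("plain", "half")) {
  X <- as.matrix(X)
  offset <- match.arg(offset)
  stopifnot(ncol(X) == 2L, nrow(X) == length(y), lambda >= 0, lambda <= 1)
  y <- as.factor(y)
  cnt <- table(y)
  if (any(cnt < 2L))
    stop("class(es) with fewer than 2 samples: ",
         paste(names(cnt)[cnt < 2L], collapse = ", "))
  classes <- levels(y)
  K <- length(classes)
  mu <- t(vapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]),
                 numeric(2)))
  covs <- lapply(classes, function(k) stats::cov(X[y == k, , drop = FALSE]))
  S <- Reduce(`+`, covs) / K
  Ssh <- (1 - lambda) * S + lambda * (sum(diag(S)) / 2) * diag(2)
  W <- solve(Ssh, t(mu)) # features x classes
  quad <- colSums(t(mu) * W) # mu_k' S^-1 mu_k
  w0 <- if (offset == "plain") -quad else -quad / 2
  structure(list(means = mu, S = S, S_shrunk = Ssh, W = W, w0 = w0,
                 classes = classes, lambda = lambda, offset = offset),
            class = "gaze_lda")
}

#' @export
print.gaze_lda <- function(x, ...) {
  cat("Gaussian gaze classifier:", length(x$classes), "classes,",
      "shrinkage lambda =", x$lambda, paste0("(", x$offset, " offset)\n"))
  invisible(x)
}

#' @export
coef.gaze_lda <- function(object, ...) rbind(object$W, offset = object$w0)

#' Posterior class probabilities or hard labels from a gaze classifier
#'
#' Softmax over the linear discriminants, `P(class = k | x) =
#' exp(a_k) / sum_j exp(a_j)` under a flat prior.
#'
#' @param object A fitted `gaze_lda`.
#' @param X New trials x 2 feature matrix (or a single 2-vector).
#' @param type `"prob"` for posteriors, `"class"` for the argmax label.
#' @param ... Unused.
#' @return Trials x classes probability matrix, or a character vector of
#'   labels.
#' @export
predict.gaze_lda <- function(object, X, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  A <- X %*% object$W + matrix(object$w0, nrow(X), length(object$w0),
                               byrow = TRUE)
  A <- A - apply(A, 1, max)
  P <- exp(A)
  P <- P / rowSums(P)
  colnames(P) <- object$classes
  if (type == "prob") P else object$classes[max.col(P, ties.method = "first")]
}

# Cross-validated accuracy for one feature matrix.
cv_accuracy <- function(X, y, folds, lambda, offset) {
  correct <- logical(length(y))
  for (f in unique(folds)) {
    te <- folds == f
    fit <- gaze_lda(X[!te, , drop = FALSE], y[!te], lambda, offset)
    correct[te] <- predict(fit, X[te, , drop = FALSE], type = "class") ==
      as.character(y[te])
  }
  mean(correct)
}

#' Assign stratified pseudo-runs within blocks
#'
#' Leave-one-run-out cross-validation needs at least two runs; when a task
#' was simulated with a single block, trials are partitioned into `k`
#' interleaved folds stratified by class label.
#'
#' @param y Class labels.
#' @param k Number of pseudo-runs (default 4).
#' @return Integer fold id per trial.
#' @export
pseudo_runs <- function(y, k = 4L) {
  fold <- integer(length(y))
  for (lev in unique(y)) {
    i <- which(y == lev)
    fold[i] <- rep_len(seq_len(k), length(i))
  }
  fold
}

#' Cross-validated gaze decoding timecourse and window accuracies
#'
#' Leave-one-run-out decoding of an orientation label from cleaned gaze
#' epochs: per timepoint the features are the (x, y) coordinates at that
#' sample; per analysis window they are the within-window mean coordinates.
#' Returns one subject's accuracy values; group-level tests against chance
#' (1/6 for six classes) are run across subjects with
#' [window_average_test()] / [cluster_permutation()].
#'
#' @param g A (cleaned) `gaze_epochs` object.
#' @param labels Class label per trial (e.g. orientation of item n, or of
#'   item n - 1 to probe the prioritized item).
#' @param runs Run label per trial (>= 2 distinct runs; see
#'   [pseudo_runs()]).
#' @param windows Optional list of `c(start, end)` windows (ms).
#' @param lambda,offset Passed to [gaze_lda()].
#' @param timecourse Compute the per-timepoint accuracy series?
#' @return List with `timecourse` (data frame `time`, `accuracy`, or
#'   `NULL`) and `windows` (data frame `window`, `start`, `end`,
#'   `accuracy`, or `NULL`).
#' @export
gaze_decode_cv <- function(g, labels, runs, windows = NULL, lambda = 0.01,
                           offset = "plain", timecourse = TRUE) {
  stopifnot(inherits(g, "gaze_epochs"))
  keep <- !is.na(labels)
  dat <- g$data[keep, , , drop = FALSE]
  labels <- as.factor(labels[keep])
  runs <- as.factor(runs[keep])
  if (nlevels(runs) < 2L)
    stop("leave-one-run-out cross-validation requires at least 2 runs")
  tc <- NULL
  if (timecourse) {
    acc <- vapply(seq_along(g$times), function(s)
      cv_accuracy(dat[, , s], labels, runs, lambda, offset), numeric(1))
    tc <- data.frame(time = g$times, accuracy = acc)
  }
  wd <- NULL
  if (!is.null(windows)) {
    if (!is.list(windows)) windows <- list(windows)
    nm <- names(windows) %||% paste0("window", seq_along(windows))
    wd <- do.call(rbind, lapply(seq_along(windows), function(i) {
      w <- windows[[i]]
      idx <- which(g$times >= w[1] & g$times <= w[2])
      if (length(idx) == 0L) stop("empty gaze decoding window")
      Xw <- apply(dat[, , idx, drop = FALSE], c(1, 2), mean)
      data.frame(window = nm[i], start = w[1], end = w[2],
                 accuracy = cv_accuracy(Xw, labels, runs, lambda, offset))
    }))
  }
  list(timecourse = tc, windows = wd)
}
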