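# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed. With
#' `seed = NULL` the expression runs under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed for a pipeline stage
#'
#' Deterministic seed-splitting rule: `child_seed(seed, i, stage)` mixes the
#' master seed with a subject/replicate index and a stage label so that
#' stages can be re-run in isolation with the same stream. Result is kept
#' within the 32-bit signed integer range.
#'
#' @param seed Master integer seed.
#' @param index Subject or replicate index (integer >= 0).
#' @param stage Character stage label.
#' @return Integer seed.
#' @export
child_seed <- function(seed, index = 0L, stage = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(paste0("s", stage))) %% 7919
  as.integer((abs(as.numeric(seed)) * 2654435.0 + index * 97003 + h * 131) %% 2147483629)
}

# Wrap angular differences on the 180-degree orientation circle into [-90, 90).
wrap_ori <- function(x) ((x + 90) %% 180) - 90

# Circularly roll a vector k positions forward (element i moves to i + k).
roll <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1:(n - k)])
}

# Centered moving average with edges truncated to the available samples.
# For even k the window extends floor((k-1)/2) samples left and the
# remainder right of the current sample.
mov_avg <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k <= 1L || n == 0L) return(x)
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - left, 1L)
  hi <- pmin(seq_len(n) + right, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Moving-average smoothing of a time series
#'
#' Centered moving mean over a window given in milliseconds; edge windows are
#' truncated to the samples actually available, so a constant series is
#' returned unchanged and a one-sample window is the identity.
#'
#' @param x Numeric vector (one time series).
#' @param window_ms Window length in ms.
#' @param srate Sampling rate in Hz.
#' @return Smoothed numeric vector of the same length.
#' @examples
#' moving_average(c(0, 0, 1, 0, 0), window_ms = 5000, srate = 1)
#' @export
moving_average <- function(x, window_ms, srate) {
  stopifnot(window_ms > 0, srate > 0)
  k <- max(1L, as.integer(round(window_ms * srate / 1000)))
  mov_avg(x, k)
}
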