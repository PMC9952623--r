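# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximal runs of TRUE in a logical vector
#'
#' @param x logical vector (NA treated as FALSE).
#' @return data.frame with columns `start`, `end` (1-based, inclusive) and
#'   `length`, one row per maximal run.
#' @keywords internal
#' @noRd
logical_runs <- function(x) {
  x <- !is.na(x) & x
  if (!any(x)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Odd window length in samples for running medians, capped at the signal
# length (runmed requires k <= n and odd k).
odd_window <- function(len_s, fs_hz, n) {
  k <- round(len_s * fs_hz)
  k <- min(k, n)
  if (k %% 2L == 0L) k <- k - 1L
  max(k, 1L)
}

# Trapezoidal integral of the piecewise-linear interpolant of (f, p) between
# exact limits [lo, hi], clipped to the grid's support.
trapz_band <- function(f, p, lo, hi) {
  lo <- max(lo, f[1L])
  hi <- min(hi, f[length(f)])
  if (hi <= lo) return(0)
  inner <- f[f > lo & f < hi]
  knots <- c(lo, inner, hi)
  vals <- stats::approx(f, p, xout = knots)$y
  sum(diff(knots) * (vals[-length(vals)] + vals[-1L]) / 2)
}

stop_insufficient <- function(msg) {
  stop(errorCondition(msg, class = c("ctg_insufficient_data", "error")))
}

stop_contract <- function(msg) {
  stop(errorCondition(msg, class = c("ctg_contract_error", "error")))
}
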