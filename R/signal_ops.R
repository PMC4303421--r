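# ---------------------------------------------------------------------------
# 1-D signal operators: median filtering, prominence-filtered local
# extrema, and mean / standard-error summaries.
# ---------------------------------------------------------------------------

as_signal_values <- function(signal) {
  if (inherits(signal, "signal_item")) signal$values else as.numeric(signal)
}

#' Sliding-window median filter
#'
#' Each output value is the median of the window centered at that index;
#' borders are handled by reflection (mirror about the end point, end point
#' not duplicated), so the output has the input's length.  Never produces
#' values outside the input's range.
#'
#' @param signal A `signal_item` or numeric vector.
#' @param window Odd window length, `window <= 2n - 1`.
#' @return Filtered signal of the same type as the input.
#' @export
median_filter <- function(signal, window = 5L) {
  v <- as_signal_values(signal)
  n <- length(v)
  if (window %% 2L == 0L || window < 1L)
    stop_parameter(sprintf("window must be odd, got %d", window))
  if (window > 2L * n - 1L)
    stop_parameter(sprintf("window %d exceeds 2n-1 = %d", window, 2L * n - 1L))
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(signal)
  idx <- c(rev(seq_len(h) + 1L), seq_len(n), n - seq_len(h))
  padded <- v[idx]
  out <- vapply(seq_len(n), function(i)
    stats::median(padded[i:(i + 2L * h)]), 0)
  if (inherits(signal, "signal_item")) {
    signal$values <- out
    signal
  } else out
}

# Local maxima of v with plateau centers and prominence filtering.
# Returns 0-based indices.
local_maxima <- function(v, min_prominence) {
  n <- length(v)
  # run-length encode so plateaus become single candidates
  r <- rle(v)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next  # runs touching the ends are not interior
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
      center <- (starts[j] + ends[j]) %/% 2L   # floor of the midpoint
      prom <- peak_prominence(v, center, r$values[j])
      if (prom >= min_prominence) out <- c(out, center - 1L)
    }
  }
  out
}

# Prominence of the peak at index i (1-based) with value pv: height above
# the higher of the two flanking saddles, each saddle being the minimum
# value on the walk from the peak to the first strictly higher value (or
# the signal end).
peak_prominence <- function(v, i, pv) {
  left <- v[seq_len(i - 1L)]
  higher <- which(left > pv)
  saddle_l <- if (length(higher) > 0L)
    min(left[(max(higher) ):(i - 1L)]) else min(left)
  right <- v[(i + 1L):length(v)]
  higher <- which(right > pv)
  saddle_r <- if (length(higher) > 0L)
    min(right[seq_len(min(higher))]) else min(right)
  pv - max(saddle_l, saddle_r)
}

#' Local extrema with prominence filtering
#'
#' Interior indices whose value is greater-or-equal (maxima) or
#' less-or-equal (minima) than both neighbours; plateaus are reported at
#' their center index (floor of the midpoint).  Candidates are kept when
#' their prominence - the height above the higher of the two flanking
#' saddle values, mirrored for minima - reaches `min_prominence`.
#' `find_extrema(-s)` swaps maxima and minima exactly.
#'
#' @param signal A `signal_item` or numeric vector, length >= 3.
#' @param min_prominence Non-negative prominence threshold.
#' @return List with `maxima` and `minima`, each a strictly increasing
#'   vector of 0-based indices.
#' @export
find_extrema <- function(signal, min_prominence = 0) {
  v <- as_signal_values(signal)
  if (length(v) < 3L)
    stop_parameter("extrema detection requires a signal of length >= 3")
  if (min_prominence < 0)
    stop_parameter("min_prominence must be non-negative")
  list(maxima = local_maxima(v, min_prominence),
       minima = local_maxima(-v, min_prominence))
}

#' Mean and standard error
#'
#' `se` is the sample standard deviation (n-1 denominator) divided by
#' `sqrt(n)`; 0 when `n = 1`.
#'
#' @param values Numeric vector, length >= 1.
#' @return List with `mean` and `se`.
#' @export
mean_and_se <- function(values) {
  values <- as_signal_values(values)
  n <- length(values)
  if (n < 1L) stop_parameter("mean_and_se requires at least one value")
  list(mean = mean(values),
       se = if (n == 1L) 0 else stats::sd(values) / sqrt(n))
}
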