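#' Linearly interpolate a track at arbitrary times
#'
#' Estimates an animal's position at time(s) `t` by linear interpolation
#' between the flanking fixes of a single-day track. Interpolation never
#' extrapolates: times outside the track's span return `NA`, as do times
#' whose flanking gap exceeds `max_gap`. At a fix time the fix itself is
#' returned exactly.
#'
#' @param track Data frame with columns `t, x, y` for one animal within one
#'   day, sorted by `t` with strictly increasing times.
#' @param t Numeric vector of query times (seconds).
#' @param max_gap Largest flanking gap (s) that may be bridged.
#' @return A tibble with columns `t, x, y`; `x`/`y` are `NA` where the
#'   position is not estimable.
#' @export
interpolate_position <- function(track, t, max_gap = 1800) {
  stop_if_missing_cols(track, c("t", "x", "y"), "track")
  tt <- track$t
  if (is.unsorted(tt, strictly = TRUE)) {
    abort("track must be sorted with strictly increasing times")
  }
  n <- length(tt)
  x <- rep(NA_real_, length(t))
  y <- rep(NA_real_, length(t))
  if (n >= 1) {
    exact <- match(t, tt)
    hit <- !is.na(exact)
    x[hit] <- track$x[exact[hit]]
    y[hit] <- track$y[exact[hit]]
    if (n >= 2) {
      inside <- !hit & t > tt[1] & t < tt[n]
      if (any(inside)) {
        i <- findInterval(t[inside], tt)
        gap <- tt[i + 1] - tt[i]
        ok <- gap <= max_gap
        idx <- which(inside)[ok]
        i <- i[ok]
        w <- (t[idx] - tt[i]) / (tt[i + 1] - tt[i])
        x[idx] <- track$x[i] + w * (track$x[i + 1] - track$x[i])
        y[idx] <- track$y[i] + w * (track$y[i + 1] - track$y[i])
      }
    }
  }
  tibble(t = t, x = x, y = y)
}
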