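# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. `seed = NULL` leaves the RNG stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Derive a reproducible child seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 7919 + 104729 * k) %% 2147483629
}

#' Unit vector between two points
#'
#' Returns the planar unit vector pointing from `from` to `to`, or `NULL`
#' when the two points are closer than `eps` (direction undefined).
#'
#' @param from,to Numeric length-2 vectors `c(x, y)` in metres.
#' @param eps Distance (m) below which the displacement is treated as zero.
#' @return A numeric length-2 unit vector, or `NULL`.
#' @examples
#' unit_vec(c(0, 0), c(3, 4)) # c(0.6, 0.8)
#' @export
unit_vec <- function(from, to, eps = 0.1) {
  d <- c(to[1] - from[1], to[2] - from[2])
  len <- sqrt(sum(d^2))
  if (!is.finite(len) || len < eps) return(NULL)
  d / len
}

# Vectorised unit vectors: (dx, dy) matrices -> list(ux, uy, len). Rows with
# length < eps come back NA.
unit_vec_xy <- function(dx, dy, eps = 0.1) {
  len <- sqrt(dx^2 + dy^2)
  bad <- !is.finite(len) | len < eps
  ux <- dx / len
  uy <- dy / len
  ux[bad] <- NA_real_
  uy[bad] <- NA_real_
  list(ux = ux, uy = uy, len = len)
}

# Highest posterior density interval from a vector of draws.
hpdi <- function(draws, prob = 0.99) {
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  width <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(width)
  c(lower = x[i], upper = x[i + m])
}

# Quantile with the conventional type-7 definition, NA-safe.
q95 <- function(x) unname(quantile(x, 0.95, names = FALSE, type = 7))

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
}
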