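# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state. All stochastic generators route through this so that seeds
# are explicit arguments, never hidden global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Vertex of the parabola through three (x, y) points; used for subpixel /
# sub-grid refinement of correlation and EER peaks. Falls back to the middle
# point when the three points are collinear or curve upwards.
parabolic_vertex <- function(x, y) {
  stopifnot(length(x) == 3L, length(y) == 3L)
  d21 <- x[2] - x[1]; d32 <- x[3] - x[2]
  s1 <- (y[2] - y[1]) / d21
  s2 <- (y[3] - y[2]) / d32
  a <- (s2 - s1) / (x[3] - x[1])
  if (!is.finite(a) || a >= 0) return(list(x = x[2], y = y[2]))
  b <- s1 - a * (x[1] + x[2])
  xv <- -b / (2 * a)
  if (xv < x[1] || xv > x[3]) return(list(x = x[2], y = y[2]))
  cc <- y[1] - a * x[1]^2 - b * x[1]
  list(x = xv, y = a * xv^2 + b * xv + cc)
}

# Running mean with shrinking windows at the edges (no NA padding).
running_mean <- function(y, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(y)
  if (k == 1L || n < 3L) return(y)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Theil-Sen slope/intercept: robust straight-line fit used for tip tracking.
theil_sen <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  dy <- y[ij[2L, ]] - y[ij[1L, ]]
  keep <- dx != 0
  slope <- stats::median(dy[keep] / dx[keep])
  intercept <- stats::median(y - slope * x)
  list(slope = slope, intercept = intercept)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}
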