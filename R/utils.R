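#' @useDynLib sidepop
#' @importFrom stats approx cor quantile rnorm runif sd setNames
#' @importFrom utils head write.csv
NULL

# Deterministic per-purpose substreams of one master seed, so any stage
# (radii, DNA, transporter, parameter design, ...) is independently
# reproducible. Keeps derived seeds < 2^31.
substream_seed <- function(seed, purpose) {
  h <- sum(as.integer(charToRaw(purpose)) * seq_along(charToRaw(purpose)))
  as.integer((as.numeric(seed) * 1103515245 + h * 12345) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One-dimensional Latin hypercube vector: exactly one draw per 1/n stratum,
# in random order.
lhs_vector <- function(n, seed = NULL) {
  draw <- function() {
    if (n == 0L) return(numeric(0))
    (sample.int(n) - runif(n)) / n
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Inverse-CDF lookup on a gridded 1D density. `x` is the grid, `d` the
# (not necessarily normalized) non-negative density values.
sample_gridded_pdf <- function(x, d, u) {
  stopifnot(length(x) == length(d), all(d >= 0))
  if (sum(d) <= 0) stop("invalid reference: density is identically zero")
  dx <- diff(x)
  # trapezoid cumulative mass between knots
  seg <- dx * (head(d, -1) + d[-1]) / 2
  cdf <- c(0, cumsum(seg))
  cdf <- cdf / cdf[length(cdf)]
  # flat (zero-density) stretches make the cdf non-strict; keep first knot
  keep <- !duplicated(cdf)
  approx(cdf[keep], x[keep], xout = u, rule = 2, ties = "ordered")$y
}

# Trapezoidal integral of a surface on a rectilinear grid.
trapz2 <- function(x, y, z) {
  wx <- trapz_weights(x)
  wy <- trapz_weights(y)
  as.numeric(wx %*% z %*% wy)
}

trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  dx <- diff(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-1] + dx[-(n - 1)]) / 2
  w
}

trapz1 <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
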