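# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a child seed from a top-level seed
#'
#' Deterministic counter scheme used to fan one user-facing seed out to
#' independent per-generator or per-replicate seeds, so that adding one more
#' draw never perturbs the others.  `child = (seed + 104729 * k) mod (2^31 - 1)`
#' (104729 is the 10000th prime; the modulus keeps the result a valid 32-bit
#' integer seed).
#'
#' @param seed Top-level integer seed.
#' @param k Child index (vectorised, any non-negative integer).
#' @return Integer seed(s).
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), all(k >= 0))
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483647)
}

# Circular moving average with an odd window (used on closed contours).
circ_movavg <- function(x, window) {
  if (window <= 1) return(x)
  if (window %% 2 == 0) window <- window + 1
  h <- (window - 1) / 2
  n <- length(x)
  xx <- c(x[(n - h + 1):n], x, x[1:h])
  as.numeric(stats::filter(xx, rep(1 / window, window), sides = 2))[(h + 1):(h + n)]
}

# Non-circular moving average; endpoints keep shrinking partial windows.
movavg_open <- function(x, window) {
  if (window <= 1) return(x)
  if (window %% 2 == 0) window <- window + 1
  h <- (window - 1) / 2
  n <- length(x)
  out <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  for (i in seq_len(min(h, n))) {
    out[i] <- mean(x[1:min(n, i + h)])
    out[n - i + 1] <- mean(x[max(1, n - i + 1 - h):n])
  }
  out
}

# Local curvature magnitude of a curve window by a quadratic fit in the
# PCA-rotated (tangent/normal) frame: kappa = |2c| / (1 + b^2)^{3/2} from
# y = a + b x + c x^2.  Linear in the fitted coefficients, hence nearly
# unbiased under symmetric digitisation noise (unlike an algebraic circle
# fit on a shallow arc).
local_curvature <- function(xy) {
  stopifnot(is.matrix(xy) || is.data.frame(xy), nrow(xy) >= 5)
  xy <- as.matrix(xy)
  cxy <- sweep(xy, 2, colMeans(xy))
  rot <- svd(cxy)$v                 # col 1 = tangent, col 2 = normal
  uv <- cxy %*% rot
  cf <- stats::coef(stats::lm(uv[, 2] ~ uv[, 1] + I(uv[, 1]^2)))
  kappa <- abs(2 * cf[3]) / (1 + cf[2]^2)^1.5
  if (!is.finite(kappa)) stop("degenerate curvature fit", call. = FALSE)
  unname(kappa)
}
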