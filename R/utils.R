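#' Derive reproducible sub-seeds from a master seed
#'
#' All stochastic steps of the package draw their own seed from a single
#' master seed through this helper, so that stages can be re-run in
#' isolation without disturbing each other's random streams.
#'
#' @param seed master seed (single integer) or `NULL` for no seeding.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n` (or `NULL` if `seed` is `NULL`).
#' @export
split_seed <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  expr
}

#' @noRd
.stop2 <- function(...) stop(..., call. = FALSE)

# multivariate normal draws via Cholesky (deterministic given the RNG state)
.rmvn <- function(n, mean, sigma) {
  p <- length(mean)
  if (p == 1L) return(matrix(rnorm(n, mean, sqrt(as.numeric(sigma))), ncol = 1L))
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% chol(sigma), 2L, mean, `+`)
}

# 2-D rotation matrix, angle in degrees
.rot2 <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

.fmt_num <- function(x) sprintf("%.10g", x)
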