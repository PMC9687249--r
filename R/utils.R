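#' @importFrom stats coef cor lm median pchisq pnorm pt qchisq qnorm quantile
#'   rbinom rnorm runif sd setNames var complete.cases p.adjust cor.test rgamma
#' @importFrom utils head modifyList
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generator calls do not disturb
#' the caller's RNG stream. All stochastic operations in the package route
#' their seed through this helper, which makes them reproducible and
#' side-effect free.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Assert that a value is a single finite number
#' @keywords internal
assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stopf("'%s' must be a single finite number in [%s, %s]", name, min, max)
  invisible(x)
}

## Column standardization dropping zero-variance columns.
## Returns list(x = standardized matrix, dropped = indices of constant cols).
standardize_columns <- function(x, tol = 1e-12) {
  mu <- colMeans(x)
  s <- matrixStats::colSds(x)
  keep <- s > tol
  xs <- sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-")
  xs <- sweep(xs, 2L, s[keep], "/")
  list(x = xs, dropped = which(!keep))
}

## Residualize columns of `y` (matrix or vector) on design matrix `x`
## (including intercept) via QR. Exact least-squares projection.
project_out <- function(y, x) {
  qx <- qr(x)
  as.matrix(y) - qr.fitted(qx, as.matrix(y))
}

## Split 1..n into chunks of at most `size` (deterministic).
chunk_indices <- function(n, size) {
  if (n == 0L) return(list())
  starts <- seq.int(1L, n, by = size)
  lapply(starts, function(s) s:min(s + size - 1L, n))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}
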