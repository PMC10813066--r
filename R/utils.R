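#' @keywords internal
"_PACKAGE"

#' @useDynLib cementmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median prcomp rnorm runif sd setNames complete.cases
#' @importFrom utils read.csv write.csv head
NULL

# Round half away from zero (the convention used for reported micrometre
# statistics; base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All stochastic generators in the package go
# through this so a spec seed fully determines the output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_field <- function(row, field, msg) {
  stop(sprintf("fixture record %s, field `%s`: %s", row, field, msg),
       call. = FALSE)
}

# Unit vector
vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
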