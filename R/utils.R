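#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (so 42.855 -> 42.86), as used for
#' all reported percentages. Base \code{round()} rounds half to even, which
#' would print 42.85 for some headline shares.
#'
#' @param x numeric vector (non-negative in all package uses)
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG state is restored afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# canonical unordered pair representation: a <= b lexicographically
canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(a = a, b = b, key = paste(a, b, sep = "\r"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
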