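#' @importFrom methods new is validObject slot
#' @importFrom stats dnorm rnorm runif sd var cor setNames
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package internals never disturb the
# user's stream.
withLocalSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive `n` child seeds from a parent seed; prefix-stable, so enlarging `n`
# extends the schedule without changing earlier entries.
deriveSeeds <- function(seed, n) {
  withLocalSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = TRUE))
}

clip01 <- function(x, lo = -1, hi = 1) pmin(hi, pmax(lo, x))

# Display rounding used by the report tables: 3 decimals, half away from zero.
roundHalfUp <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
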