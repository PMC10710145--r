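#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

## Run code under a fixed RNG state without disturbing the caller's stream.
## All user-facing seeds funnel through here so results are bit-reproducible.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())
    ), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

## Derive a per-stage seed from a global one; kept well below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(
    genotypes = 11L, covariates = 23L, phenotype = 37L, views = 53L,
    causal = 71L, split = 89L, train = 101L, grid = 131L, pipeline = 151L
  )
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000000L) * 2L + off
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mvfuse <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop_mvfuse(msg)
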