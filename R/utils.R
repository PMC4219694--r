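#' @importFrom stats ecdf ks.test chisq.test wilcox.test quantile rnorm runif
#' @importFrom stats rmultinom setNames
#' @importFrom utils read.table write.table
NULL

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one top-level integer seed.
#' Stage-specific seeds are derived deterministically from the top-level
#' seed and a stage name, so individual pipeline stages can be re-run in
#' isolation and still reproduce their output bit-for-bit.
#'
#' @param seed Top-level integer seed.
#' @param name Character stage name (e.g. `"genome"`, `"variants"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "genome")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps the result a valid R integer
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
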