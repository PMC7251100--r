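#' @importFrom rlang %||%
#' @importFrom stats fft rnorm runif sd quantile median setNames
#' @importFrom utils head tail
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All generator functions funnel randomness through
# this so that results are pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_seizr <- function(..., call. = FALSE) stop(..., call. = call.)

assert_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_seizr(sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) stop_seizr(sprintf("`%s` must be finite", name))
  if (positive && x <= 0) stop_seizr(sprintf("`%s` must be > 0", name))
  invisible(x)
}
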