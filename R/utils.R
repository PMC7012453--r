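# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a stage-specific seed from a root seed
#'
#' Fans a single root seed out to per-stage seeds by hashing the stage name,
#' so that pipeline stages remain individually reproducible. The result is
#' always a valid 32-bit integer seed.
#'
#' @param root_seed integer root seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(root_seed) + h * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample interquartile range (75th - 25th percentile).
iqr_of <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75), na.rm = TRUE)))

stop_invalid <- function(...) stop(..., call. = FALSE)
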