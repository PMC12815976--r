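#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

## NULL-default helper (avoids importing rlang's %||% semantics into the API)
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible substream seed
#'
#' One master seed plus a quantity tag yields an independent, stable integer
#' seed, so adding a simulated quantity never perturbs the draws of another.
#' The hash is a plain polynomial rolling hash over the tag, reduced modulo a
#' prime below 2^31.
#'
#' @param seed master integer seed.
#' @param tag character scalar naming the substream (e.g. `"age"`, `"iiv"`).
#' @return an integer in `[0, 2147480009)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag), length(tag) == 1L)
  m <- 2147480009
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer((abs(seed) %% m + h) %% m)
}

## Evaluate `code` under a substream seed, restoring the caller's RNG state.
with_substream <- function(seed, tag, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(derive_seed(seed, tag))
  force(code)
}

## stop() with a message that names the offending field
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

## trapezoidal integral of y over x (both numeric, x increasing)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}
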