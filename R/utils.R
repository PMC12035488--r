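#' @useDynLib mrsisr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named sub-seed from a root seed
#'
#' All randomness in the package flows from a single root seed split into
#' named streams (phantom generation, concentration sampling, weight
#' initialization, augmentation, ...), so that components can be re-run
#' independently yet reproducibly.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "phantom")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483647)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# mean over a logical mask; NA-free inputs assumed
masked_mean <- function(x, mask) {
  if (!any(mask)) return(NA_real_)
  mean(x[mask])
}
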