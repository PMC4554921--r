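#' Derive a child seed from a top-level seed
#'
#' Every stochastic stage of the package draws its randomness from a seed
#' derived deterministically from one top-level seed and a stage key, so any
#' stage can be regenerated in isolation. The rule is a 31-multiplier
#' polynomial string hash of \code{key} folded into \code{seed}, reduced
#' modulo 2^31 - 1 (keeping the result a valid 32-bit R integer).
#'
#' @param seed integer top-level seed.
#' @param key character scalar naming the stage (and, typically, the
#'   fraction/replicate or scene it concerns).
#' @return a single integer seed.
#' @examples
#' childSeed(1L, "psm:HermesBody:1")
#' @export
childSeed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483647  # 2^31 - 1
  s <- as.double(seed %% m)
  for (c in utf8ToInt(key)) s <- (s * 31 + c) %% m
  as.integer(s)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

# stable sample key used for matrix columns
.sampleKey <- function(fraction, replicate) paste0(fraction, ".", replicate)
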