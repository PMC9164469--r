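#' Derive a deterministic substream seed
#'
#' Mixes a master seed with an arbitrary sequence of name/value tokens into a
#' 32-bit integer seed.  All randomness in the package flows from one master
#' seed through named substreams (e.g. `("labels", "1a")`,
#' `("manipulation", "spectral_noise", level, replicate)`), so that components
#' can be varied independently while runs stay bit-reproducible.
#'
#' The hash is a plain polynomial rolling hash over the UTF-8 token string,
#' reduced modulo 2^31 - 1; it is stable across platforms and R versions
#' (no dependence on R's RNG internals).
#'
#' @param seed integer master seed.
#' @param ... tokens (strings or numbers) naming the substream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "labels", "1a")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  tokens <- vapply(list(...), function(x) {
    paste(format(x, digits = 15L, scientific = FALSE, trim = TRUE),
          collapse = "|")
  }, character(1L))
  h <- as.double(abs(seed) %% 2147483647)
  for (ch in utf8ToInt(paste(tokens, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}
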