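#' Derive a named RNG substream seed
#'
#' A single global seed fans out into one deterministic substream per named
#' consumer (module, wavelength, replicate, ...), so adding consumers does
#' not perturb the draws of existing ones. Plain polynomial string hash,
#' folded with the global seed modulo 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param name substream label.
#' @return integer in [1, 2^31 - 2], suitable for \code{set.seed}.
#' @export
stream_seed <- function(seed, name) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (b in utf8ToInt(as.character(name))) h <- (h * 131 + b) %% m
  as.integer(h %% (m - 1) + 1)
}
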