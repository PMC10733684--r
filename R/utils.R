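#' Derive a reproducible sub-stream seed
#'
#' Hashes a root seed together with any number of string/numeric tags into a
#' 31-bit integer, so every stage of the pipeline draws from its own stream
#' and adding a stage never perturbs the draws of an earlier one.
#'
#' @param root integer root seed.
#' @param ... stage tags (strings or numbers) identifying the sub-stream.
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(root, ...) {
  parts <- c(as.character(root), vapply(list(...), as.character, character(1)))
  h <- 0
  for (p in parts) {
    for (cc in utf8ToInt(p)) h <- (h * 31 + cc) %% 2147483647
  }
  as.integer(h)
}

# stop() with sprintf formatting, no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

CONSTITUENTS <- c("mper", "hav", "bmp9", "tgfb1")
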