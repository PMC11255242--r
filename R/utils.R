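`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global integer seed and a stage name to a stage
#' seed, so that every pipeline stage is independently reproducible. The
#' mapping is a simple polynomial hash over the stage name, folded into the
#' 31-bit positive integer range.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return A positive integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h + 1)
}

# run code under a temporary RNG state
local_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# random DNA as a character string, memory-frugal for multi-Mb lengths
random_dna <- function(n, freqs) {
  idx <- sample.int(4L, n, replace = TRUE, prob = freqs)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[idx]))  # A C G T
}

reverse_complement_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

abort_if <- function(cond, msg, ...) if (cond) stop(sprintf(msg, ...), call. = FALSE)

# uniform integer in [lo, hi], safe for lo == hi (unlike sample())
sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
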