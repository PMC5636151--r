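#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of a run draws its own substream seed from one
#' master seed and a stage label, so stages can be re-run independently and
#' a whole run is reproducible from a single integer.
#'
#' @param master Master seed (integer).
#' @param label Stage label (character scalar), e.g. `"reads:tumor_a0.3"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(label),
            length(label) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# round-half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
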