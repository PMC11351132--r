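## Hierarchical seed derivation. A study seed is split into independent
## sub-seeds per stage/experiment so that adding experiments or re-running a
## single stage never perturbs the random streams of the others.

#' Derive a sub-seed from a base seed and a label
#'
#' Deterministic integer mixing (splitmix-style multiplicative hash) of a base
#' seed with a character label and an optional index. The result is always in
#' `[0, 2^31 - 2]`, valid for [set.seed()].
#'
#' @param seed Base integer seed.
#' @param label Stage label, e.g. `"simulate"`, `"vae"`.
#' @param index Optional integer index (e.g. experiment number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647  # 2^31 - 1 (Mersenne prime)
  h <- as.double(seed) %% m
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 48271 + as.double(index) * 69621 + 1) %% m
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
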