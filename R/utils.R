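#' Derive reproducible child seeds from one base seed
#'
#' One global seed governs a whole pipeline; each stochastic step receives
#' its own seed drawn deterministically from the base seed, so partial
#' pipelines (for example, re-running only the transfer step) remain
#' reproducible.
#'
#' @param base_seed Single non-negative integer.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(base_seed, n) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L,
            is.finite(base_seed), base_seed >= 0, n >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(base_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# repr-level numeric formatting so text round-trips are lossless
fmt_num <- function(x) sprintf("%.17g", x)
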