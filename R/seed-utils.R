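#' Derive a per-operation random seed from a top-level seed
#'
#' Every stochastic operation in the package draws from its own stream, with
#' the stream seed derived deterministically from a single top-level seed and
#' a short operation label. The splitting rule is a multiplicative string
#' hash: starting from `seed mod (2^31 - 1)`, each character code `c` of
#' `label` updates `h <- (h * 31 + c) mod (2^31 - 1)`; the result is mapped
#' into `[1, 2^31 - 2]`. The rule keeps derived seeds in 32-bit integer
#' range and gives distinct streams for distinct labels.
#'
#' @param seed Integer top-level seed.
#' @param label Character scalar naming the operation (e.g. `"network"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "network")
#' derive_seed(1L, "render") # different stream
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1
  h <- abs(as.numeric(seed)) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
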