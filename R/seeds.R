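#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from one master seed. Each table type
#' (plates, expression, cells, chase, ...) draws from its own stream whose
#' seed is a deterministic function of the master seed and a stream label, so
#' generators can be re-run independently and still reproduce a full-pipeline
#' run bit-for-bit.
#'
#' The derivation is a small polynomial string hash folded into the master
#' seed, reduced modulo 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed Master seed (single integer).
#' @param label Stream label (single string), e.g. `"plates"`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "plates")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label),
            length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
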