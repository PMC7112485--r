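#' Derive a child seed from a master seed
#'
#' Counter-based derivation: every stochastic component of a run draws its own
#' seed as `derive_seed(master, index)`, so adding a new component (a new
#' counter value) never shifts the random streams of existing ones.
#'
#' @param master integer master seed (any finite number; reduced mod 2^31-1).
#' @param index non-negative integer counter identifying the component/stream.
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, 0)
#' derive_seed(42, 1)
#' @export
derive_seed <- function(master, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(index), length(index) == 1L, index >= 0)
  m31 <- 2147483647 # 2^31 - 1, prime
  s <- (abs(master) %% m31)
  # two rounds of a Lehmer-style mix; constants keep products < 2^53 exact
  s <- (s * 48271 + (index %% m31) * 69621 + 11) %% m31
  s <- (s * 16807 + 7) %% m31
  as.integer(s %% (m31 - 2L) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
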