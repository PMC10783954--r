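# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Sets the R RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state afterwards so that seeded package functions never perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# 31-bit polynomial hash of a string combined with a master seed. Used to
# derive per-pathway seeds so results do not depend on pathway iteration
# order. Modulus 2^31 - 1 keeps every derived seed a valid R integer and all
# intermediate products below 2^53 (exact in doubles).
derive_seed <- function(master_seed, name) {
  mod <- 2147483647
  h <- as.numeric(master_seed) %% mod
  for (c in utf8ToInt(as.character(name))) {
    h <- (h * 31 + c) %% mod
  }
  as.integer(h)
}

#' @keywords internal
#' @noRd
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}
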