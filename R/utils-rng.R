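# Seeded RNG helpers. Every stochastic operation in the package draws from a
# named stream derived from (base seed, stream label), so adding a stage to a
# pipeline never shifts another stage's draws. The global .Random.seed is
# always restored afterwards.

#' Derive a child seed from a base seed and a stream label
#'
#' Deterministic, platform-independent mixing of an integer seed with a
#' character label. The result is a non-negative integer below 2^31, suitable
#' for `set.seed()`.
#'
#' @param seed Integer base seed.
#' @param label Character stream label (e.g. `"impute"`, `"member3"`).
#' @return A single integer seed.
#' @export
#' @examples
#' seed_stream(1, "impute")
seed_stream <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- as.double(seed %% 2147483647)
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Half-up rounding to the nearest integer (R's round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
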