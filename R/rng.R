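# Seed substreams: every stochastic entry point takes a single master seed and
# derives named substreams from it, so no function touches hidden global state.

#' Derive a reproducible substream seed from a master seed
#'
#' Hashes a character tag together with a master seed into a deterministic
#' 32-bit seed. Used internally so that all randomness in a pipeline run flows
#' from one master seed via named substreams.
#'
#' @param master integer master seed.
#' @param tag character label of the substream (e.g. `"subject_12/other1"`).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(tag), length(tag) == 1L)
  codes <- utf8ToInt(tag)
  h <- 0
  for (ch in codes) h <- (h * 31 + ch) %% 1014573659
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
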