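#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are not disturbed. A NULL
#' seed evaluates `code` under the current stream.
#'
#' @param seed Integer seed or NULL.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a deterministic substream seed
#'
#' Stages and per-patient streams are seeded from one master seed with a
#' splitmix-style integer hash of (master, label tokens, index), so any stage
#' can be rerun in isolation and reproduces the run exactly. Result is in
#' [0, 2^31 - 2].
#'
#' @param master Master integer seed.
#' @param ... Character or integer tokens naming the substream.
#' @return Integer seed.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master) %% m
  for (tok in list(...)) {
    codes <- if (is.character(tok)) utf8ToInt(tok) else as.integer(tok)
    for (x in codes) {
      # 48271 (MINSTD multiplier); doubles hold products < 2^53 exactly
      h <- (h * 48271 + as.double(x) + 11) %% m
    }
  }
  as.integer(h)
}
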