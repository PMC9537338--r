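#' Derive a stage-specific seed from a global seed
#'
#' Combines a global integer seed with a character stage tag through a stable
#' polynomial hash, so every pipeline stage draws from its own reproducible
#' stream and adding stages never perturbs earlier stages.
#'
#' @param seed Global integer seed.
#' @param tag Character stage tag, e.g. `"single_cells"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(tag), length(tag) == 1L, nzchar(tag))
  m <- 2147480009  # large prime below 2^31
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  as.integer((h + (abs(seed) %% m) * 7919) %% m + 1)
}

# run expr under a local RNG state seeded with `seed`, restoring the caller's
# stream afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# scalar finite numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
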