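# Run `fun` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
.with_seed <- function(seed, fun) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fun()
}

#' @importFrom rlang .data
NULL
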