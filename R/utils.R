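`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logarithmically spaced grid
#'
#' @param from,to positive endpoints (included).
#' @param n number of points.
#' @return numeric vector of `n` values equally spaced in log10.
#' @export
lgrid <- function(from, to, n) {
  stopifnot(from > 0, to > 0, n >= 1)
  10^seq(log10(from), log10(to), length.out = n)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1, abs(seed) < 2^31)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Stage seeds derived from one master seed; offsets keep all values < 2^31.
derive_seeds <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed < 2^31 - 1e4)
  seed <- as.integer(seed)
  list(characterization = seed + 101L, split = seed + 202L,
       array_noise = seed + 303L, ann = seed + 404L,
       spike = seed + 505L, spike_noise = seed + 606L)
}
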