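# internal helpers shared across modules

# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is restored afterwards so seeded operations are side-effect free.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
}

# degrees -> radians
deg2rad <- function(deg) deg * pi / 180

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
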