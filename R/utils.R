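#' @keywords internal
"_PACKAGE"

## Run an expression with a private RNG state: seed the generator if a seed is
## given, and always restore the caller's .Random.seed afterwards so that
## seeded package functions never perturb the user's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a bounded child seed from a parent seed and a stream index, keeping
## the result strictly below 2^31 so it stays a valid R integer seed.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483629
}

stop_eegclean <- function(...) stop(..., call. = FALSE)

## Circular shift of a vector: positive k moves entries towards higher indices.
circ_shift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) return(x)
  c(x[(n - k + 1L):n], x[1L:(n - k)])
}
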