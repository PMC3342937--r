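# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`, then
#' restores the previous RNG state, so that generator functions are pure
#' functions of their inputs and never perturb the caller's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("`seed` must be a single non-missing integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# check a single numeric scalar
is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x) &&
    (!positive || x > 0)
}
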