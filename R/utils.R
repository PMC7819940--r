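# internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards so that seeded package
#' functions do not perturb an enclosing simulation.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# near-integer test used for grid divisibility checks
is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
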