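#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

abort_input <- function(...) stop(..., call. = FALSE)

# scalar checks used across modules
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    abort_input(sprintf("`%s` must be strictly positive and finite", name))
  invisible(x)
}
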