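# Internal helpers: scoped RNG and stage-tagged errors.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Error with a stage label so pipeline failures name the failing module.
stage_error <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

# Run code, re-tagging any error with the stage name.
with_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    m <- conditionMessage(e)
    if (grepl("^\\[", m)) stop(e) else stage_error(stage, m)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
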