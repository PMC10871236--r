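# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  expr
}
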