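# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards so seeded helpers do not perturb user simulations.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
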