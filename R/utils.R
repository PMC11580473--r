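# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards. seed = NULL leaves the
# RNG stream alone.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
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

# Derive a deterministic 31-bit child seed from a parent seed and a label.
.derive_seed <- function(seed, label) {
  h <- sum(as.integer(charToRaw(label)) * seq_along(charToRaw(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
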