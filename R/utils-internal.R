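# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

# Linear interpolation across NA runs whose time gap (between the flanking
# observed samples) is at most maxGap seconds; longer gaps and edge runs stay
# NA.
.fillGaps <- function(t, v, maxGap = 2) {
  isna <- is.na(v)
  if (!any(isna) || all(isna)) return(v)
  obs <- which(!isna)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- v
  for (j in which(r$values)) {
    a <- starts[j] - 1L
    b <- ends[j] + 1L
    if (a < 1L || b > length(v)) next
    if (t[b] - t[a] > maxGap) next
    idx <- starts[j]:ends[j]
    out[idx] <- v[a] + (v[b] - v[a]) * (t[idx] - t[a]) / (t[b] - t[a])
  }
  out
}

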