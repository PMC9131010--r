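# Seeded evaluation that leaves the caller's RNG state untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(restoreSeed(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Stable per-stage seed derived from one global seed: polynomial hash of the
# stage name folded into [0, 2^31 - 2]. One knob, independent streams.
stageSeed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147480000
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480000 + 1)
}

# two-sided normal-tail p for a z statistic
zToP <- function(z) 2 * pnorm(-abs(z))
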