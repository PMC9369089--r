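# Evaluate an expression under a temporary RNG state. The caller's
# .Random.seed is restored afterwards so seeded package functions do
# not perturb the session RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Derive a named substream seed from a root seed; keeps all randomness
# (split / init / shuffle / subsample / folds) reproducible from one
# integer while decorrelating the streams. Result stays below 2^31.
.deriveSeed <- function(seed, stream) {
  offs <- c(split = 11L, init = 23L, shuffle = 41L, subsample = 59L,
            fold = 73L, sim = 97L, scores = 113L)
  off <- offs[[stream]]
  as.integer((as.numeric(seed) * 2654435.0 + off * 40503.0) %%
             2147483647.0)
}

.stopIfNot01 <- function(y, what = "labels") {
  if (!all(y %in% c(0, 1)))
    stop(what, " must be binary 0/1", call. = FALSE)
  invisible(as.integer(y))
}
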