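#' @include AllClasses.R
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic small-integer hash of a tuple, kept below 2^31 so it can be
# fed to set.seed(). Used to give every (target, level, sample) stimulus a
# fixed private seed derived from the base seed.
hashSeed <- function(...) {
  parts <- c(...)
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p, "|"))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}
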