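# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream. All stochastic entry points route their draws through this, so a
# run is fully determined by the seeds it is handed.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seeds derived from one master seed, kept inside
# the 32-bit integer range.
derive_seed <- function(master, stage) {
  offsets <- c(fit = 101L, train = 211L, ga = 307L, simulate = 401L,
               split = 503L)
  if (!stage %in% names(offsets)) stop("unknown stage '", stage, "'")
  as.integer((as.numeric(master) * 1009 + offsets[[stage]]) %% .Machine$integer.max)
}
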