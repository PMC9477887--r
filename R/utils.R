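# Internal helpers shared across modules.

# Round half away from zero for non-negative input. base::round() rounds
# half to even, which would make the tie-smoothing average and the count
# rounding of the simulator depend on parity.
round_half_up <- function(x) floor(x + 0.5)

# Evaluate code under a temporary RNG state; the caller's stream is
# restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds: one master seed fans out to named
# components (jitter per taxon, simulation draws, CV folds) so that
# taxon-parallel execution is reproducible regardless of scheduling.
# Kept strictly below 2^31 - 1.
substream_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  streams <- c(jitter = 11L, simulate = 23L, folds = 37L, assign = 41L,
               zeros = 53L, split = 67L)
  sid <- if (is.character(stream)) {
    if (!stream %in% names(streams)) stop("unknown RNG stream: ", stream)
    streams[[stream]]
  } else as.integer(stream)
  as.integer((abs(seed) * 48271 + sid * 1664525 + index * 22695477) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable integer hash of a taxon identifier, so a taxon keeps its jitter
# stream when the table is split into prevalence sub-tables or corrected
# in parallel.
taxon_stream_index <- function(taxon_id) {
  v <- utf8ToInt(as.character(taxon_id))
  as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 1000003)
}
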