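# Reproducible random substreams for common-random-number (CRN) pairing.
#
# Every uniform deviate consumed by the engine is addressed by the key
# (master_seed, outer_index, patient_key, purpose, block): the same key
# always yields the same deviates, independent of the treatment arm and of
# the order in which patients are processed. Purposes separate the deviates
# used for relapse sojourns, remission sojourns, death candidates and
# episode-type decisions, so that the k-th such decision of a patient uses
# the same uniform in both arms even when earlier event *times* differ.

PURPOSE_RELAPSE <- 1L
PURPOSE_REMISSION <- 2L
PURPOSE_DEATH <- 3L
PURPOSE_EPISODE_TYPE <- 4L

STREAM_BLOCK <- 64L
MIX_MOD <- 2147483647 # 2^31 - 1; keeps products exact in doubles

# Deterministically mix any number of non-negative integers into a seed in
# [1, 2^31 - 2] (Lehmer-style modular hash; 48271 * 2^32 < 2^53 so all
# intermediate products are exact).
mix_seed <- function(...) {
  ks <- c(...)
  h <- 104729
  for (k in ks) {
    h <- ((h + (k %% MIX_MOD) + 1) * 48271) %% MIX_MOD
  }
  as.integer(max(1, h))
}

# A stream set for one (master_seed, outer_index, patient_key) triple.
# Deviates are materialised lazily in blocks so that extension of one
# purpose never disturbs another.
new_streams <- function(master_seed, outer_index, patient_key) {
  st <- new.env(parent = emptyenv())
  st$master <- as.integer(master_seed)
  st$outer <- as.integer(outer_index)
  st$patient <- as.integer(patient_key)
  st$u <- vector("list", 4L)
  st$n <- integer(4L)
  st
}

next_u <- function(st, purpose) {
  i <- st$n[purpose] + 1L
  st$n[purpose] <- i
  v <- st$u[[purpose]]
  if (i > length(v)) {
    block <- length(v) %/% STREAM_BLOCK
    seed <- mix_seed(st$master, st$outer, st$patient, purpose, block)
    v <- c(v, with_seed(seed, runif(STREAM_BLOCK)))
    st$u[[purpose]] <- v
  }
  v[[i]]
}

# Run code under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
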