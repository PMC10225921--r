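# Internal helpers.

# Seed the RNG for the duration of the calling function, restoring the
# caller's random state afterwards so seeded components compose without
# perturbing each other's streams. seed = NULL leaves the stream alone.
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}

# Derive a child seed from a root seed and a stage label, staying inside
# 32-bit integer range.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
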