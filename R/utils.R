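# run code under a local RNG state, restoring the caller's stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic per-component sub-seed derivation from one global seed, kept
# below 2^31 - 1; adding a new stream never perturbs existing ones
mix_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 + stream * 9973) %%
    2147483647L
}

# Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1   # degenerate guard
  g / sum(g)
}
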