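# Deterministic sub-seed derivation: mixes a master seed with integer ids
# (scale index, permutation index, ...) so that every surrogate stream is
# reproducible in isolation.  Kept strictly below 2^31 - 1.
subseed <- function(master, ...) {
  s <- as.double(master %% 2147483629)
  for (id in c(...)) s <- (s * 69069 + as.double(id) + 1) %% 2147483629
  as.integer(s)
}

# Evaluate expr under a temporary RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# z-score columns; zero-variance columns are left centred (the 1e-8 jitter
# added afterwards breaks the resulting exact ties).
standardize_cols <- function(m) {
  if (ncol(m) == 0) return(m)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, sd, "/")
}

# Gaussianized rank (normal-scores) transform per column: makes every
# marginal exactly standard normal, so surrogate-induced changes in marginal
# shape cannot shift the estimator's bias; dependence structure (the copula)
# is untouched and kNN MI is approximately invariant under monotone maps.
rank_gauss_cols <- function(m) {
  if (ncol(m) == 0) return(m)
  n <- nrow(m)
  apply(m, 2, function(col) stats::qnorm((rank(col, ties.method = "average") -
                                            0.5) / n))
}

# deterministic tie-breaking jitter for the kNN search
add_jitter <- function(m, seed, amplitude = 1e-8) {
  if (length(m) == 0) return(m)
  with_seed(seed, m + matrix(stats::runif(length(m), -amplitude, amplitude),
                             nrow = nrow(m)))
}
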