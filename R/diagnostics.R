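# Convergence diagnostics for the MCMC path.

# classic split-chain potential scale reduction factor
split_rhat <- function(chains) {
  # chains: list of iteration x parameter matrices (same dims)
  half <- floor(nrow(chains[[1]]) / 2)
  seqs <- unlist(lapply(chains, function(ch) {
    list(ch[seq_len(half), , drop = FALSE],
         ch[seq(nrow(ch) - half + 1, nrow(ch)), , drop = FALSE])
  }), recursive = FALSE)
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    x <- vapply(seqs, function(s) c(mean(s[, j]), stats::var(s[, j])),
                numeric(2))
    W <- mean(x[2, ])
    B <- half * stats::var(x[1, ])
    if (W <= 0) return(1)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
}

# effective sample size across chains (coda's spectral estimator per chain)
ess_chains <- function(chains) {
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    sum(vapply(chains, function(ch) {
      v <- stats::var(ch[, j])
      if (v <= 0) return(0)
      s0 <- coda::spectrum0.ar(ch[, j])$spec
      nrow(ch) * v / s0
    }, numeric(1)))
  }, numeric(1))
}
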