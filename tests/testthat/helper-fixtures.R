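# shared fixtures, built in code

# fixed 4+4 toy data set used throughout the oracle comparisons
toy_data <- function() {
  two_sample_data(c(-1.1, -0.2, 0.3, 0.9), c(0.1, 0.8, 1.4, 2.0))
}

# summary statistics of the hypothetical replication study
# (20 + 20 observations, means 12.35/3.65, SDs 12.18/3.94)
replication_summary <- function() {
  two_sample_summary(20, 12.35, 12.18, 20, 3.65, 3.94)
}

# light but reliable sampler settings for tests
test_sampler <- function(...) {
  sampler_settings(warmup = 500, samples = 1000, max_tries = 3, ...)
}

# independent 1-D dense-grid Bayes factor for the equal-variance normal
# model: trapezoid rule over delta on [-50, 50], conditional marginal
# evaluated through the noncentral-t identity (a different evaluation route
# than the production Gauss-Legendre path)
dense_grid_bf_student <- function(stats, n_nodes = 1e6,
                                  priors = prior_settings()) {
  sf <- mbttest:::normal_suffstats(stats)
  delta <- seq(-50, 50, length.out = n_nodes)
  lg <- mbttest:::cond_logml_normal_nct(sf, delta, 0.5) +
    stats::dcauchy(delta, priors$delta_location, priors$delta_scale, log = TRUE)
  h <- delta[2] - delta[1]
  w <- rep(h, n_nodes); w[c(1, n_nodes)] <- h / 2
  m <- max(lg)
  log_num <- m + log(sum(w * exp(lg - m)))
  log_den <- mbttest:::cond_logml_normal_nct(sf, 0, 0.5)
  exp(log_num - log_den)
}
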