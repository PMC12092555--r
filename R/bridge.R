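# Bridge estimator for the log marginal likelihood from posterior draws.
#
# A multivariate-normal proposal is moment-matched to one half of the
# posterior draws; the iterative optimal-bridge update of Meng & Wong is then
# run between the proposal sample and the second half. The relative
# mean-squared error formula accounts for autocorrelation in the posterior
# draws through an AR spectral estimate at frequency zero.

mvn_fit <- function(z) {
  m <- colMeans(z)
  S <- stats::cov(z)
  S <- S + diag(1e-10, ncol(z))
  list(mean = m, chol = chol(S))
}

mvn_logpdf <- function(z, fit) {
  d <- ncol(z)
  zc <- sweep(z, 2, fit$mean)
  sol <- backsolve(fit$chol, t(zc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(fit$chol))) - 0.5 * colSums(sol^2)
}

mvn_draw <- function(n, fit) {
  d <- length(fit$mean)
  z <- matrix(stats::rnorm(n * d), n, d) %*% fit$chol
  sweep(z, 2, fit$mean, `+`)
}

# z_post: posterior draws (rows) in unconstrained space, ordered by chain;
# log_post: vectorized function matrix -> numeric of unnormalized log
# posterior densities. Returns list(log_ml, log_ml_se, n_iter).
bridge_logml <- function(z_post, log_post, tol = 1e-6, max_iter = 1000L) {
  n <- nrow(z_post)
  first <- seq_len(floor(n / 2))
  fit <- mvn_fit(z_post[first, , drop = FALSE])
  z2 <- z_post[-first, , drop = FALSE]   # posterior side of the bridge
  n1 <- nrow(z2)
  n2 <- n1                               # proposal sample of equal size
  zp <- mvn_draw(n2, fit)

  l1 <- log_post(z2) - mvn_logpdf(z2, fit)   # on posterior draws
  l2 <- log_post(zp) - mvn_logpdf(zp, fit)   # on proposal draws
  if (!any(is.finite(l2))) stop_mbt("bridge proposal missed the posterior entirely.")
  lstar <- stats::median(l1[is.finite(l1)])
  s1 <- n1 / (n1 + n2); s2 <- n2 / (n1 + n2)

  r <- exp(log_mean_exp(l2[is.finite(l2)]) - lstar)  # importance-sampling start
  iter <- 0L
  repeat {
    iter <- iter + 1L
    e2 <- exp(l2 - lstar); e1 <- exp(l1 - lstar)
    num <- mean(e2 / (s1 * e2 + s2 * r))
    den <- mean(1 / (s1 * e1 + s2 * r))
    r_new <- num / den
    if (!is.finite(r_new) || r_new <= 0) stop_mbt("bridge iteration diverged.")
    done <- abs(r_new - r) / r_new < tol
    r <- r_new
    if (done || iter >= max_iter) break
  }
  if (iter >= max_iter) {
    stop_mbt(sprintf("bridge did not converge in %d iterations.", max_iter))
  }

  # relative MSE (delta method); spectral variance for the autocorrelated side
  f1 <- exp(l2 - lstar) / (s1 * exp(l2 - lstar) + s2 * r)
  f2 <- 1 / (s1 * exp(l1 - lstar) + s2 * r)
  rho_f2 <- tryCatch(coda::spectrum0.ar(f2)$spec, error = function(e) stats::var(f2))
  re2 <- stats::var(f1) / (n2 * mean(f1)^2) + rho_f2 / (n1 * mean(f2)^2)
  list(log_ml = log(r) + lstar, log_ml_se = sqrt(max(re2, 0)), n_iter = iter)
}
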