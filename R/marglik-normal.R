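# Marginal likelihoods for normal-likelihood models.
#
# Conditional on (delta, rho) the grand mean and scale integrate out in
# closed form under the Jeffreys prior p(mu, sigma) ~ 1/sigma, leaving
#   p(y | delta, rho) = C(rho) * exp(-wt*delta^2/2) * int_0^inf u^(N-2)
#                       exp(-p u^2/2 + q u) du,   u = 1/sigma,
# with p = S + wt*dbar^2, q = wt*dbar*delta; S is the precision-weighted
# residual sum of squares and wt the harmonic precision weight. The u
# integral is a noncentral-t density in disguise; it is evaluated by
# mode-centred Gauss-Legendre quadrature in log space, which stays accurate
# at noncentralities where the textbook noncentral-t identity degrades.

# log of int_0^inf u^k exp(-p u^2/2 + q u) du, vectorized over (p, q)
log_int_u <- function(k, p, q, n_nodes = 120L) {
  stopifnot(k >= 1, all(p > 0))
  ustar <- (q + sqrt(q^2 + 4 * p * k)) / (2 * p)
  h <- 1 / sqrt(k / ustar^2 + p)
  lo <- pmax(0, ustar - 12 * h)
  hi <- ustar + 12 * h
  gl <- gauss_legendre_01(n_nodes)
  # nodes matrix: length(p) x n_nodes
  u <- lo + outer(hi - lo, gl$x)
  f <- k * log(u) - (p / 2) * u^2 + q * u
  m <- apply(f, 1L, max)
  m + log(as.vector(exp(f - m) %*% gl$w) * (hi - lo))
}

# cached Gauss-Legendre rule on (0, 1)
gauss_legendre_01 <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      g <- pracma::gaussLegendre(n, 0, 1)
      cache[[key]] <- list(x = g$x, w = g$w)
    }
    cache[[key]]
  }
})

# sufficient-statistic bundle reused by every conditional evaluation
normal_suffstats <- function(stats) {
  f <- summary_fields(stats)
  list(n1 = f$n1, n2 = f$n2, N = f$n1 + f$n2, k = f$n1 + f$n2 - 2,
       ss1 = (f$n1 - 1) * f$sd1^2, ss2 = (f$n2 - 1) * f$sd2^2,
       dbar = f$mean2 - f$mean1)
}

# log p(y | delta, rho) for the normal likelihood; vectorized over
# equal-length delta and rho
cond_logml_normal <- function(sf, delta, rho) {
  c1s <- 2 * (1 - rho); c2s <- 2 * rho
  w1 <- sf$n1 / c1s; w2 <- sf$n2 / c2s
  W <- w1 + w2; wt <- w1 * w2 / W
  S <- sf$ss1 / c1s + sf$ss2 / c2s
  p <- S + wt * sf$dbar^2
  q <- wt * sf$dbar * delta
  -(sf$N / 2) * log(2 * pi) + 0.5 * log(2 * pi) - 0.5 * log(W) -
    (sf$n1 / 2) * log(c1s) - (sf$n2 / 2) * log(c2s) -
    (wt / 2) * delta^2 + log_int_u(sf$k, p, q)
}

# independent evaluation route via the noncentral-t density identity;
# used as a cross-check in the test suite
cond_logml_normal_nct <- function(sf, delta, rho) {
  c1s <- 2 * (1 - rho); c2s <- 2 * rho
  w1 <- sf$n1 / c1s; w2 <- sf$n2 / c2s
  W <- w1 + w2; wt <- w1 * w2 / W
  S <- sf$ss1 / c1s + sf$ss2 / c2s
  k <- sf$k
  tt <- sf$dbar * sqrt(wt * k / S)
  log_ck <- log(2) + (k / 2) * log(k / 2) - lgamma(k / 2) - 0.5 * log(2 * pi)
  -((sf$N - 1) / 2) * log(2 * pi) - 0.5 * log(W) -
    (sf$n1 / 2) * log(c1s) - (sf$n2 / 2) * log(c2s) +
    ((k + 1) / 2) * log(k / S) - log_ck +
    stats::dt(tt, k, ncp = delta * sqrt(wt), log = TRUE)
}

# quantile transform of the (possibly truncated) Cauchy prior on delta
delta_from_u <- function(u, priors) {
  lo <- 0; hi <- 1
  tr <- priors$delta_truncation
  if (!is.null(tr)) {
    lo <- stats::pcauchy(tr[1], priors$delta_location, priors$delta_scale)
    hi <- stats::pcauchy(tr[2], priors$delta_location, priors$delta_scale)
  }
  stats::qcauchy(lo + u * (hi - lo), priors$delta_location, priors$delta_scale)
}

rho_from_u <- function(u, priors) {
  stats::qbeta(u, priors$rho_shape[1], priors$rho_shape[2])
}

# Gauss-Legendre rule for integrating f(rho) against the Beta(a, b) prior:
# the substitution rho = sin^2(theta) removes the sqrt-type endpoint
# singularities of the Beta density, so the rule converges spectrally for
# smooth f (exactly so for half-integer shapes such as the default 1.5)
beta_quad <- function(n, a, b) {
  gl <- gauss_legendre_01(n)
  theta <- gl$x * (pi / 2)
  s <- sin(theta); co <- cos(theta)
  lw <- log(gl$w) + log(pi) + (2 * a - 1) * log(s) + (2 * b - 1) * log(co) -
    lbeta(a, b)
  list(x = s^2, lw = lw)
}

# one fixed-order tensor quadrature pass over the free members of (delta, rho)
logml_normal_pass <- function(sf, spec, priors, n_nodes) {
  gl <- gauss_legendre_01(n_nodes)
  if (spec$effect == "null" && spec$variances == "equal") {
    return(cond_logml_normal(sf, 0, 0.5))
  }
  if (spec$effect == "alternative" && spec$variances == "equal") {
    d <- delta_from_u(gl$x, priors)
    lg <- cond_logml_normal(sf, d, rep(0.5, n_nodes))
    m <- max(lg)
    return(m + log(sum(gl$w * exp(lg - m))))
  }
  bq <- beta_quad(n_nodes, priors$rho_shape[1], priors$rho_shape[2])
  if (spec$effect == "null") {
    lg <- cond_logml_normal(sf, rep(0, n_nodes), bq$x) + bq$lw
    m <- max(lg)
    return(m + log(sum(exp(lg - m))))
  }
  # 2-D: delta x rho
  d <- delta_from_u(gl$x, priors)
  dd <- rep(d, times = n_nodes)
  rr <- rep(bq$x, each = n_nodes)
  lg <- matrix(cond_logml_normal(sf, dd, rr), n_nodes, n_nodes)
  lg <- sweep(lg, 2, bq$lw, `+`)
  lg <- sweep(lg, 1, log(gl$w), `+`)
  m <- max(lg)
  m + log(sum(exp(lg - m)))
}

#' Marginal likelihood of a normal-likelihood model from summary statistics
#'
#' Integrates the grand mean and scale analytically under the Jeffreys
#' nuisance prior and the remaining free parameters (none, \eqn{\delta},
#' \eqn{\rho}, or both) by adaptive tensor Gauss-Legendre quadrature after a
#' prior-quantile variable transform that bounds the heavy-tailed Cauchy
#' direction. Node counts are doubled until successive estimates agree to
#' `rel_tol`; the result is deterministic with `log_ml_se = 0`.
#'
#' @param stats A [two_sample_summary()] (or a `two_sample_data`, which is
#'   summarized first).
#' @param spec A [model_spec()] with `likelihood = "normal"`.
#' @param priors An [prior_settings()] object.
#' @param rel_tol Relative tolerance on the marginal likelihood.
#' @return A `model_fit` object; see [logml_t_model()] for the shared layout.
#' @examples
#' st <- two_sample_summary(10, 0.5, 1, 10, 0, 1)
#' fit1 <- logml_normal_model(st, model_spec("alternative", "equal", "normal"))
#' fit0 <- logml_normal_model(st, model_spec("null", "equal", "normal"))
#' bayes_factor(fit1, fit0)
#' @export
logml_normal_model <- function(stats, spec, priors = prior_settings(),
                               rel_tol = 1e-8) {
  if (inherits(stats, "two_sample_data")) stats <- summarize_groups(stats)
  stopifnot(inherits(spec, "mbt_model_spec"))
  if (spec$likelihood != "normal") {
    stop_mbt("`logml_normal_model` handles normal-likelihood models only.")
  }
  sf <- normal_suffstats(stats)
  orders <- c(65L, 129L, 257L, 513L, 1025L)
  last <- logml_normal_pass(sf, spec, priors, orders[1])
  achieved <- Inf
  for (n in orders[-1]) {
    cur <- logml_normal_pass(sf, spec, priors, n)
    achieved <- abs(cur - last)  # |log difference| ~ relative error
    last <- cur
    if (achieved < rel_tol) break
  }
  if (achieved >= rel_tol) {
    stop_mbt(sprintf(
      "quadrature did not reach rel_tol = %g (achieved %g) for model %s.",
      rel_tol, achieved, spec$label))
  }
  new_model_fit(spec = spec, log_ml = last, log_ml_se = 0,
                method = "quadrature", stats = stats, priors = priors,
                diagnostics = tibble::tibble(achieved_tol = min(achieved, rel_tol)))
}

# constructor shared by the quadrature and sampler paths
new_model_fit <- function(spec, log_ml, log_ml_se, method, stats = NULL,
                          priors = NULL, draws = NULL, diagnostics = NULL,
                          hash = NULL) {
  if (!is.finite(log_ml)) {
    stop_mbt(sprintf("non-finite log marginal likelihood for model %s.",
                     spec$label))
  }
  structure(list(spec = spec, log_ml = log_ml, log_ml_se = log_ml_se,
                 method = method, stats = stats, priors = priors,
                 draws = draws, diagnostics = diagnostics,
                 hash = hash %||% fit_hash(stats)),
            class = "mbt_model_fit")
}

fit_hash <- function(stats) {
  if (is.null(stats)) return(NA_character_)
  f <- summary_fields(stats)
  data_hash(c(f$n1, f$mean1, f$sd1), c(f$n2, f$mean2, f$sd2))
}

#' @export
print.mbt_model_fit <- function(x, ...) {
  cat(sprintf("<model_fit %s>  log ML = %.4f (SE %.4f, %s)\n",
              x$spec$label, x$log_ml, x$log_ml_se, x$method))
  invisible(x)
}

#' Bayes factor between two fitted models
#'
#' `exp(log_ml1 - log_ml0)`, with the Monte-Carlo standard errors of the two
#' log marginal likelihoods propagated in quadrature. Both fits must come
#' from the same data (checked via a data hash) and may not be compared
#' otherwise.
#'
#' @param fit1,fit0 `model_fit` objects for the numerator and denominator.
#' @return A list with `bf`, `log_bf` and `log_bf_se`.
#' @export
bayes_factor <- function(fit1, fit0) {
  stopifnot(inherits(fit1, "mbt_model_fit"), inherits(fit0, "mbt_model_fit"))
  if (!is.na(fit1$hash) && !is.na(fit0$hash) && fit1$hash != fit0$hash) {
    stop_mbt("the two fits were computed on different data sets.")
  }
  log_bf <- fit1$log_ml - fit0$log_ml
  list(bf = exp(log_bf), log_bf = log_bf,
       log_bf_se = sqrt(fit1$log_ml_se^2 + fit0$log_ml_se^2))
}

# posterior draws of (delta, rho) for a quadrature fit, by inverse-CDF
# sampling on a fine midpoint grid in prior-quantile space with within-cell
# jitter; mu/sigma are not tracked on this path (NA)
sample_posterior_normal <- function(fit, n_draws, seed = NULL) {
  spec <- fit$spec; priors <- fit$priors
  sf <- normal_suffstats(fit$stats)
  free_d <- spec$effect == "alternative"
  free_r <- spec$variances == "unequal"
  with_seed(seed, {
    if (!free_d && !free_r) {
      return(tibble::tibble(mu = NA_real_, sigma = NA_real_,
                            delta = rep(0, n_draws), rho = 0.5, nu = Inf))
    }
    if (xor(free_d, free_r)) {
      m <- 4096L
      u <- (seq_len(m) - 0.5) / m
      lw <- if (free_d) cond_logml_normal(sf, delta_from_u(u, priors), rep(0.5, m))
            else cond_logml_normal(sf, rep(0, m), rho_from_u(u, priors))
      w <- exp(lw - max(lw))
      idx <- sample.int(m, n_draws, replace = TRUE, prob = w)
      uu <- u[idx] + stats::runif(n_draws, -0.5, 0.5) / m
      tibble::tibble(mu = NA_real_, sigma = NA_real_,
                     delta = if (free_d) delta_from_u(uu, priors) else 0,
                     rho = if (free_r) rho_from_u(uu, priors) else 0.5,
                     nu = Inf)
    } else {
      m <- 256L
      u <- (seq_len(m) - 0.5) / m
      d <- delta_from_u(u, priors); r <- rho_from_u(u, priors)
      lw <- matrix(cond_logml_normal(sf, rep(d, times = m), rep(r, each = m)), m, m)
      w <- exp(lw - max(lw))
      idx <- sample.int(m * m, n_draws, replace = TRUE, prob = as.vector(w))
      iu <- (idx - 1L) %% m + 1L
      iv <- (idx - 1L) %/% m + 1L
      ud <- u[iu] + stats::runif(n_draws, -0.5, 0.5) / m
      ur <- u[iv] + stats::runif(n_draws, -0.5, 0.5) / m
      tibble::tibble(mu = NA_real_, sigma = NA_real_,
                     delta = delta_from_u(ud, priors),
                     rho = rho_from_u(ur, priors), nu = Inf)
    }
  })
}
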