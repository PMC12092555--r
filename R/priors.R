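#' Prior settings for the model ensemble
#'
#' Collects the prior hyperparameters shared by every model of the ensemble:
#'
#' * the effect-size prior, a Cauchy distribution on Cohen's \eqn{\delta}
#'   (default location 0, scale \eqn{1/\sqrt{2}}), optionally truncated to a
#'   one-sided interval;
#' * the precision-proportion prior, a Beta distribution on \eqn{\rho}, the
#'   share of the total precision contributed by group 1 (default
#'   Beta(1.5, 1.5), concentrating mass on realistic variance ratios);
#' * the degrees-of-freedom prior for t-likelihood models, a unit-scale
#'   exponential shifted to the right of 2 (so the t likelihood always has a
#'   finite mean and variance, keeping Cohen's \eqn{\delta} well defined);
#' * prior model probabilities over the ensemble members (default uniform).
#'
#' The nuisance grand mean and scale \eqn{(\mu, \sigma)} carry the improper
#' Jeffreys prior \eqn{p(\mu,\sigma) \propto 1/\sigma} in every model, so its
#' arbitrary constant cancels from all Bayes factors.
#'
#' @param delta_location,delta_scale Location and scale of the Cauchy prior
#'   on \eqn{\delta}. Scale must be positive.
#' @param delta_truncation Optional length-2 numeric interval restricting
#'   \eqn{\delta} (e.g. `c(0, Inf)` for a directional test); `NULL` for the
#'   default two-sided prior.
#' @param rho_shape Length-2 positive shapes of the Beta prior on \eqn{\rho}.
#' @param nu_shift,nu_scale Shift and scale of the exponential prior on
#'   \eqn{\nu}; the shift must be at least 2.
#' @param model_probs Optional prior model probabilities; length must match
#'   the ensemble in use. `NULL` means uniform.
#' @param sdr_convention Either `"group1/group2"` (the default:
#'   \eqn{SDR = \sigma_1/\sigma_2 = \sqrt{(1-\rho)/\rho}} with \eqn{\rho} the
#'   group-1 precision share) or `"group2/group1"` to flip the reported ratio.
#' @return An object of class `mbt_priors`.
#' @examples
#' prior_settings()
#' prior_settings(delta_scale = 0.05)  # tightly informed effect-size prior
#' @export
prior_settings <- function(delta_location = 0, delta_scale = 1 / sqrt(2),
                           delta_truncation = NULL,
                           rho_shape = c(1.5, 1.5),
                           nu_shift = 2, nu_scale = 1,
                           model_probs = NULL,
                           sdr_convention = c("group1/group2", "group2/group1")) {
  assert_scalar_num(delta_location, "delta_location")
  assert_scalar_num(delta_scale, "delta_scale", 0, strict = TRUE)
  if (!is.null(delta_truncation)) {
    if (length(delta_truncation) != 2L || delta_truncation[1] >= delta_truncation[2]) {
      stop_mbt("`delta_truncation` must be an increasing length-2 interval.")
    }
  }
  if (length(rho_shape) != 2L || any(rho_shape <= 0)) {
    stop_mbt("`rho_shape` must be two positive Beta shape parameters.")
  }
  assert_scalar_num(nu_shift, "nu_shift", 2)
  assert_scalar_num(nu_scale, "nu_scale", 0, strict = TRUE)
  if (!is.null(model_probs)) {
    if (any(model_probs < 0) || abs(sum(model_probs) - 1) > 1e-8) {
      stop_mbt("`model_probs` must be nonnegative and sum to 1.")
    }
    model_probs <- model_probs / sum(model_probs)
  }
  structure(list(
    delta_location = delta_location, delta_scale = delta_scale,
    delta_truncation = delta_truncation,
    rho_shape = as.numeric(rho_shape),
    nu_shift = nu_shift, nu_scale = nu_scale,
    model_probs = model_probs,
    sdr_convention = match.arg(sdr_convention)
  ), class = "mbt_priors")
}

#' @export
print.mbt_priors <- function(x, ...) {
  cat("<mbt_priors>\n")
  tr <- if (is.null(x$delta_truncation)) "" else
    sprintf(" truncated to [%g, %g]", x$delta_truncation[1], x$delta_truncation[2])
  cat(sprintf("  delta ~ Cauchy(%g, %.4g)%s\n", x$delta_location, x$delta_scale, tr))
  cat(sprintf("  rho   ~ Beta(%g, %g)\n", x$rho_shape[1], x$rho_shape[2]))
  cat(sprintf("  nu    ~ %g + Exponential(scale = %g)\n", x$nu_shift, x$nu_scale))
  cat(sprintf("  model probabilities: %s\n",
              if (is.null(x$model_probs)) "uniform" else
                paste(signif(x$model_probs, 3), collapse = ", ")))
  invisible(x)
}

#' Read / write prior settings as YAML or JSON
#'
#' The on-disk layout is `{delta: {family: cauchy, location, scale,
#' truncation}, rho: {a, b}, nu: {shift, scale}, model_probs: [...]}`.
#'
#' @param priors An `mbt_priors` object.
#' @param path File path; extension `.json` selects JSON, anything else YAML.
#' @return `read_prior_settings` returns an `mbt_priors`.
#' @export
write_prior_settings <- function(priors, path) {
  stopifnot(inherits(priors, "mbt_priors"))
  x <- list(
    delta = list(family = "cauchy", location = priors$delta_location,
                 scale = priors$delta_scale,
                 truncation = priors$delta_truncation),
    rho = list(a = priors$rho_shape[1], b = priors$rho_shape[2]),
    nu = list(shift = priors$nu_shift, scale = priors$nu_scale),
    model_probs = priors$model_probs,
    sdr_convention = priors$sdr_convention
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_prior_settings
#' @export
read_prior_settings <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  prior_settings(
    delta_location = x$delta$location %||% 0,
    delta_scale = x$delta$scale %||% (1 / sqrt(2)),
    delta_truncation = unlist(x$delta$truncation),
    rho_shape = c(x$rho$a %||% 1.5, x$rho$b %||% 1.5),
    nu_shift = x$nu$shift %||% 2, nu_scale = x$nu$scale %||% 1,
    model_probs = unlist(x$model_probs),
    sdr_convention = x$sdr_convention %||% "group1/group2"
  )
}

#' Precision proportion from group variances
#'
#' \eqn{\rho} is the share of the total precision (inverse variance)
#' contributed by group 1: with variances 2 and 4 the precisions are 1/2 and
#' 1/4, so \eqn{\rho = (1/2)/(3/4) = 2/3}.
#'
#' @param var1,var2 Positive group variances.
#' @return \eqn{\rho \in (0, 1)}.
#' @examples
#' rho_from_variances(2, 4)  # 2/3
#' @export
rho_from_variances <- function(var1, var2) {
  if (any(!is.finite(var1)) || any(!is.finite(var2)) ||
      any(var1 <= 0) || any(var2 <= 0)) {
    stop_mbt("variances must be finite and positive.")
  }
  (1 / var1) / (1 / var1 + 1 / var2)
}

#' Convert between the precision proportion and the SD ratio
#'
#' Under the default convention \eqn{SDR = \sigma_1/\sigma_2 =
#' \sqrt{(1-\rho)/\rho}}: a large group-1 precision share means a *small*
#' group-1 standard deviation. `convention = "group2/group1"` reports the
#' reciprocal ratio instead.
#'
#' @param rho Precision proportion strictly inside (0, 1).
#' @param sdr Positive standard-deviation ratio.
#' @param convention Which ratio the SDR denotes; see [prior_settings()].
#' @return The transformed value; the two functions are mutually inverse.
#' @examples
#' sdr_from_rho(0.5)        # 1
#' sdr_from_rho(2 / 3)      # sqrt(1/2): group 1 is the more precise group
#' rho_from_sdr(sdr_from_rho(0.3))
#' @export
sdr_from_rho <- function(rho, convention = "group1/group2") {
  if (any(rho <= 0 | rho >= 1)) stop_mbt("`rho` must lie strictly in (0, 1).")
  sdr <- sqrt((1 - rho) / rho)
  if (convention == "group2/group1") 1 / sdr else sdr
}

#' @rdname sdr_from_rho
#' @export
rho_from_sdr <- function(sdr, convention = "group1/group2") {
  if (any(!is.finite(sdr) | sdr <= 0)) stop_mbt("`sdr` must be finite and positive.")
  if (convention == "group2/group1") sdr <- 1 / sdr
  1 / (1 + sdr^2)
}

#' Per-group parameters implied by the common parametrization
#'
#' The common parameters are the grand mean \eqn{\mu}, the grand scale
#' \eqn{\sigma} (defined through \eqn{\sigma_1^2 + \sigma_2^2 = 2\sigma^2}),
#' Cohen's \eqn{\delta} and the precision proportion \eqn{\rho}. The mean
#' difference is \eqn{MD = \delta\sigma}, split symmetrically:
#' \eqn{\mu_1 = \mu - MD/2}, \eqn{\mu_2 = \mu + MD/2}; the group variances are
#' \eqn{\sigma_1^2 = 2\sigma^2(1-\rho)} and \eqn{\sigma_2^2 = 2\sigma^2\rho}.
#'
#' @param mu,sigma Grand mean and (positive) grand scale.
#' @param delta Cohen's \eqn{\delta}.
#' @param rho Precision proportion in (0, 1).
#' @return A named list `mu1, mu2, sigma1, sigma2`. Vectorized.
#' @examples
#' group_params(0, 1, 1, 0.5)  # means -0.5/+0.5, unit SDs
#' @export
group_params <- function(mu, sigma, delta, rho) {
  if (any(sigma <= 0)) stop_mbt("`sigma` must be positive.")
  if (any(rho <= 0 | rho >= 1)) stop_mbt("`rho` must lie strictly in (0, 1).")
  md <- delta * sigma
  list(mu1 = mu - md / 2, mu2 = mu + md / 2,
       sigma1 = sigma * sqrt(2 * (1 - rho)),
       sigma2 = sigma * sqrt(2 * rho))
}

#' @describeIn group_params Inverse map from per-group parameters back to the
#'   common parametrization.
#' @param mu1,mu2,sigma1,sigma2 Per-group means and (positive) SDs.
#' @export
grand_params <- function(mu1, mu2, sigma1, sigma2) {
  if (any(sigma1 <= 0) || any(sigma2 <= 0)) stop_mbt("group SDs must be positive.")
  sigma <- sqrt((sigma1^2 + sigma2^2) / 2)
  list(mu = (mu1 + mu2) / 2, sigma = sigma,
       delta = (mu2 - mu1) / sigma,
       rho = rho_from_variances(sigma1^2, sigma2^2))
}

#' Scale parameter of the standardized t likelihood
#'
#' The t-likelihood models parametrize each group by its standard deviation
#' \eqn{\sigma_g}, not the raw t scale: the scale is shrunk to
#' \eqn{s_g = \sigma_g\sqrt{(\nu-2)/\nu}} so that a
#' \eqn{t(\nu, \mu_g, s_g)} observable has SD exactly \eqn{\sigma_g}. This
#' keeps Cohen's \eqn{\delta} comparable across \eqn{\nu} and across the
#' normal/t ensemble halves.
#'
#' @param sigma_g Target group standard deviation(s), positive.
#' @param nu Degrees of freedom, must exceed 2 (may be `Inf`).
#' @return The t-density scale `s_g`.
#' @examples
#' t_scale(1, 4)    # sqrt(1/2)
#' t_scale(1, Inf)  # 1, the normal limit
#' @export
t_scale <- function(sigma_g, nu) {
  if (any(sigma_g <= 0)) stop_mbt("`sigma_g` must be positive.")
  if (any(nu <= 2)) stop_mbt("`nu` must exceed 2 for the SD to exist.")
  ifelse(is.infinite(nu), sigma_g, sigma_g * sqrt((nu - 2) / nu))
}

# log density of the truncated Cauchy prior on delta
log_dprior_delta <- function(delta, priors) {
  d <- stats::dcauchy(delta, priors$delta_location, priors$delta_scale, log = TRUE)
  tr <- priors$delta_truncation
  if (!is.null(tr)) {
    mass <- stats::pcauchy(tr[2], priors$delta_location, priors$delta_scale) -
      stats::pcauchy(tr[1], priors$delta_location, priors$delta_scale)
    d <- ifelse(delta >= tr[1] & delta <= tr[2], d - log(mass), -Inf)
  }
  d
}

log_dprior_rho <- function(rho, priors) {
  stats::dbeta(rho, priors$rho_shape[1], priors$rho_shape[2], log = TRUE)
}

log_dprior_nu <- function(nu, priors) {
  ifelse(is.infinite(nu), -Inf,
         stats::dexp(nu - priors$nu_shift, 1 / priors$nu_scale, log = TRUE))
}

#' Joint log prior density of the free parameters of a model
#'
#' Sums the log prior densities of exactly the parameters a model leaves
#' free: the Cauchy prior on \eqn{\delta} (alternative models), the Beta
#' prior on \eqn{\rho} (unequal-variance models), the shifted-exponential
#' prior on \eqn{\nu} (t-likelihood models), and the improper Jeffreys factor
#' \eqn{-\log\sigma} shared by all models.
#'
#' @param theta Named list/vector with elements `mu`, `sigma`, `delta`,
#'   `rho`, `nu`. Constrained members must match the model: `delta = 0` under
#'   a null model, `rho = 0.5` under equal variances, `nu = Inf` under the
#'   normal likelihood.
#' @param priors An [prior_settings()] object.
#' @param spec A [model_spec()].
#' @return The joint log prior density (improper in \eqn{\mu,\sigma}).
#' @export
log_prior <- function(theta, priors, spec) {
  theta <- as.list(theta)
  if (theta$sigma <= 0) stop_mbt("`sigma` must be positive.")
  if (spec$effect == "null" && theta$delta != 0) {
    stop_mbt("null model requires delta = 0.")
  }
  if (spec$variances == "equal" && theta$rho != 0.5) {
    stop_mbt("equal-variance model requires rho = 0.5.")
  }
  if (spec$likelihood == "normal" && !is.infinite(theta$nu)) {
    stop_mbt("normal-likelihood model requires nu = Inf.")
  }
  lp <- -log(theta$sigma)
  if (spec$effect == "alternative") lp <- lp + log_dprior_delta(theta$delta, priors)
  if (spec$variances == "unequal") lp <- lp + log_dprior_rho(theta$rho, priors)
  if (spec$likelihood == "t") lp <- lp + log_dprior_nu(theta$nu, priors)
  lp
}

#' Prior mass on an interval of standard-deviation ratios
#'
#' Probability that the SD ratio falls in `[lo, hi]` under the Beta prior on
#' \eqn{\rho}, computed exactly through the regularized incomplete beta
#' function on the \eqn{\rho}-interval implied by the SDR bounds. With the
#' default Beta(1.5, 1.5) prior about 90% of the mass lies between 1/3 and 3.
#'
#' @param lo,hi SDR bounds, `0 <= lo < hi <= Inf`.
#' @param priors An [prior_settings()] object (only `rho_shape` is used).
#' @return The prior probability.
#' @examples
#' prior_mass_sdr_interval(1 / 3, 3)  # ~0.90
#' @export
prior_mass_sdr_interval <- function(lo, hi, priors = prior_settings()) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi <= lo) {
    stop_mbt("need 0 <= lo < hi.")
  }
  a <- priors$rho_shape[1]; b <- priors$rho_shape[2]
  # sdr = sqrt((1-rho)/rho) is decreasing in rho
  rho_hi <- if (lo == 0) 1 else 1 / (1 + lo^2)
  rho_lo <- if (is.infinite(hi)) 0 else 1 / (1 + hi^2)
  stats::pbeta(rho_hi, a, b) - stats::pbeta(rho_lo, a, b)
}

#' Summary of the degrees-of-freedom prior
#'
#' For the shifted exponential prior \eqn{\nu \sim shift + Exp(1/scale)} the
#' mean is `shift + scale` and the quartiles are
#' `shift - scale * log(0.75/0.5/0.25)`; the default prior has mean 3 and
#' interquartile range from about 2.3 to 3.4.
#'
#' @param priors An [prior_settings()] object.
#' @return A tibble with columns `mean`, `q1`, `median`, `q3`.
#' @export
nu_prior_summary <- function(priors = prior_settings()) {
  s <- priors$nu_shift; sc <- priors$nu_scale
  tibble::tibble(mean = s + sc,
                 q1 = s - sc * log(0.75),
                 median = s - sc * log(0.5),
                 q3 = s - sc * log(0.25))
}
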