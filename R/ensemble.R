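#' Posterior model probabilities from log marginal likelihoods
#'
#' Softmax of `log_ml + log(prior_prob)` computed through log-sum-exp, so it
#' stays stable for log marginal likelihoods of magnitude up to about 1e3.
#'
#' @param log_mls Numeric vector of log marginal likelihoods.
#' @param prior_probs Prior model probabilities (same length, nonnegative,
#'   summing to one up to roundoff).
#' @return Posterior probabilities summing to one.
#' @examples
#' posterior_model_probs(log(c(37.2, 1)), c(0.5, 0.5))  # ~0.974 for model 1
#' @export
posterior_model_probs <- function(log_mls, prior_probs) {
  if (length(log_mls) != length(prior_probs)) {
    stop_mbt("`log_mls` and `prior_probs` must have equal length.")
  }
  if (any(prior_probs < 0) || sum(prior_probs) <= 0) {
    stop_mbt("`prior_probs` must be a nonnegative probability vector.")
  }
  lw <- log_mls + log(prior_probs / sum(prior_probs))
  exp(lw - log_sum_exp(lw))
}

#' Inclusion Bayes factor for a set of models
#'
#' The change from prior to posterior odds of the indicated model set:
#' `[sum(post in)/sum(post out)] / [sum(prior in)/sum(prior out)]`. With two
#' models and the indicator selecting one of them this reduces to the
#' pairwise Bayes factor.
#'
#' @param model_probs Posterior model probabilities.
#' @param prior_probs Prior model probabilities.
#' @param indicator Logical vector (or index vector) selecting the model set;
#'   must be neither empty nor all models.
#' @return The inclusion Bayes factor (possibly `Inf` with a warning when the
#'   excluded set has zero posterior mass).
#' @examples
#' inclusion_bf(c(0.4, 0.4, 0.1, 0.1), rep(0.25, 4), c(TRUE, TRUE, FALSE, FALSE))
#' @export
inclusion_bf <- function(model_probs, prior_probs, indicator) {
  if (!is.logical(indicator)) {
    indicator <- seq_along(model_probs) %in% indicator
  }
  if (!any(indicator) || all(indicator)) {
    stop_mbt("`indicator` must select a proper, non-empty subset of models.")
  }
  post_in <- sum(model_probs[indicator]); post_out <- sum(model_probs[!indicator])
  pri_in <- sum(prior_probs[indicator]); pri_out <- sum(prior_probs[!indicator])
  if (pri_in <= 0 || pri_out <= 0) {
    stop_mbt("both model sets need positive prior probability.")
  }
  if (post_out == 0) {
    warning("excluded set has zero posterior mass; inclusion BF is +Inf.",
            call. = FALSE)
    return(Inf)
  }
  (post_in / post_out) / (pri_in / pri_out)
}

# stable inclusion BF from log marginal likelihoods (avoids 0/0 when one
# side dominates), with a propagated Monte-Carlo SE on the log BF
inclusion_bf_log <- function(log_mls, ses, prior_probs, indicator) {
  lw <- log_mls + log(prior_probs / sum(prior_probs))
  l_in <- log_sum_exp(lw[indicator]) - log(sum(prior_probs[indicator]))
  l_out <- log_sum_exp(lw[!indicator]) - log(sum(prior_probs[!indicator]))
  # weights of each model within its own averaged marginal likelihood
  w_in <- exp(lw[indicator] - log_sum_exp(lw[indicator]))
  w_out <- exp(lw[!indicator] - log_sum_exp(lw[!indicator]))
  se <- sqrt(sum((w_in * ses[indicator])^2) + sum((w_out * ses[!indicator])^2))
  list(bf = exp(l_in - l_out), log_bf = l_in - l_out, log_bf_se = se)
}

# draw pool of one parameter for one fit, generating quadrature-path draws
# on demand; constants for spec-fixed parameters
param_pool <- function(fit, parameter, n_pool, seed) {
  spec <- fit$spec
  fixed <- switch(parameter,
    delta = if (spec$effect == "null") 0,
    rho = if (spec$variances == "equal") 0.5,
    nu = if (spec$likelihood == "normal") Inf,
    stop_mbt(sprintf("unknown parameter '%s'.", parameter)))
  if (!is.null(fixed)) return(fixed)
  if (is.null(fit$draws)) {
    fit$draws <- sample_posterior_normal(fit, n_pool, seed = seed)
  }
  fit$draws[[parameter]]
}

#' Model-averaged posterior draws and summary for one parameter
#'
#' Implements mixture sampling over the ensemble: first a model is sampled in
#' proportion to the posterior model probabilities, then a parameter value is
#' drawn from that model's posterior (or its spec-implied constant:
#' \eqn{\delta = 0} under null models, \eqn{\rho = 0.5} under equal
#' variances, \eqn{\nu = \infty} under the normal likelihood). The
#' conditional variant instead restricts to the models in which the parameter
#' is free and renormalizes their weights.
#'
#' @param fits List of `model_fit` objects.
#' @param model_probs Posterior model probabilities (same order).
#' @param parameter One of `"delta"`, `"rho"`, `"sdr"`, `"nu"` (`"sdr"` is
#'   the SD-ratio transform of the \eqn{\rho} draws).
#' @param n_draws Number of mixture draws (warned below 1000).
#' @param seed Integer seed.
#' @param conditional Restrict to models where the parameter is free?
#' @param sdr_convention Which SD ratio to report; see [prior_settings()].
#' @return A list with `draws` (numeric vector, possibly containing `Inf`
#'   for \eqn{\nu}) and `summary`, a one-row tibble with the posterior mean
#'   (median for \eqn{\nu}) and central 95% credible interval.
#' @export
model_averaged_posterior <- function(fits, model_probs, parameter,
                                     n_draws = 1e5, seed = NULL,
                                     conditional = FALSE,
                                     sdr_convention = "group1/group2") {
  if (n_draws < 1000) {
    warning("fewer than 1000 mixture draws; summaries will be noisy.",
            call. = FALSE)
  }
  base_param <- if (parameter == "sdr") "rho" else parameter
  free <- vapply(fits, function(f) {
    switch(base_param,
           delta = f$spec$effect == "alternative",
           rho = f$spec$variances == "unequal",
           nu = f$spec$likelihood == "t")
  }, logical(1))
  if (conditional) {
    if (!any(free & model_probs > 0)) {
      stop_mbt(sprintf(
        "no posterior mass on models where '%s' is free; conditional summary undefined.",
        parameter))
    }
    w <- ifelse(free, model_probs, 0)
  } else {
    w <- model_probs
  }
  w <- w / sum(w)
  draws <- with_seed(seed, {
    idx <- sample.int(length(fits), n_draws, replace = TRUE, prob = w)
    out <- numeric(n_draws)
    for (m in unique(idx)) {
      sel <- idx == m
      pool <- param_pool(fits[[m]], base_param, n_pool = 20000L,
                         seed = sub_seed(seed, "pool", m, base_param))
      out[sel] <- if (length(pool) == 1L) pool else
        pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
    out
  })
  if (parameter == "sdr") {
    draws <- sdr_from_rho(pmin(pmax(draws, 1e-12), 1 - 1e-12),
                          convention = sdr_convention)
    draws[abs(draws - 1) < 1e-9] <- 1  # exact at the equal-variance constant
  }
  qs <- stats::quantile(draws, c(0.025, 0.5, 0.975), type = 1, names = FALSE)
  summary <- tibble::tibble(
    parameter = parameter,
    type = if (conditional) "conditional" else "averaged",
    mean = if (parameter == "nu") NA_real_ else mean(draws),
    median = qs[2], lower = qs[1], upper = qs[3]
  )
  list(draws = draws, summary = summary)
}

#' Fit a model ensemble to two-group data
#'
#' The top-level engine: fits every member of the chosen ensemble
#' (normal-likelihood members by closed-form-nuisance quadrature from the
#' summary statistics, t-likelihood members by MCMC plus bridge estimation
#' from the raw data), combines the marginal likelihoods into posterior
#' model probabilities, and computes the three inclusion Bayes factors --
#' presence of an effect, unequal variances, t likelihood (outliers) --
#' together with model-averaged and conditional posterior summaries of
#' Cohen's \eqn{\delta}, the SD ratio, and the degrees of freedom.
#'
#' @param x A [two_sample_data()], a [two_sample_summary()] (normal-likelihood
#'   ensembles only), or a data frame with `value`/`group` columns.
#' @param priors An [prior_settings()] object; its `model_probs`, when set,
#'   must match the ensemble size (default uniform).
#' @param ensemble `"romb8"` (default), `"mb4"`, `"welch"` or `"student"`.
#' @param settings A [sampler_settings()] for the t-likelihood members.
#' @param seed Integer seed governing all sampling.
#' @param n_mixture_draws Draws used for model-averaged summaries.
#' @return An object of class `mbt_ensemble` with elements `models` (tibble:
#'   one row per model with prior probability, log marginal likelihood, SE
#'   and posterior probability), `incl_bf` (list of effect/variances/outliers
#'   entries), `estimates` (tibble of averaged and conditional parameter
#'   summaries), `fits`, `mixture_draws`, and the call configuration.
#' @examples
#' st <- two_sample_summary(20, 12.35, 12.18, 20, 3.65, 3.94)
#' fit <- fit_ensemble(st, ensemble = "mb4", seed = 1)
#' fit
#' @export
fit_ensemble <- function(x, priors = prior_settings(),
                         ensemble = c("romb8", "mb4", "welch", "student"),
                         settings = sampler_settings(), seed = NULL,
                         n_mixture_draws = 1e5) {
  ensemble <- match.arg(ensemble)
  if (is.data.frame(x) && !inherits(x, "two_sample_summary")) {
    x <- data_from_frame(x, value, group)
  }
  specs <- model_grid(ensemble)
  has_t <- any(indicator_outliers(specs))
  if (inherits(x, "two_sample_summary")) {
    if (has_t) {
      stop_mbt("the romb8 ensemble needs raw data; summary statistics only ",
               "suffice for normal-likelihood ensembles (student/welch/mb4). ",
               "Consider `fixture_from_summary()`.")
    }
    data <- NULL; stats <- x
  } else {
    stopifnot(inherits(x, "two_sample_data"))
    data <- x; stats <- summarize_groups(x)
  }

  prior_probs <- priors$model_probs %||% rep(1 / length(specs), length(specs))
  if (length(prior_probs) != length(specs)) {
    stop_mbt(sprintf("`model_probs` has length %d but ensemble '%s' has %d models.",
                     length(prior_probs), ensemble, length(specs)))
  }

  fits <- purrr::imap(specs, function(spec, label) {
    tryCatch({
      if (spec$likelihood == "normal") {
        logml_normal_model(stats, spec, priors)
      } else {
        logml_t_model(data, spec, priors, settings, seed = seed)
      }
    }, error = function(e) {
      stop_mbt(sprintf("fit of model %s failed: %s", label, conditionMessage(e)))
    })
  })

  log_mls <- purrr::map_dbl(fits, "log_ml")
  ses <- purrr::map_dbl(fits, "log_ml_se")
  post <- posterior_model_probs(log_mls, prior_probs)

  # pre-generate posterior draws for quadrature fits with free parameters so
  # the mixture summaries below draw from cached pools
  for (m in seq_along(fits)) {
    sp <- fits[[m]]$spec
    if (fits[[m]]$method == "quadrature" && is.null(fits[[m]]$draws) &&
        post[m] > 1e-3 &&
        (sp$effect == "alternative" || sp$variances == "unequal")) {
      fits[[m]]$draws <- sample_posterior_normal(
        fits[[m]], n_draws = 8000L, seed = sub_seed(seed, "pool", m))
    }
  }

  models <- tibble::tibble(
    model = names(specs),
    effect = purrr::map_chr(specs, "effect"),
    variances = purrr::map_chr(specs, "variances"),
    likelihood = purrr::map_chr(specs, "likelihood"),
    prior_prob = prior_probs,
    log_ml = log_mls, log_ml_se = ses,
    post_prob = post
  )

  incl <- list(
    effect = inclusion_bf_log(log_mls, ses, prior_probs, indicator_effect(specs))
  )
  if (length(unique(models$variances)) > 1) {
    incl$variances <- inclusion_bf_log(log_mls, ses, prior_probs,
                                       indicator_variances(specs))
  }
  if (length(unique(models$likelihood)) > 1) {
    incl$outliers <- inclusion_bf_log(log_mls, ses, prior_probs,
                                      indicator_outliers(specs))
  }

  params <- c("delta",
              if (length(unique(models$variances)) > 1) "sdr",
              if (length(unique(models$likelihood)) > 1) "nu")
  mixture_draws <- list()
  estimates <- purrr::map_dfr(params, function(p) {
    avg <- model_averaged_posterior(fits, post, p, n_mixture_draws,
                                    seed = sub_seed(seed, "avg", p),
                                    sdr_convention = priors$sdr_convention)
    mixture_draws[[p]] <<- avg$draws
    cond <- tryCatch(
      model_averaged_posterior(fits, post, p, n_mixture_draws,
                               seed = sub_seed(seed, "cond", p),
                               conditional = TRUE,
                               sdr_convention = priors$sdr_convention)$summary,
      error = function(e) NULL)
    dplyr::bind_rows(avg$summary, cond)
  })

  structure(list(ensemble = ensemble, models = models, incl_bf = incl,
                 estimates = estimates, fits = fits,
                 mixture_draws = mixture_draws,
                 stats = stats, priors = priors, settings = settings,
                 seed = seed, n1 = stats$n[1], n2 = stats$n[2]),
            class = "mbt_ensemble")
}

#' Model-averaged Bayesian t test on a tidy data frame
#'
#' Data-frame-first front end to [fit_ensemble()]: give it a data frame, the
#' value column and the group column, and it validates the two groups and
#' runs the chosen ensemble.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval) holding observations and group
#'   labels; default `value` and `group`.
#' @param ... Passed on to [fit_ensemble()] (`priors`, `ensemble`,
#'   `settings`, `seed`, ...).
#' @return An `mbt_ensemble` object.
#' @examples
#' df <- tibble::tibble(value = c(rnorm(10), rnorm(10, 1)),
#'                      group = rep(c("ctrl", "trt"), each = 10))
#' mbt_test(df, ensemble = "student")
#' @export
mbt_test <- function(data, value = value, group = group, ...) {
  fit_ensemble(data_from_frame(data, {{ value }}, {{ group }}), ...)
}
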