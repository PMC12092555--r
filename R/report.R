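#' Verbal evidence label for a Bayes factor
#'
#' The conventional rule of thumb: BF between 1 and 3 is weak evidence,
#' between 3 and 10 moderate, above 10 strong; values below 1 are inverted
#' and labelled as evidence for the complementary hypothesis. Class
#' boundaries are closed upwards (a BF of exactly 3 counts as moderate) and
#' a BF of exactly 1 is labelled equivocal.
#'
#' @param bf Positive Bayes factor(s).
#' @param h1 Label of the favoured hypothesis when `bf > 1`.
#' @param h0 Label of the favoured hypothesis when `bf < 1`.
#' @return Character vector of labels.
#' @examples
#' evidence_label(c(5, 37.2, 1, 0.02))
#' @export
evidence_label <- function(bf, h1 = "H1", h0 = "H0") {
  if (any(bf <= 0, na.rm = TRUE)) stop_mbt("Bayes factors must be positive.")
  vapply(bf, function(b) {
    if (is.na(b)) return(NA_character_)
    if (b == 1) return("no evidence / equivocal")
    target <- if (b > 1) h1 else h0
    b <- max(b, 1 / b)
    strength <- if (b >= 10) "strong" else if (b >= 3) "moderate" else "weak"
    sprintf("%s evidence for %s", strength, target)
  }, character(1))
}

#' Format a Bayes factor for reporting
#'
#' One decimal place above 10, three significant digits otherwise.
#'
#' @param bf Positive Bayes factor(s).
#' @return Character vector.
#' @export
format_bf <- function(bf) {
  vapply(bf, function(b) {
    if (is.na(b)) return("NA")
    if (is.infinite(b)) return("Inf")
    if (b >= 10) sprintf("%.1f", b) else format(signif(b, 3))
  }, character(1))
}

#' @export
print.mbt_ensemble <- function(x, digits = 3, ...) {
  cat(sprintf("Model-averaged Bayesian t test (%s ensemble, %d models)\n",
              x$ensemble, nrow(x$models)))
  cat(sprintf("  groups: %s (n = %d) vs %s (n = %d)\n\n",
              x$stats$group[1], x$n1, x$stats$group[2], x$n2))
  cat("Inclusion Bayes factors\n")
  lab <- c(effect = "BF10   (difference in means)",
           variances = "BFrr   (unequal variances)  ",
           outliers = "BFtn   (outliers/t-likelihood)")
  for (nm in names(x$incl_bf)) {
    b <- x$incl_bf[[nm]]$bf
    cat(sprintf("  %s = %-9s %s\n", lab[[nm]], format_bf(b),
                paste0("[", evidence_label(b), "]")))
  }
  cat("\nPosterior model probabilities\n")
  m <- x$models
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-13s p = %.3f   (log ML %8.3f%s)\n", m$model[i],
                m$post_prob[i], m$log_ml[i],
                if (m$log_ml_se[i] > 0) sprintf(" ± %.3f", m$log_ml_se[i]) else ""))
  }
  if (nrow(x$estimates)) {
    cat("\nParameter estimates (central 95% CI)\n")
    e <- x$estimates
    for (i in seq_len(nrow(e))) {
      loc <- if (e$parameter[i] == "nu") e$median[i] else e$mean[i]
      cat(sprintf("  %-5s %-12s %s, 95%% CI [%s, %s]\n",
                  e$parameter[i], paste0("(", e$type[i], ")"),
                  format(signif(loc, digits)),
                  format(signif(e$lower[i], digits)),
                  format(signif(e$upper[i], digits))))
    }
  }
  invisible(x)
}

#' Tidy an ensemble fit
#'
#' @param x An `mbt_ensemble`.
#' @param type `"models"` (one row per ensemble member) or `"estimates"`
#'   (parameter summaries).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mbt_ensemble <- function(x, type = c("models", "estimates"), ...) {
  switch(match.arg(type), models = x$models, estimates = x$estimates)
}

#' One-row summary of an ensemble fit
#'
#' @param x An `mbt_ensemble`.
#' @param ... Unused.
#' @return A tibble with the three inclusion Bayes factors and sample sizes.
#' @export
glance.mbt_ensemble <- function(x, ...) {
  tibble::tibble(
    ensemble = x$ensemble,
    n1 = x$n1, n2 = x$n2,
    bf_effect = x$incl_bf$effect$bf,
    bf_variances = x$incl_bf$variances$bf %||% NA_real_,
    bf_outliers = x$incl_bf$outliers$bf %||% NA_real_,
    n_models = nrow(x$models)
  )
}

#' Plot posterior model probabilities of an ensemble fit
#'
#' @param object An `mbt_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mbt_ensemble <- function(object, ...) {
  m <- object$models
  m$model <- factor(m$model, levels = m$model)
  df <- tidyr::pivot_longer(m[, c("model", "prior_prob", "post_prob")],
                            c("prior_prob", "post_prob"),
                            names_to = "which", values_to = "probability")
  df$which <- factor(df$which, c("prior_prob", "post_prob"),
                     c("prior", "posterior"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$probability,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "model probability", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Posterior density plot of a model-averaged parameter
#'
#' @param x An `mbt_ensemble`.
#' @param parameter `"delta"`, `"sdr"` or `"nu"`.
#' @return A ggplot (finite draws only; any point mass at `Inf` is noted in
#'   the subtitle).
#' @export
plot_averaged_posterior <- function(x, parameter = "delta") {
  stopifnot(inherits(x, "mbt_ensemble"))
  draws <- x$mixture_draws[[parameter]]
  if (is.null(draws)) stop_mbt(sprintf("no mixture draws for '%s'.", parameter))
  p_inf <- mean(is.infinite(draws))
  df <- tibble::tibble(value = draws[is.finite(draws)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::labs(
      x = parameter, y = "model-averaged posterior density",
      subtitle = if (p_inf > 0)
        sprintf("point mass of %.2f at infinity (normal-likelihood models)", p_inf)
    ) +
    ggplot2::theme_minimal()
}

#' Export an ensemble fit as a JSON report
#'
#' Per-model entries (spec, log marginal likelihood, SE, posterior
#' probability), the inclusion Bayes factors, parameter summaries and the
#' configuration (ensemble, priors, seed) needed to regenerate the fit.
#'
#' @param x An `mbt_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_json <- function(x, path) {
  stopifnot(inherits(x, "mbt_ensemble"))
  out <- list(
    ensemble = x$ensemble,
    seed = x$seed,
    groups = list(labels = as.character(x$stats$group),
                  n = as.integer(x$stats$n)),
    models = x$models,
    inclusion_bf = purrr::map(x$incl_bf, function(b) {
      list(bf = b$bf, log_bf = b$log_bf, log_bf_se = b$log_bf_se,
           label = evidence_label(b$bf))
    }),
    estimates = x$estimates,
    priors = list(delta = list(family = "cauchy",
                               location = x$priors$delta_location,
                               scale = x$priors$delta_scale),
                  rho = list(a = x$priors$rho_shape[1], b = x$priors$rho_shape[2]),
                  nu = list(shift = x$priors$nu_shift, scale = x$priors$nu_scale))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' Student vs. Welch evidence over a grid of mean differences and SD ratios
#'
#' Builds summary statistics on a fixed template (group sizes `n1`, `n2`,
#' grand mean 0, grand standard deviation 1) for every combination of
#' observed mean difference and SD ratio, and computes the equal-variance
#' (Student) and unequal-variance (Welch) Bayes factors for an effect plus
#' their log ratio. Group means are \eqn{\mu \mp MD/2}; group SDs follow the
#' variance-average construction \eqn{\sigma_1^2 + \sigma_2^2 = 2\sigma^2}
#' with \eqn{SDR = \sigma_1/\sigma_2}.
#'
#' @param n1,n2 Template group sizes.
#' @param md Numeric vector of observed mean differences
#'   (\eqn{MD = \bar y_2 - \bar y_1}).
#' @param sdr Numeric vector of observed SD ratios (\eqn{s_1/s_2}).
#' @param priors An [prior_settings()] object.
#' @return A tibble with columns `md`, `sdr`, `bf_student`, `bf_welch`,
#'   `log_ratio` (`log(bf_welch) - log(bf_student)`).
#' @export
explore_grid <- function(n1, n2, md, sdr, priors = prior_settings()) {
  if (!length(md) || !length(sdr)) stop_mbt("empty grid.")
  grid <- tidyr::expand_grid(md = md, sdr = sdr)
  specs <- list(s1 = model_spec("alternative", "equal", "normal"),
                s0 = model_spec("null", "equal", "normal"),
                w1 = model_spec("alternative", "unequal", "normal"),
                w0 = model_spec("null", "unequal", "normal"))
  res <- purrr::pmap_dfr(grid, function(md, sdr) {
    s2 <- sqrt(2 / (1 + sdr^2))
    st <- two_sample_summary(n1, -md / 2, sdr * s2, n2, md / 2, s2)
    lm <- purrr::map_dbl(specs, ~ logml_normal_model(st, .x, priors)$log_ml)
    tibble::tibble(md = md, sdr = sdr,
                   bf_student = exp(lm[["s1"]] - lm[["s0"]]),
                   bf_welch = exp(lm[["w1"]] - lm[["w0"]]))
  })
  res$log_ratio <- log(res$bf_welch) - log(res$bf_student)
  res
}
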