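#' Sequential evidence trajectory over accumulating data
#'
#' Re-fits the ensemble on nested subsets of the data and records the
#' inclusion Bayes factors and posterior model probabilities at each
#' checkpoint. Every checkpoint is a full-data recomputation on the subset
#' observed so far (Bayes factors have no path dependence), so the final
#' checkpoint coincides with a fresh fit on all data.
#'
#' @param data A [two_sample_data()]; observation order within each group is
#'   taken as the accrual order.
#' @param priors,ensemble,settings,seed Passed to [fit_ensemble()].
#' @param schedule `"pairwise"` (one new observation per group per
#'   checkpoint, starting at two per group) or a list of `c(n1, n2)` counts,
#'   strictly increasing in total and each at least 2 per group.
#' @param keep_fits Keep the full `mbt_ensemble` of every checkpoint (can be
#'   large); otherwise only the final one is retained.
#' @return An `mbt_trajectory`: a list with `checkpoints` (a tibble with one
#'   row per checkpoint: `n1`, `n2`, the available inclusion BFs and
#'   per-model posterior probabilities) and `final` (the last ensemble fit).
#' @export
sequential_trajectory <- function(data, priors = prior_settings(),
                                  ensemble = "mb4",
                                  schedule = "pairwise",
                                  settings = sampler_settings(),
                                  seed = NULL, keep_fits = FALSE) {
  stopifnot(inherits(data, "two_sample_data"))
  n1 <- length(data$group1); n2 <- length(data$group2)
  counts <- if (identical(schedule, "pairwise")) {
    lapply(2:max(n1, n2), function(j) c(min(j, n1), min(j, n2)))
  } else {
    schedule
  }
  counts <- lapply(counts, as.integer)
  tot <- vapply(counts, sum, integer(1))
  if (any(diff(tot) <= 0)) stop_mbt("checkpoints must be strictly increasing in total n.")
  first <- counts[[1]]
  if (first[1] < 2 || first[2] < 2) {
    stop_mbt("the first checkpoint needs at least 2 observations per group.")
  }
  if (any(vapply(counts, function(cc) cc[1] > n1 || cc[2] > n2, logical(1)))) {
    stop_mbt("schedule exceeds the available observations.")
  }

  fits <- vector("list", length(counts))
  rows <- purrr::imap_dfr(counts, function(cc, i) {
    sub <- two_sample_data(data$group1[seq_len(cc[1])],
                           data$group2[seq_len(cc[2])], labels = data$labels)
    fit <- fit_ensemble(sub, priors = priors, ensemble = ensemble,
                        settings = settings,
                        seed = sub_seed(seed, "seq", i),
                        n_mixture_draws = 1000)
    if (keep_fits || i == length(counts)) fits[[i]] <<- fit
    probs <- stats::setNames(as.list(fit$models$post_prob),
                             paste0("p_", fit$models$model))
    tibble::as_tibble(c(list(checkpoint = i, n1 = cc[1], n2 = cc[2],
                             bf_effect = fit$incl_bf$effect$bf,
                             bf_variances = fit$incl_bf$variances$bf %||% NA_real_,
                             bf_outliers = fit$incl_bf$outliers$bf %||% NA_real_),
                        probs))
  })
  structure(list(checkpoints = rows, final = fits[[length(counts)]],
                 fits = if (keep_fits) fits, ensemble = ensemble, seed = seed),
            class = "mbt_trajectory")
}

#' @export
print.mbt_trajectory <- function(x, ...) {
  k <- nrow(x$checkpoints)
  last <- x$checkpoints[k, ]
  cat(sprintf("<mbt_trajectory> %d checkpoints (%s ensemble); final n = %d + %d, BF10 = %s\n",
              k, x$ensemble, last$n1, last$n2, format_bf(last$bf_effect)))
  invisible(x)
}

#' Plot a sequential evidence trajectory
#'
#' @param object An `mbt_trajectory`.
#' @param ... Unused.
#' @return A ggplot of the inclusion Bayes factors (log scale) over total
#'   sample size.
#' @export
autoplot.mbt_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$checkpoints[, c("n1", "n2", "bf_effect", "bf_variances", "bf_outliers")],
    dplyr::starts_with("bf_"), names_to = "quantity", values_to = "bf")
  df <- df[!is.na(df$bf), ]
  df$n <- df$n1 + df$n2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$bf,
                                   colour = .data$quantity)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "total sample size", y = "inclusion Bayes factor",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write a trajectory to long-format CSV
#'
#' @param traj An `mbt_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "mbt_trajectory"))
  utils::write.csv(traj$checkpoints, path, row.names = FALSE)
  invisible(path)
}

#' Replication Bayes factor by evidence updating
#'
#' The evidence the replication data add on top of the original study:
#' the Bayes factor of the combined data divided by the Bayes factor of the
#' original data. This quotient identity equals the Bayes factor computed
#' with the original study's posterior (including its posterior model
#' probabilities) as the replication's prior.
#'
#' @param bf_combined Bayes factor from analyzing both data sets together.
#' @param bf_original Bayes factor from the original data alone.
#' @return The replication Bayes factor.
#' @examples
#' replication_bf(1135.2, 51.2)  # 22.2
#' @export
replication_bf <- function(bf_combined, bf_original) {
  if (any(bf_combined <= 0) || any(bf_original <= 0)) {
    stop_mbt("Bayes factors must be positive.")
  }
  bf_combined / bf_original
}

#' Replication analysis for a two-group design
#'
#' Fits the ensemble to the original data and to the pooled data (original
#' plus replication) and returns the replication Bayes factors for the
#' effect, unequal variances, and outliers as quotients of the pooled and
#' original inclusion Bayes factors, together with the pooled-data ensemble
#' fit (whose model-averaged estimates describe the combined evidence).
#'
#' @param original,replication [two_sample_data()] objects with groups in
#'   the same order.
#' @param priors,ensemble,settings,seed Passed to [fit_ensemble()].
#' @return A list with `bf_rep` (tibble: quantity, bf_original, bf_combined,
#'   bf_rep), `fit_original` and `fit_combined`.
#' @export
replication_analysis <- function(original, replication,
                                 priors = prior_settings(),
                                 ensemble = "romb8",
                                 settings = sampler_settings(), seed = NULL) {
  stopifnot(inherits(original, "two_sample_data"),
            inherits(replication, "two_sample_data"))
  pooled <- two_sample_data(c(original$group1, replication$group1),
                            c(original$group2, replication$group2),
                            labels = original$labels)
  fit_o <- fit_ensemble(original, priors = priors, ensemble = ensemble,
                        settings = settings, seed = sub_seed(seed, "orig"))
  fit_c <- fit_ensemble(pooled, priors = priors, ensemble = ensemble,
                        settings = settings, seed = sub_seed(seed, "comb"))
  quantities <- names(fit_o$incl_bf)
  bf_rep <- purrr::map_dfr(quantities, function(q) {
    tibble::tibble(quantity = q,
                   bf_original = fit_o$incl_bf[[q]]$bf,
                   bf_combined = fit_c$incl_bf[[q]]$bf,
                   bf_rep = replication_bf(fit_c$incl_bf[[q]]$bf,
                                           fit_o$incl_bf[[q]]$bf))
  })
  list(bf_rep = bf_rep, fit_original = fit_o, fit_combined = fit_c)
}
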