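#' Define a simulation condition
#'
#' One cell of the factorial simulation design: population effect size
#' (Cohen's \eqn{\delta}), SD ratio, likelihood shape (normal, i.e.
#' \eqn{\nu = \infty}, or Student-t with \eqn{\nu} degrees of freedom),
#' total sample size and allocation ratio. The grand mean is 0 and the
#' grand SD 1 throughout. The full factorial of the study design crosses
#' \eqn{\delta \in \{0, 0.3, 0.5\}}, \eqn{SDR \in \{1, 1.5, 2\}},
#' \eqn{\nu \in \{\infty, 10, 5\}}, total n in \{20, 50, 100\} and
#' allocation \eqn{n_1{:}n_2 \in \{1/2, 1, 2\}}.
#'
#' @param delta Population standardized mean difference.
#' @param sdr Population SD ratio \eqn{\sigma_1/\sigma_2}.
#' @param nu Degrees of freedom of the generating t distribution; `Inf` for
#'   normal data.
#' @param total_n Total sample size across groups.
#' @param allocation Allocation ratio \eqn{n_1:n_2}; group sizes are
#'   `n2 = round(total_n/(1+allocation))`, `n1 = total_n - n2`.
#' @param reps Number of replicate data sets.
#' @return A one-row tibble of class `mbt_condition` (with derived `n1`,
#'   `n2` and a condition id).
#' @examples
#' sim_condition(delta = 0.5, sdr = 2, nu = 5, total_n = 50, allocation = 2)
#' @export
sim_condition <- function(delta = 0, sdr = 1, nu = Inf, total_n = 20,
                          allocation = 1, reps = 1L) {
  assert_scalar_num(sdr, "sdr", 0, strict = TRUE)
  if (!is.infinite(nu)) assert_scalar_num(nu, "nu", 2, strict = TRUE)
  n2 <- round(total_n / (1 + allocation))
  n1 <- total_n - n2
  if (n1 < 2 || n2 < 2) {
    stop_mbt(sprintf("allocation %g of total %d gives group sizes %d/%d (< 2).",
                     allocation, total_n, n1, n2))
  }
  out <- tibble::tibble(
    condition = sprintf("d%g_sdr%g_nu%s_N%d_r%g", delta, sdr,
                        ifelse(is.infinite(nu), "Inf", format(nu)),
                        total_n, allocation),
    delta = delta, sdr = sdr, nu = nu,
    total_n = as.integer(total_n), allocation = allocation,
    n1 = as.integer(n1), n2 = as.integer(n2), reps = as.integer(reps)
  )
  class(out) <- c("mbt_condition", class(out))
  out
}

#' The full factorial condition grid of the simulation study
#'
#' @param reps Replicates per condition.
#' @return A tibble of 243 conditions (rows).
#' @export
full_condition_grid <- function(reps = 1000L) {
  g <- tidyr::expand_grid(delta = c(0, 0.3, 0.5), sdr = c(1, 1.5, 2),
                          nu = c(Inf, 10, 5), total_n = c(20L, 50L, 100L),
                          allocation = c(1 / 2, 1, 2))
  dplyr::bind_rows(purrr::pmap(g, sim_condition, reps = reps))
}

#' Simulate one two-group data set under a condition
#'
#' Group SDs follow the variance-average construction
#' (\eqn{\sigma_1^2 + \sigma_2^2 = 2} with \eqn{\sigma_1/\sigma_2 = SDR});
#' group means are \eqn{\mp\delta/2}. Normal conditions draw from
#' \eqn{N(\mu_g, \sigma_g)}; t conditions draw t(\eqn{\nu}) variates scaled
#' by \eqn{\sigma_g\sqrt{(\nu-2)/\nu}} so the population SD equals
#' \eqn{\sigma_g} exactly, keeping Cohen's \eqn{\delta} comparable across
#' \eqn{\nu} (set `raw_t_scale = TRUE` to skip the standardization and use
#' the raw t scale instead).
#'
#' @param cond A [sim_condition()] row.
#' @param rep_index Replicate number; together with `seed` it fully
#'   determines the data.
#' @param seed Base seed of the study.
#' @param raw_t_scale Use \eqn{\sigma_g} as the raw t scale parameter
#'   (population SD then exceeds \eqn{\sigma_g}).
#' @return A [two_sample_data()] object.
#' @export
simulate_condition <- function(cond, rep_index = 1L, seed = NULL,
                               raw_t_scale = FALSE) {
  stopifnot(inherits(cond, "mbt_condition"), nrow(cond) == 1L)
  s2 <- sqrt(2 / (1 + cond$sdr^2))
  s1 <- cond$sdr * s2
  mu <- c(-cond$delta / 2, cond$delta / 2)
  with_seed(sub_seed(seed, "sim", cond$condition, rep_index), {
    draw <- function(n, m, s) {
      if (is.infinite(cond$nu)) {
        stats::rnorm(n, m, s)
      } else {
        scale <- if (raw_t_scale) s else s * sqrt((cond$nu - 2) / cond$nu)
        m + scale * stats::rt(n, cond$nu)
      }
    }
    two_sample_data(draw(cond$n1, mu[1], s1), draw(cond$n2, mu[2], s2))
  })
}

#' Evidence distortion factor
#'
#' The ratio of the Bayes factor produced by a candidate test to the Bayes
#' factor of the test matching the data-generating model; 1 means no
#' distortion.
#'
#' @param bf_numerator Candidate-test Bayes factor.
#' @param bf_reference Reference (matching-test) Bayes factor.
#' @return The ratio.
#' @examples
#' edf(67.4, 37.2)
#' @export
edf <- function(bf_numerator, bf_reference) {
  if (any(bf_numerator <= 0) || any(bf_reference <= 0)) {
    stop_mbt("Bayes factors must be positive.")
  }
  bf_numerator / bf_reference
}

# reference test for a condition: the test matching the generating model
reference_method <- function(cond) {
  if (is.infinite(cond$nu)) {
    if (cond$sdr == 1) "student" else "welch"
  } else {
    "robust_ref"
  }
}

# BF10 of a single-model pair (alternative vs null), normal path
pair_bf_normal <- function(stats, variances, priors) {
  f1 <- logml_normal_model(stats, model_spec("alternative", variances, "normal"), priors)
  f0 <- logml_normal_model(stats, model_spec("null", variances, "normal"), priors)
  bayes_factor(f1, f0)$bf
}

# BF10 of the matching t-likelihood single-model pair
pair_bf_t <- function(data, variances, priors, settings, seed) {
  f1 <- logml_t_model(data, model_spec("alternative", variances, "t"),
                      priors, settings, seed = sub_seed(seed, "ref1"))
  f0 <- logml_t_model(data, model_spec("null", variances, "t"),
                      priors, settings, seed = sub_seed(seed, "ref0"))
  bayes_factor(f1, f0)$bf
}

# inclusion BF10 of a model-averaged ensemble, computed from per-model fits
incl_bf10 <- function(log_mls, specs) {
  k <- length(log_mls)
  inclusion_bf_log(log_mls, rep(0, k), rep(1 / k, k), indicator_effect(specs))$bf
}

#' Run the evidence-distortion simulation study
#'
#' For every condition and replicate, simulates a data set, computes the
#' Bayes factor for a difference in means under each requested method
#' (`student`, `welch`: single-model pairs; `mb4`, `romb8`: inclusion Bayes
#' factors), computes the condition's reference Bayes factor from the test
#' matching the generating model (Student for normal/equal-SD data, Welch
#' for normal/unequal-SD data, the matching t-likelihood pair otherwise),
#' and records evidence distortion factors. Per-replicate seeds are derived
#' from `seed`, so results do not depend on evaluation order.
#'
#' @param grid A tibble of conditions ([sim_condition()] rows, e.g. from
#'   [full_condition_grid()]).
#' @param methods Character subset of
#'   `c("student", "welch", "mb4", "romb8")`.
#' @param seed Base seed.
#' @param priors An [prior_settings()] object.
#' @param settings [sampler_settings()] for t-likelihood fits.
#' @param workers Number of parallel workers (forked; results identical to
#'   the serial run because seeds are per replicate).
#' @return A tibble with one row per condition x replicate x method:
#'   `condition`, `rep`, `method`, `bf10`, `ref_method`, `bf_ref`, `edf`.
#'   Failed replicates carry `NA` with a warning at the end.
#' @export
run_study <- function(grid, methods = c("student", "welch", "mb4"),
                      seed = 1L, priors = prior_settings(),
                      settings = sampler_settings(warmup = 500, samples = 1000,
                                                  max_tries = 3),
                      workers = 1L) {
  methods <- match.arg(methods, c("student", "welch", "mb4", "romb8"),
                       several.ok = TRUE)
  conds <- split(grid, seq_len(nrow(grid)))
  one_rep <- function(cond, r) {
    data <- simulate_condition(cond, r, seed = seed)
    stats <- summarize_groups(data)
    bf <- c()
    if ("student" %in% methods || reference_method(cond) == "student") {
      bf["student"] <- pair_bf_normal(stats, "equal", priors)
    }
    if ("welch" %in% methods || reference_method(cond) == "welch") {
      bf["welch"] <- pair_bf_normal(stats, "unequal", priors)
    }
    if ("mb4" %in% methods) {
      specs <- model_grid("mb4")
      lm <- purrr::map_dbl(specs, ~ logml_normal_model(stats, .x, priors)$log_ml)
      bf["mb4"] <- incl_bf10(lm, specs)
    }
    if ("romb8" %in% methods) {
      fit <- fit_ensemble(data, priors = priors, ensemble = "romb8",
                          settings = settings,
                          seed = sub_seed(seed, "romb8", cond$condition, r),
                          n_mixture_draws = 1000)
      bf["romb8"] <- fit$incl_bf$effect$bf
    }
    ref <- reference_method(cond)
    bf_ref <- if (ref == "robust_ref") {
      pair_bf_t(data, if (cond$sdr == 1) "equal" else "unequal", priors,
                settings, sub_seed(seed, "ref", cond$condition, r))
    } else {
      bf[[ref]]
    }
    tibble::tibble(condition = cond$condition, rep = r,
                   method = intersect(methods, names(bf)),
                   bf10 = unname(bf[intersect(methods, names(bf))]),
                   ref_method = ref, bf_ref = bf_ref,
                   edf = unname(bf[intersect(methods, names(bf))]) / bf_ref)
  }
  run_one <- function(task) {
    tryCatch(one_rep(task$cond, task$r),
             error = function(e) tibble::tibble(
               condition = task$cond$condition, rep = task$r,
               method = methods, bf10 = NA_real_,
               ref_method = reference_method(task$cond), bf_ref = NA_real_,
               edf = NA_real_))
  }
  tasks <- purrr::flatten(purrr::map(conds, function(cond) {
    purrr::map(seq_len(cond$reps), ~ list(cond = cond, r = .x))
  }))
  results <- if (workers > 1L) {
    parallel::mclapply(tasks, run_one, mc.cores = workers)
  } else {
    purrr::map(tasks, run_one)
  }
  out <- dplyr::bind_rows(results)
  n_fail <- sum(is.na(out$bf10))
  if (n_fail > 0) {
    warning(sprintf("%d replicate fits failed and were recorded as NA.", n_fail),
            call. = FALSE)
  }
  out
}

#' Summarize a simulation study on the EDF ratio scale
#'
#' Evidence distortion factors are ratios, so per condition and method the
#' geometric mean and log-scale quantiles are reported.
#'
#' @param records Output of [run_study()].
#' @param probs Quantiles to report.
#' @return A tibble with one row per condition x method.
#' @export
summarize_study <- function(records, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  records |>
    dplyr::filter(is.finite(.data$edf)) |>
    dplyr::group_by(.data$condition, .data$method, .data$ref_method) |>
    dplyr::summarise(
      n = dplyr::n(),
      geo_mean_edf = exp(mean(log(.data$edf))),
      q = list(stats::setNames(
        exp(stats::quantile(log(.data$edf), probs, names = FALSE)),
        paste0("edf_q", probs * 100))),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("q")
}

#' Read / write a condition grid as YAML
#'
#' @param grid A tibble of conditions.
#' @param path File path.
#' @return `read_condition_grid` returns the condition tibble.
#' @export
write_condition_grid <- function(grid, path) {
  rows <- purrr::pmap(grid[, c("delta", "sdr", "nu", "total_n", "allocation", "reps")],
                      function(delta, sdr, nu, total_n, allocation, reps) {
                        list(delta = delta, sdr = sdr,
                             nu = if (is.infinite(nu)) "Inf" else nu,
                             total_n = total_n, allocation = allocation,
                             reps = reps)
                      })
  yaml::write_yaml(list(conditions = rows), path)
  invisible(path)
}

#' @rdname write_condition_grid
#' @export
read_condition_grid <- function(path) {
  x <- yaml::read_yaml(path)
  dplyr::bind_rows(purrr::map(x$conditions, function(r) {
    sim_condition(delta = r$delta, sdr = r$sdr,
                  nu = if (identical(r$nu, "Inf")) Inf else r$nu,
                  total_n = r$total_n, allocation = r$allocation,
                  reps = r$reps %||% 1L)
  }))
}
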