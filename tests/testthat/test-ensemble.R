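test_that("posterior model probabilities reproduce the worked arithmetic", {
  # BF = 37.2 with unit prior odds -> P(H1) = 37.2/38.2
  p <- posterior_model_probs(log(c(37.2, 1)), c(0.5, 0.5))
  expect_equal(p[1], 37.2 / 38.2, tolerance = 1e-12)
  expect_equal(round(p[1], 3), 0.974)
  p2 <- posterior_model_probs(log(c(67.4, 1)), c(0.5, 0.5))
  expect_equal(p2[1], 67.4 / 68.4, tolerance = 1e-12)
  expect_equal(round(p2[1], 2), 0.99)

  # symmetry: identical marginals, uniform prior
  for (k in c(2, 5, 8)) {
    expect_equal(posterior_model_probs(rep(-3.7, k), rep(1 / k, k)),
                 rep(1 / k, k))
  }
  # numerically stable at extreme magnitudes
  p3 <- posterior_model_probs(c(-1000, -995, 990), rep(1 / 3, 3))
  expect_equal(sum(p3), 1, tolerance = 1e-12)
  expect_equal(p3[3], 1)
  expect_error(posterior_model_probs(c(1, 2), c(1)), "length")
})

test_that("inclusion Bayes factors reduce correctly and follow the definition", {
  # two models: the pairwise BF exactly
  post <- posterior_model_probs(log(c(5, 1)), c(0.5, 0.5))
  expect_equal(inclusion_bf(post, c(0.5, 0.5), c(TRUE, FALSE)), 5,
               tolerance = 1e-12)
  # four models, uniform prior, posterior (0.4, 0.4, 0.1, 0.1)
  expect_equal(inclusion_bf(c(0.4, 0.4, 0.1, 0.1), rep(0.25, 4),
                            c(TRUE, TRUE, FALSE, FALSE)), 4)
  expect_error(inclusion_bf(c(0.5, 0.5), c(0.5, 0.5), c(TRUE, TRUE)), "subset")
  expect_error(inclusion_bf(c(0.5, 0.5), c(0.5, 0.5), c(FALSE, FALSE)), "subset")

  # invariance to a common additive shift of all log marginal likelihoods
  lm <- c(-3, -1, -5, -2.2)
  pri <- c(0.1, 0.2, 0.3, 0.4)
  ind <- c(TRUE, FALSE, TRUE, FALSE)
  b1 <- mbttest:::inclusion_bf_log(lm, rep(0, 4), pri, ind)$bf
  b2 <- mbttest:::inclusion_bf_log(lm + 123.4, rep(0, 4), pri, ind)$bf
  expect_equal(b1, b2, tolerance = 1e-12)

  # prior-sensitivity identity: doubling the prior odds of the set doubles
  # its posterior odds but leaves the inclusion BF unchanged
  pri2 <- pri * ifelse(ind, 2, 1); pri2 <- pri2 / sum(pri2)
  post1 <- posterior_model_probs(lm, pri)
  post2 <- posterior_model_probs(lm, pri2)
  odds1 <- sum(post1[ind]) / sum(post1[!ind])
  odds2 <- sum(post2[ind]) / sum(post2[!ind])
  prior_odds_ratio <- (sum(pri2[ind]) / sum(pri2[!ind])) /
    (sum(pri[ind]) / sum(pri[!ind]))
  expect_equal(odds2 / odds1, prior_odds_ratio, tolerance = 1e-12)
  expect_equal(inclusion_bf(post2, pri2, ind), inclusion_bf(post1, pri, ind),
               tolerance = 1e-12)
})

test_that("model-averaged mixtures honor point masses and degenerate cases", {
  st <- two_sample_summary(10, 0.5, 1, 10, 0, 1)
  f1 <- logml_normal_model(st, model_spec("alternative", "equal", "normal"))
  f0 <- logml_normal_model(st, model_spec("null", "equal", "normal"))

  # single-model "ensemble": summaries equal that model's own posterior
  one <- model_averaged_posterior(list(f1), 1, "delta", n_draws = 5e4, seed = 1)
  f1$draws <- mbttest:::sample_posterior_normal(f1, 5e4, seed = 2)
  expect_equal(one$summary$mean, mean(f1$draws$delta), tolerance = 0.02)

  # equal-weight mixture with a null model: point mass of 0.5 at zero
  two <- model_averaged_posterior(list(f1, f0), c(0.5, 0.5), "delta",
                                  n_draws = 5e4, seed = 3)
  expect_equal(mean(two$draws == 0), 0.5, tolerance = 0.02)

  # conditional variant is undefined when all mass sits on constants
  expect_error(model_averaged_posterior(list(f0), 1, "delta", seed = 4,
                                        conditional = TRUE),
               "conditional")
  expect_warning(model_averaged_posterior(list(f1), 1, "delta", n_draws = 500,
                                          seed = 5),
                 "1000")
})

test_that("the nu summary reports an infinite median when normal models dominate", {
  toy <- toy_data()
  f_t <- logml_t_model(toy, model_spec("null", "equal", "t"),
                       settings = test_sampler(), seed = 6)
  f_n <- logml_normal_model(summarize_groups(toy),
                            model_spec("null", "equal", "normal"))
  res <- model_averaged_posterior(list(f_n, f_t), c(0.7, 0.3), "nu",
                                  n_draws = 2e4, seed = 7)
  expect_equal(res$summary$median, Inf)
  expect_true(is.finite(res$summary$lower))  # finite lower CI bound
  expect_equal(res$summary$upper, Inf)
})

test_that("the student ensemble reduces to the pairwise Bayes factor", {
  st <- two_sample_summary(10, 0.5, 1, 10, 0, 1)
  fit <- fit_ensemble(st, ensemble = "student", seed = 1)
  bf_pair <- dense_grid_bf_student(st, n_nodes = 1e5)
  expect_equal(fit$incl_bf$effect$bf, bf_pair, tolerance = 1e-5)
  expect_null(fit$incl_bf$variances)
  expect_equal(sum(fit$models$post_prob), 1, tolerance = 1e-12)
})

test_that("the mb4 ensemble on the replication summaries finds effect and variance evidence", {
  fit <- fit_ensemble(replication_summary(), ensemble = "mb4", seed = 2)
  expect_gt(fit$incl_bf$effect$bf, 10)
  expect_gt(fit$incl_bf$variances$bf, 10)
  expect_equal(sum(fit$models$post_prob), 1, tolerance = 1e-12)
  # grid-oracle cross-check of the effect inclusion BF on a fixture
  d <- fixture_from_summary(replication_summary(), seed = 3)
  specs <- model_grid("mb4")
  lm_o <- vapply(specs, function(sp)
    logml_grid_oracle(d, sp, nodes_per_dim = 60, nodes_nuisance = 60),
    numeric(1))
  bf_o <- mbttest:::inclusion_bf_log(lm_o, rep(0, 4), rep(0.25, 4),
                                     mbttest:::indicator_effect(specs))$bf
  fit_d <- fit_ensemble(summarize_groups(d), ensemble = "mb4", seed = 4)
  expect_equal(fit_d$incl_bf$effect$bf, bf_o, tolerance = 1e-4)
})

test_that("romb8 with prior mass only on normal models reproduces mb4", {
  set.seed(10)
  d <- two_sample_data(rnorm(15, 0.6), rnorm(15))
  pr8 <- prior_settings(model_probs = c(rep(0.25, 4), rep(0, 4)))
  fit8 <- fit_ensemble(d, priors = pr8, ensemble = "romb8",
                       settings = test_sampler(), seed = 5)
  fit4 <- fit_ensemble(d, ensemble = "mb4", seed = 6)
  se <- fit8$incl_bf$effect$log_bf_se
  expect_lt(abs(fit8$incl_bf$effect$log_bf - fit4$incl_bf$effect$log_bf),
            max(3 * se, 1e-6))
  expect_lt(abs(fit8$incl_bf$variances$log_bf - fit4$incl_bf$variances$log_bf),
            max(3 * fit8$incl_bf$variances$log_bf_se, 1e-6))
})

test_that("romb8 under the joint null leaves all three inclusion BFs below one", {
  hits <- 0
  for (s in 1:10) {
    cond <- sim_condition(delta = 0, sdr = 1, nu = Inf, total_n = 200,
                          allocation = 1)
    d <- simulate_condition(cond, rep_index = s, seed = 99)
    fit <- fit_ensemble(d, ensemble = "romb8", settings = test_sampler(),
                        seed = s, n_mixture_draws = 1000)
    if (fit$incl_bf$effect$bf < 1 && fit$incl_bf$variances$bf < 1 &&
        fit$incl_bf$outliers$bf < 1) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 8)
})

test_that("ensemble objects tidy, glance, print and plot", {
  fit <- fit_ensemble(replication_summary(), ensemble = "mb4", seed = 7)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4L)
  es <- tidy(fit, "estimates")
  expect_true(all(c("averaged", "conditional") %in% es$type))
  gl <- glance(fit)
  expect_equal(gl$n1, 20L)
  expect_true(is.na(gl$bf_outliers))
  expect_output(print(fit), "Inclusion Bayes factors")
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  p2 <- plot_averaged_posterior(fit, "sdr")
  expect_s3_class(p2, "ggplot")
  jp <- withr::local_tempfile(fileext = ".json")
  write_ensemble_json(fit, jp)
  x <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(nrow(x$models), 4L)
})

test_that("mbt_test accepts a tidy data frame front door", {
  set.seed(1)
  df <- tibble::tibble(y = c(rnorm(10), rnorm(10, 2)),
                       arm = rep(c("ctrl", "trt"), each = 10))
  fit <- mbt_test(df, value = y, group = arm, ensemble = "student", seed = 1)
  expect_s3_class(fit, "mbt_ensemble")
  expect_gt(fit$incl_bf$effect$bf, 1)
})
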