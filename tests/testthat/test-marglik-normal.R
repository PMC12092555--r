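test_that("two conditional-marginal evaluation routes agree", {
  # noncentral-t identity route vs the mode-centred log-space quadrature;
  # compared where the nct evaluation is itself numerically reliable (the
  # posterior bulk; in far tails R's noncentral-t density loses precision)
  sf <- mbttest:::normal_suffstats(two_sample_summary(10, 0, 1, 10, 0.5, 1))
  for (delta in c(0, 0.3, -1.2, 2)) {
    for (rho in c(0.5, 0.3, 0.8)) {
      expect_equal(mbttest:::cond_logml_normal(sf, delta, rho),
                   mbttest:::cond_logml_normal_nct(sf, delta, rho),
                   tolerance = 1e-7)
    }
  }
})

test_that("unequal-variance integrand at rho = 0.5 nests the equal-variance one", {
  sf <- mbttest:::normal_suffstats(replication_summary())
  # dbar < 0 here, so probe deltas on the matching side of the bulk
  for (delta in c(-1.5, -0.7, 0)) {
    # the equal-variance model is the rho = 0.5 slice of the Welch model
    expect_equal(mbttest:::cond_logml_normal(sf, delta, 0.5),
                 mbttest:::cond_logml_normal_nct(sf, delta, 0.5),
                 tolerance = 1e-7)
  }
})

test_that("equal-variance Bayes factor matches a dense 1-D grid oracle", {
  st <- two_sample_summary(10, 0.5, 1, 10, 0, 1)
  f1 <- logml_normal_model(st, model_spec("alternative", "equal", "normal"))
  f0 <- logml_normal_model(st, model_spec("null", "equal", "normal"))
  bf <- bayes_factor(f1, f0)$bf
  bf_oracle <- dense_grid_bf_student(st)
  expect_equal(bf, bf_oracle, tolerance = 1e-6)  # 6+ significant digits
  expect_equal(f1$log_ml_se, 0)
})

test_that("Bayes factors are invariant to location shifts and rescaling", {
  st <- two_sample_summary(12, 1.1, 0.8, 9, 0.2, 1.9)
  specs <- model_grid("mb4")
  lm <- vapply(specs, function(sp) logml_normal_model(st, sp)$log_ml, numeric(1))
  for (tf in list(c(a = 5.5, c = 1), c(a = 0, c = 3.2), c(a = -2, c = 0.04))) {
    st2 <- two_sample_summary(12, tf["c"] * 1.1 + tf["a"], tf["c"] * 0.8,
                              9, tf["c"] * 0.2 + tf["a"], tf["c"] * 1.9)
    lm2 <- vapply(specs, function(sp) logml_normal_model(st2, sp)$log_ml,
                  numeric(1))
    # every pairwise BF unchanged: log-ml differences shift by a common constant
    expect_equal(lm2 - lm2[1], lm - lm[1], tolerance = 1e-8)
  }
})

test_that("a point mass at rho = 0.5 reproduces the equal-variance model", {
  st <- replication_summary()
  sf <- mbttest:::normal_suffstats(st)
  # exact statement: the Welch integrand restricted to rho = 0.5 IS the
  # equal-variance marginal, for the null model and along the delta axis
  f_eq0 <- logml_normal_model(st, model_spec("null", "equal", "normal"))
  expect_equal(mbttest:::cond_logml_normal(sf, 0, 0.5), f_eq0$log_ml,
               tolerance = 1e-12)
  gl <- mbttest:::gauss_legendre_01(257)
  d_nodes <- mbttest:::delta_from_u(gl$x, prior_settings())
  lg <- mbttest:::cond_logml_normal(sf, d_nodes, rep(0.5, 257))
  m <- max(lg)
  f_eq1 <- logml_normal_model(st, model_spec("alternative", "equal", "normal"))
  expect_equal(m + log(sum(gl$w * exp(lg - m))), f_eq1$log_ml,
               tolerance = 1e-8)
  # and a Beta(a, a) prior concentrating at 1/2 approaches the equal-variance
  # marginal as a grows (O(1/a) approximation error)
  gap <- vapply(c(50, 200), function(a) {
    abs(logml_normal_model(st, model_spec("null", "unequal", "normal"),
                           prior_settings(rho_shape = c(a, a)))$log_ml -
          f_eq0$log_ml)
  }, numeric(1))
  expect_lt(gap[2], gap[1] / 2)
})

test_that("quadrature marginal likelihoods match the tensor-grid oracle", {
  toy <- toy_data()
  st <- summarize_groups(toy)
  checks <- list(
    list(spec = model_spec("null", "equal", "normal"), nd = 1, nn = 100),
    list(spec = model_spec("alternative", "equal", "normal"), nd = 120, nn = 100),
    list(spec = model_spec("null", "unequal", "normal"), nd = 80, nn = 100),
    list(spec = model_spec("alternative", "unequal", "normal"), nd = 70, nn = 100)
  )
  for (ch in checks) {
    f <- logml_normal_model(st, ch$spec)
    o <- logml_grid_oracle(toy, ch$spec, nodes_per_dim = ch$nd,
                           nodes_nuisance = ch$nn)
    expect_equal(f$log_ml, o, tolerance = 1e-6,
                 label = sprintf("log ML of %s", ch$spec$label))
  }
})

test_that("Bayes factor bookkeeping refuses mismatched data and inverts", {
  st <- two_sample_summary(10, 0.5, 1, 10, 0, 1)
  f1 <- logml_normal_model(st, model_spec("alternative", "equal", "normal"))
  f0 <- logml_normal_model(st, model_spec("null", "equal", "normal"))
  expect_equal(bayes_factor(f1, f1)$bf, 1)
  expect_equal(bayes_factor(f1, f0)$bf, 1 / bayes_factor(f0, f1)$bf,
               tolerance = 1e-12)
  other <- logml_normal_model(two_sample_summary(8, 1, 1, 8, 0, 1),
                              model_spec("null", "equal", "normal"))
  expect_error(bayes_factor(f1, other), "different data")
})
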