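test_that("precision proportion follows the worked variance example", {
  expect_equal(rho_from_variances(2, 4), 2 / 3)
  expect_equal(rho_from_variances(7.3, 7.3), 0.5)
  for (v in list(c(1, 9), c(0.2, 5), c(3, 0.01))) {
    expect_equal(rho_from_variances(v[1], v[2]) + rho_from_variances(v[2], v[1]), 1)
  }
  expect_error(rho_from_variances(-1, 2), "positive")
})

test_that("rho/SDR transforms are mutually inverse and match the variance pair", {
  expect_equal(sdr_from_rho(0.5), 1)
  # variances 2 and 4 give rho = 2/3 and sigma1/sigma2 = sqrt(1/2)
  expect_equal(sdr_from_rho(2 / 3), sqrt(1 / 2), tolerance = 1e-12)
  r <- c(0.01, 0.2, 0.5, 0.77, 0.99)
  expect_equal(rho_from_sdr(sdr_from_rho(r)), r, tolerance = 1e-12)
  expect_equal(sdr_from_rho(rho_from_sdr(c(0.3, 1, 4))), c(0.3, 1, 4),
               tolerance = 1e-12)
  # flipped convention is the reciprocal
  expect_equal(sdr_from_rho(0.2, convention = "group2/group1"),
               1 / sdr_from_rho(0.2))
  expect_error(sdr_from_rho(1), "strictly")
  expect_error(rho_from_sdr(0), "positive")
})

test_that("group parametrization is a bijection with the common parameters", {
  gp <- group_params(0, 1, 0, 0.5)
  expect_equal(unlist(gp), c(mu1 = 0, mu2 = 0, sigma1 = 1, sigma2 = 1))
  gp1 <- group_params(0, 1, 1, 0.5)
  expect_equal(unlist(gp1), c(mu1 = -0.5, mu2 = 0.5, sigma1 = 1, sigma2 = 1))

  set.seed(1)
  for (i in 1:25) {
    th <- list(mu = rnorm(1), sigma = rexp(1) + 0.1,
               delta = rnorm(1, 0, 2), rho = runif(1, 0.02, 0.98))
    gp <- group_params(th$mu, th$sigma, th$delta, th$rho)
    # implied precision share reproduces rho
    expect_equal(rho_from_variances(gp$sigma1^2, gp$sigma2^2), th$rho,
                 tolerance = 1e-12)
    # grand variance identity
    expect_equal(gp$sigma1^2 + gp$sigma2^2, 2 * th$sigma^2, tolerance = 1e-12)
    back <- grand_params(gp$mu1, gp$mu2, gp$sigma1, gp$sigma2)
    expect_equal(unlist(back), unlist(th), tolerance = 1e-12)
  }
})

test_that("t scale keeps the group SD fixed", {
  expect_equal(t_scale(1, 4), sqrt(1 / 2))
  expect_equal(t_scale(2.5, Inf), 2.5)
  for (nu in c(2.1, 3, 7, 50)) {
    s <- t_scale(1.7, nu)
    expect_equal(s * sqrt(nu / (nu - 2)), 1.7, tolerance = 1e-12)
  }
  expect_error(t_scale(1, 2), "exceed 2")
})

test_that("log prior matches closed-form densities and model constraints", {
  pr <- prior_settings()
  th <- list(mu = 0, sigma = 1, delta = 0, rho = 0.5, nu = Inf)
  sp <- model_spec("null", "equal", "normal")
  expect_equal(log_prior(th, pr, sp), 0)  # only the Jeffreys -log(sigma) term

  th1 <- list(mu = 0, sigma = 2, delta = 0, rho = 0.5, nu = Inf)
  sp1 <- model_spec("alternative", "equal", "normal")
  expect_equal(log_prior(th1, pr, sp1), -log(2) + log(sqrt(2) / pi))
  th2 <- list(mu = 0, sigma = 1, delta = 0.4, rho = 0.5, nu = 2.7)
  sp2 <- model_spec("alternative", "equal", "t")
  expect_equal(log_prior(th2, pr, sp2),
               dcauchy(0.4, 0, 1 / sqrt(2), log = TRUE) + dexp(0.7, log = TRUE))
  # Beta(1.5, 1.5) at 1/2 is 4/pi
  th3 <- list(mu = 0, sigma = 1, delta = 0, rho = 0.5, nu = Inf)
  sp3 <- model_spec("null", "unequal", "normal")
  expect_equal(log_prior(th3, pr, sp3), log(4 / pi))
  # support boundary of the shifted exponential
  th4 <- list(mu = 0, sigma = 1, delta = 0, rho = 0.5, nu = 2)
  sp4 <- model_spec("null", "equal", "t")
  expect_equal(exp(log_prior(th4, pr, sp4)), 1)
  th5 <- th4; th5$nu <- 1.5
  expect_error(log_prior(th5, pr, sp4), NA)  # value check below
  expect_equal(log_prior(th5, pr, sp4), -Inf)

  expect_error(log_prior(list(mu = 0, sigma = 1, delta = 1, rho = 0.5, nu = Inf),
                         pr, model_spec("null", "equal", "normal")),
               "delta = 0")
})

test_that("free prior densities integrate to one", {
  pr <- prior_settings()
  expect_equal(integrate(dcauchy, -Inf, Inf, location = 0,
                         scale = pr$delta_scale, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(dbeta, 0, 1, shape1 = 1.5, shape2 = 1.5,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
  expect_equal(integrate(function(x) dexp(x - 2), 2, Inf,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
})

test_that("SDR interval mass matches the incomplete-beta value and Monte Carlo", {
  m <- prior_mass_sdr_interval(1 / 3, 3)
  expect_equal(m, pbeta(0.9, 1.5, 1.5) - pbeta(0.1, 1.5, 1.5), tolerance = 1e-12)
  expect_equal(round(m, 1), 0.9)  # the headline ~90% statement
  expect_equal(prior_mass_sdr_interval(0, Inf), 1)

  set.seed(2)
  n <- 1e6
  sdr <- sdr_from_rho(rbeta(n, 1.5, 1.5))
  mc <- mean(sdr >= 1 / 3 & sdr <= 3)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(mc - m), 3 * se)

  # mass is increasing in the interval width and tends to 1
  xs <- c(1.5, 2, 3, 5, 10, 100)
  ms <- vapply(xs, function(x) prior_mass_sdr_interval(1 / x, x), numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_equal(ms[length(ms)], 1, tolerance = 1e-3)
})

test_that("degrees-of-freedom prior summary matches the shifted exponential", {
  s <- nu_prior_summary()
  expect_equal(s$mean, 3)
  expect_equal(s$median, 2 + log(2))
  expect_equal(round(s$q1, 1), 2.3)
  expect_equal(round(s$q3, 1), 3.4)
})

test_that("prior settings validate and round-trip through YAML and JSON", {
  expect_error(prior_settings(delta_scale = -1), "range")
  expect_error(prior_settings(rho_shape = c(0, 1)), "positive")
  expect_error(prior_settings(nu_shift = 1.5), "range")
  expect_error(prior_settings(model_probs = c(0.6, 0.6)), "sum to 1")

  pr <- prior_settings(delta_scale = 0.05, rho_shape = c(2, 3),
                       delta_truncation = c(0, Inf))
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_prior_settings(pr, path)
    pr2 <- read_prior_settings(path)
    expect_equal(pr2$delta_scale, 0.05)
    expect_equal(pr2$rho_shape, c(2, 3))
    expect_equal(pr2$delta_truncation, c(0, Inf))
  }
})
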