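test_that("condition construction derives group sizes with the rounding rule", {
  c1 <- sim_condition(total_n = 50, allocation = 2)
  expect_equal(c(c1$n1, c1$n2), c(33L, 17L))
  c2 <- sim_condition(total_n = 20, allocation = 1)
  expect_equal(c(c2$n1, c2$n2), c(10L, 10L))
  c3 <- sim_condition(total_n = 20, allocation = 1 / 2)
  expect_equal(c(c3$n1, c3$n2), c(7L, 13L))
  expect_error(sim_condition(total_n = 5, allocation = 4), "< 2")
  g <- full_condition_grid(reps = 2)
  expect_equal(nrow(g), 243L)
  expect_true(all(g$n1 >= 2 & g$n2 >= 2))
})

test_that("simulated populations match the requested moments and tails", {
  # large-sample moment check on a heavy-tailed unequal-variance condition
  cond <- sim_condition(delta = 0.5, sdr = 2, nu = 5, total_n = 20,
                        allocation = 1)
  big <- local({
    # pool many replicates for a Monte-Carlo estimate of population moments
    g1 <- c(); g2 <- c()
    for (r in 1:2000) {
      d <- simulate_condition(cond, rep_index = r, seed = 1)
      g1 <- c(g1, d$group1); g2 <- c(g2, d$group2)
    }
    list(g1 = g1, g2 = g2)
  })
  expect_equal(sd(big$g1) / sd(big$g2), 2, tolerance = 0.02)
  expect_equal(mean(big$g2) - mean(big$g1), 0.5, tolerance = 0.02)
  # population SD standardized: grand variance-average equals 1
  expect_equal((sd(big$g1)^2 + sd(big$g2)^2) / 2, 1, tolerance = 0.03)
  # excess kurtosis under nu = 5 exceeds the normal value
  kurt <- function(x) mean((x - mean(x))^4) / sd(x)^4
  expect_gt(kurt(big$g1), 3.5)

  # null normal condition: standard normal populations
  cond0 <- sim_condition(delta = 0, sdr = 1, nu = Inf, total_n = 20)
  d0 <- simulate_condition(cond0, 1, seed = 2)
  expect_equal(length(d0$group1), 10L)
  set.seed(99)
  y <- replicate(3000, {
    d <- simulate_condition(cond0, sample.int(1e6, 1), seed = 3)
    c(mean(d$group1), sd(d$group1))
  })
  expect_equal(mean(y[1, ]), 0, tolerance = 0.02)
  expect_equal(mean(y[2, ]^2), 1, tolerance = 0.03)

  # raw t scale skips the SD standardization
  d_raw <- simulate_condition(cond, 1, seed = 4, raw_t_scale = TRUE)
  expect_s3_class(d_raw, "two_sample_data")
})

test_that("simulation is reproducible from (seed, condition, rep)", {
  cond <- sim_condition(delta = 0.3, sdr = 1.5, nu = 10, total_n = 50)
  a <- simulate_condition(cond, 7, seed = 5)
  b <- simulate_condition(cond, 7, seed = 5)
  expect_identical(a$group1, b$group1)
  c2 <- simulate_condition(cond, 8, seed = 5)
  expect_false(identical(a$group1, c2$group1))
})

test_that("evidence distortion factor is a guarded ratio", {
  expect_equal(edf(5, 5), 1)
  expect_equal(edf(67.4, 37.2), 67.4 / 37.2, tolerance = 1e-12)
  expect_equal(round(edf(67.4, 37.2), 2), 1.81)
  expect_equal(edf(3, 7) * edf(7, 3), 1, tolerance = 1e-12)
  expect_error(edf(-1, 2), "positive")
})

test_that("run_study produces the tidy record schema deterministically", {
  grid <- sim_condition(delta = 0.5, sdr = 1, nu = Inf, total_n = 20, reps = 2)
  rec <- run_study(grid, methods = c("student", "welch", "mb4"), seed = 3)
  expect_equal(nrow(rec), 6L)  # 2 reps x 3 methods
  expect_named(rec, c("condition", "rep", "method", "bf10", "ref_method",
                      "bf_ref", "edf"))
  expect_true(all(is.finite(rec$bf10)))
  expect_equal(unique(rec$ref_method), "student")
  # matching test has EDF identically 1
  expect_true(all(rec$edf[rec$method == "student"] == 1))

  rec2 <- run_study(grid, methods = c("student", "welch", "mb4"), seed = 3)
  expect_identical(rec$bf10, rec2$bf10)

  summ <- summarize_study(rec)
  expect_true(all(c("geo_mean_edf", "edf_q50") %in% names(summ)))
  expect_equal(nrow(summ), 3L)
})

test_that("Student and Welch agree under equal n, equal variances, normal data", {
  grid <- sim_condition(delta = 0.3, sdr = 1, nu = Inf, total_n = 100, reps = 40)
  rec <- run_study(grid, methods = c("student", "welch"), seed = 11)
  wide <- tidyr::pivot_wider(rec[, c("rep", "method", "bf10")],
                             names_from = "method", values_from = "bf10")
  ratio <- wide$welch / wide$student
  expect_gte(mean(abs(log(ratio)) < log(1.1)), 0.95)
})

test_that("Welch evidence exceeds Student evidence when the larger group is more variable", {
  # deterministic summary-statistic grid, no simulation: n1 = 33 < n2 = 66
  grid <- explore_grid(n1 = 33, n2 = 66, md = c(0.5, 0.8, 1),
                       sdr = c(1 / 3, 1 / 2, 2 / 3))
  # sdr = s1/s2 < 1: the larger (second) group is the more variable one
  expect_true(all(grid$bf_welch > grid$bf_student))
})

test_that("condition grids round-trip through YAML", {
  g <- dplyr::bind_rows(
    sim_condition(delta = 0.5, sdr = 2, nu = 5, total_n = 50, allocation = 2,
                  reps = 3),
    sim_condition(delta = 0, sdr = 1, nu = Inf, total_n = 20, reps = 2)
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_condition_grid(g, path)
  g2 <- read_condition_grid(path)
  expect_equal(g2$delta, g$delta)
  expect_equal(g2$nu, g$nu)
  expect_equal(g2$n1, g$n1)
  expect_equal(g2$reps, g$reps)
})
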