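test_that("rejection threshold matches the two-sided normal quantile", {
  expect_equal(rejection_threshold(1), 0)
  expect_equal(rejection_threshold(0.05), 1.959964, tolerance = 1e-6)
  expect_equal(rejection_threshold(5e-8), 5.4513, tolerance = 1e-4)
  expect_error(rejection_threshold(0), "0, 1")
  expect_error(rejection_threshold(1.5), "0, 1")
})

test_that("power at beta = 0 is exactly the size of the test", {
  for (pc in c(5e-8, 1e-6, 0.05)) {
    zc <- rejection_threshold(pc)
    for (v in c(1e-5, 1e-4, 1e-2, 1)) {
      expect_equal(detection_power(0, v, zc), pc, tolerance = 1e-12)
    }
  }
})

test_that("power is symmetric, monotone in effect, and near 1 far out", {
  zc <- rejection_threshold(5e-8)
  v <- 2.5e-4
  b <- seq(0.005, 0.3, by = 0.005)
  expect_equal(detection_power(b, v, zc), detection_power(-b, v, zc))
  expect_true(all(diff(detection_power(b, v, zc)) >= 0))  # saturates at 1
  expect_true(all(diff(detection_power(b[b <= 0.1], v, zc)) > 0))
  # standardized effect of 10 is detected essentially always
  expect_gte(detection_power(10 * sqrt(v), v, zc), 0.99999)
})

test_that("power agrees with a Monte-Carlo rejection rate of Wald draws", {
  pc <- 0.05
  zc <- rejection_threshold(pc)
  mu <- 3
  v <- 4e-4
  beta <- mu * sqrt(v)
  set.seed(101)
  z <- rnorm(1e6, mean = mu, sd = 1)
  rate <- mean(abs(z) >= zc)
  p <- detection_power(beta, v, zc)
  se <- sqrt(p * (1 - p) / 1e6)
  expect_lt(abs(rate - p), 3 * se)
})

test_that("variance rescaling follows the inverse-sample-size ratio", {
  expect_equal(rescale_variance(3e-4, 5000, 6000, 5000, 6000), 3e-4)
  expect_equal(rescale_variance(3e-4, 5000, 6000, 10000, 12000), 1.5e-4)
  expect_equal(rescale_variance(1, 200, 200, 100, 300), 4 / 3)
})

test_that("effective cases is the harmonic mean of the two arms", {
  expect_equal(effective_cases(12000, 12000), 12000)
  expect_equal(effective_cases(100, 300), 150)
  # unbalanced real-study-sized arms, checked against direct arithmetic
  expect_equal(effective_cases(130664, 330470),
               2 / (1 / 130664 + 1 / 330470))
})

test_that("rejection probability mixes null size with power over g", {
  grid <- make_grid()
  g2 <- two_spike_g(grid)
  zc <- rejection_threshold(5e-8)
  v <- 2.5e-4
  expect_equal(rejection_probability(v, fake_fit(0, g2), zc), 5e-8,
               tolerance = 1e-12)
  pm <- point_mass_distribution(grid, 0.1)
  expect_equal(rejection_probability(v, fake_fit(1, pm), zc),
               detection_power(0.1, v, zc))
  # generic fit vs Monte-Carlo rejection rate of SNPs simulated from it
  f <- fake_fit(0.3, g2)
  pc <- 1e-3
  zc2 <- rejection_threshold(pc)
  p <- rejection_probability(v, f, zc2)
  y <- simulate_from_fit(f, rep(v, 1e6), seed = 77)
  rate <- mean(abs(y) / sqrt(v) >= zc2)
  expect_lt(abs(rate - p), 3 * sqrt(p * (1 - p) / 1e6))
})

test_that("predicted count is m_star times the mean rejection probability", {
  grid <- make_grid()
  g2 <- two_spike_g(grid)
  sc <- synthetic_scenario(m = 400, pi_true = 0.2, g_true = g2,
                           n_r = 10000, n_s = 10000, seed = 4)
  ds <- simulate_dataset(sc)
  cfg <- prediction_config(p_c = 5e-8, m_star = 100000,
                           n_r = 10000, n_s = 10000,
                           n_r_star = 40000, n_s_star = 40000)
  # null-only fit: K = m_star * p_c
  expect_equal(predict_num_significant(fake_fit(0, g2), ds$table, cfg),
               0.005, tolerance = 1e-10)
  # definitional identity against an explicit per-SNP loop
  f <- fake_fit(0.25, g2)
  k <- predict_num_significant(f, ds$table, cfg)
  zc <- rejection_threshold(cfg$p_c)
  pj <- vapply(seq_len(nrow(ds$table)), function(j) {
    vs <- ds$table$var_hat[j] * (1 / 40000 + 1 / 40000) / (1 / 10000 + 1 / 10000)
    (1 - f$pi) * detection_power(0, vs, zc) +
      f$pi * sum(f$g$masses * detection_power(f$g$points, vs, zc))
  }, numeric(1))
  expect_equal(k, cfg$m_star * mean(pj), tolerance = 1e-10)
})

test_that("discovery curves are consistent, monotone, and flat under the null", {
  g2 <- two_spike_g()
  sc <- synthetic_scenario(m = 400, pi_true = 0.2, g_true = g2,
                           n_r = 10000, n_s = 10000, seed = 4)
  ds <- simulate_dataset(sc)
  cfg <- prediction_config(n_r = 10000, n_s = 10000,
                           n_r_star = 10000, n_s_star = 10000)
  f <- fake_fit(0.25, g2)
  grid_ne <- c(5000, 10000, 20000, 40000, 80000)
  curve <- discovery_curve(f, ds$table, cfg, grid_ne)
  expect_true(all(diff(curve$k_hat) > 0))
  # at the current effective size the curve reproduces the point prediction
  expect_equal(curve$k_hat[curve$n_e_star == 10000],
               predict_num_significant(f, ds$table, cfg))
  flat <- discovery_curve(fake_fit(0, g2), ds$table, cfg, grid_ne)
  expect_equal(flat$k_hat, rep(0.005, 5), tolerance = 1e-10)
  expect_error(discovery_curve(f, ds$table, cfg, c(2, 1)), "increasing")
})

test_that("required effective cases inverts the discovery curve", {
  g2 <- two_spike_g()
  sc <- synthetic_scenario(m = 400, pi_true = 0.2, g_true = g2,
                           n_r = 10000, n_s = 10000, seed = 4)
  ds <- simulate_dataset(sc)
  cfg <- prediction_config(n_r = 10000, n_s = 10000,
                           n_r_star = 10000, n_s_star = 10000)
  f <- fake_fit(0.25, g2)
  k_at <- function(ne) {
    cc <- prediction_config(n_r = 10000, n_s = 10000,
                            n_r_star = ne, n_s_star = ne)
    predict_num_significant(f, ds$table, cc)
  }
  for (k_target in c(5, 50)) {
    ne <- required_effective_cases(f, ds$table, cfg, k_target)
    expect_equal(as.numeric(ne) %% 1000, 0)
    expect_gte(k_at(ne), k_target)
    expect_lt(k_at(as.numeric(ne) - 1000), k_target)
  }
  expect_gte(required_effective_cases(f, ds$table, cfg, 100),
             required_effective_cases(f, ds$table, cfg, 10))
  # trivially achievable target returns the smallest reporting unit
  expect_equal(as.numeric(required_effective_cases(f, ds$table, cfg, 1e-9)),
               1000)
  # unachievable target caps with a warning
  expect_warning(
    capped <- required_effective_cases(f, ds$table, cfg, 1e7,
                                       ceiling_n = 50000),
    "not achievable"
  )
  expect_equal(as.numeric(capped), 50000)
})

test_that("percentile intervals use the documented order statistics", {
  expect_equal(percentile_interval(1:100, 0.95), c(3, 98))
  expect_equal(percentile_interval(c(4, 9), 0.95), c(4, 9))
  # equivariance under a positive linear map (K = m_star * mean rate)
  set.seed(3)
  x <- runif(30)
  expect_equal(percentile_interval(1e5 * x, 0.9),
               1e5 * percentile_interval(x, 0.9))
})
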