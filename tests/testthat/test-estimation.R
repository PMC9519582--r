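test_that("sigma points have the closed scalar form and unit weight sum", {
  cfg <- filter_config(alpha = 1e-3, beta = 2, kappa = 0)
  sp <- sigma_points(0, matrix(1), cfg)
  lambda <- cfg$alpha^2 * (1 + cfg$kappa) - 1
  expect_equal(sp$points[, 1],
               c(0, sqrt(1 + lambda), -sqrt(1 + lambda)))
  expect_equal(sum(sp$wm), 1)
})

test_that("sigma points reconstruct a 5-D Gaussian to 1e-10", {
  cfg <- filter_config()
  set.seed(3)
  for (i in 1:5) {
    A <- matrix(rnorm(25), 5)
    P <- crossprod(A) + diag(5) * 0.1
    m <- rnorm(5)
    sp <- sigma_points(m, P, cfg)
    mom <- stromasim:::ut_moments(sp$points, sp$wm, sp$wc)
    expect_lt(max(abs(mom$mean - m)), 1e-10)
    expect_lt(max(abs(mom$cov - P)), 1e-10)
  }
})

test_that("non-PSD covariance is rejected", {
  expect_error(sigma_points(c(0, 0), matrix(c(1, 2, 2, 1), 2),
                            filter_config()),
               "positive semi-definite")
})

test_that("hybrid filter matches a discrete Kalman filter on a linear system", {
  a <- 0.3
  lin <- make_linear_model(a)
  times <- c(0, 24, 48, 72)
  obs <- matrix(c(1, 0.7, 0.4, 0.2), 1, 4,
                dimnames = list("SMAD7", times))
  q <- 1e-4; R <- 0.05; P0 <- 0.3^2
  cfg <- filter_config(n_passes = 1, measurement_noise = R,
                       process_noise = q, init_state_sd = sqrt(P0),
                       ode_rtol = 1e-11, ode_atol = 1e-13)
  res <- hukf_estimate(lin, obs, cfg)
  oracle <- scalar_kf(a, times, obs[1, ], m0 = 1, P0 = P0, q = q, R = R)
  expect_lt(abs(res$filter_state$mean - oracle$mean), 1e-6)
  expect_lt(abs(res$filter_state$covariance - oracle$var), 1e-6)
})

test_that("truth-initialized filter on exact data does not drift", {
  spec <- build_cancer_cell_network()
  free <- c("k8p", "k9p")
  truth <- spec$network$parameters[free]
  obs <- generate_timecourse(spec, noise_sd = 0, times = c(0, 24, 48))
  cfg <- filter_config(free_parameters = free, n_passes = 3,
                       measurement_noise = 1e-4,
                       init_param_sd = 1e-4,
                       param_process_noise = 1e-10,
                       ode_rtol = 1e-8, ode_atol = 1e-10)
  res <- hukf_estimate(spec, obs, cfg)
  drift <- abs(res$estimated_parameters - truth) / truth
  expect_lt(max(drift), 1e-4)
})

test_that("filter output is finite with a PSD covariance", {
  spec <- build_cancer_cell_network()
  cfg <- filter_config(free_parameters = c("k8p", "k8m"), n_passes = 2)
  obs <- generate_timecourse(spec, noise_sd = 0.05, seed = 4)
  res <- hukf_estimate(spec, obs, cfg)
  expect_true(all(is.finite(res$filter_state$mean)))
  expect_true(all(res$estimated_parameters > 0))
  ev <- eigen(res$filter_state$covariance, symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), 0)
})

test_that("goodness of fit matches hand computations", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$r_squared, 1)
  expect_equal(g$rmse, 0)

  obs <- c(1, 2, 3)
  g2 <- goodness_of_fit(rep(mean(obs), 3), obs)
  expect_equal(g2$r_squared, 0)

  g3 <- goodness_of_fit(c(1, 2, 4), obs)
  expect_equal(g3$rmse, sqrt(1 / 3))
  expect_equal(g3$mae, 1 / 3)

  expect_error(goodness_of_fit(c(1, 2), c(2, 2)), "variance")
})

test_that("Bland-Altman bias and limits match hand computations", {
  ba <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 0)

  a <- c(1, 2, 3)
  ba2 <- bland_altman(a, a + 0.5)
  expect_equal(ba2$bias, -0.5)
  expect_equal(ba2$loa_high - ba2$loa_low, 0)

  ba3 <- bland_altman(c(1, 2, 3), c(2, 2, 2))
  expect_equal(ba3$bias, 0)
  expect_equal(ba3$loa_low, -1.96)
  expect_equal(ba3$loa_high, 1.96)

  expect_error(bland_altman(1, 1), "length")
})
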