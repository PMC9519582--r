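mech0 <- mechanics_params()

test_that("state classification follows the decision precedence", {
  cell <- cell_agent(1, "cancer", c(0, 0, 0))
  thr <- thresholds(T_CXCL12 = 1, T_SNAIL = 1, T_ECM = 0.5)

  expect_equal(classify_state(cell, 0, 0, 1, thr), "quiescent")
  expect_equal(classify_state(cell, 0, 2, 0.4, thr), "migratory")
  expect_equal(classify_state(cell, 2, 0.5, 0.4, thr), "proliferative")
  # SNAIL above threshold but ECM intact: not migratory
  expect_equal(classify_state(cell, 0, 2, 2, thr), "quiescent")
  # migratory takes precedence over proliferative
  expect_equal(classify_state(cell, 2, 2, 0.4, thr), "migratory")

  caf <- cell_agent(2, "caf", c(0, 0, 0))
  expect_error(classify_state(caf, 0, 0, 0, thr), "cancer")
})

test_that("raising SNAIL never demotes a migratory cell", {
  cell <- cell_agent(1, "cancer", c(0, 0, 0))
  set.seed(8)
  for (i in 1:50) {
    thr <- thresholds(runif(1), runif(1), runif(1, 0, 2))
    u_c <- runif(1); u_s <- runif(1); ecm <- runif(1, 0, 2)
    s1 <- classify_state(cell, u_c, u_s, ecm, thr)
    s2 <- classify_state(cell, u_c, u_s + runif(1), ecm, thr)
    if (s1 == "migratory") expect_equal(s2, "migratory")
  }
})

test_that("pairwise forces have the printed Hertz magnitude and symmetry", {
  # geometry with delta = 1: radii 1+1, centers 1 apart, unit moduli
  m <- mechanics_params(E_hat = 1, W = 0, adhesion_range = 0)
  ci <- cell_agent(1, "cancer", c(0, 0, 0), radius = 1)
  cj <- cell_agent(2, "cancer", c(1, 0, 0), radius = 1)
  # Rhat = 1/2 here; rescale radii so Rhat = 1: use radius 2 cells
  ci2 <- cell_agent(1, "cancer", c(0, 0, 0), radius = 2)
  cj2 <- cell_agent(2, "cancer", c(3, 0, 0), radius = 2)   # delta = 1
  f <- pairwise_force(ci2, cj2, m)
  expect_equal(sqrt(sum(f^2)), 4 / 3 * sqrt(1) * 1^1.5)
  expect_equal(f[1], -4 / 3)    # pushes ci2 away from cj2 (negative x)

  # Newton's third law
  f_ji <- pairwise_force(cj2, ci2, m)
  expect_equal(f_ji, -f)

  # no interaction beyond contact + adhesion range
  far <- cell_agent(3, "cancer", c(100, 0, 0), radius = 1)
  expect_equal(pairwise_force(ci, far, mech0), c(0, 0, 0))
})

test_that("adhesion acts as a constant attraction near contact", {
  m <- mechanics_params(E_hat = 0, W = 0.1, adhesion_range = 2)
  ci <- cell_agent(1, "cancer", c(0, 0, 0), radius = 8)
  cj <- cell_agent(2, "cancer", c(17, 0, 0), radius = 8)  # gap 1 um
  f <- pairwise_force(ci, cj, m)
  Rhat <- 8 * 8 / 16
  expect_equal(f[1], pi * 0.1 * Rhat)   # pulls ci toward cj (+x)
})

test_that("pairwise forces sum to zero over a random population", {
  set.seed(12)
  cells <- lapply(1:12, function(i)
    cell_agent(i, sample(c("cancer", "caf"), 1),
               runif(3, -20, 20), radius = runif(1, 6, 9)))
  F <- population_pairwise_forces(cells, mech0)
  scale <- max(abs(F), 1e-12)
  expect_lt(max(abs(colSums(F))) / scale, 1e-9)
})

test_that("environment force combines haptotaxis and active terms", {
  cell <- cell_agent(1, "cancer", c(0, 0, 0))
  m <- mechanics_params(chi = 2, eta = 10, A0 = 0.5, n_hill = 2)

  # uniform ECM and no SNAIL: zero force
  expect_equal(environment_force(cell, c(0, 0, 0), 0, c(1, 0, 0), m),
               c(0, 0, 0))

  # half saturation: active magnitude eta/2
  f <- environment_force(cell, c(0, 0, 0), 0.5, c(0, 1, 0), m)
  expect_equal(f, c(0, 5, 0))

  # haptotaxis as printed: -chi * grad
  f2 <- environment_force(cell, c(0.3, 0, 0), 0, c(1, 0, 0), m)
  expect_equal(f2, c(-0.6, 0, 0))

  # non-unit direction is normalized with a warning
  expect_warning(f3 <- environment_force(cell, c(0, 0, 0), 10,
                                         c(0, 2, 0), m), "unit")
  expect_equal(f3[2], 10 * (10^2 / (10^2 + 0.5^2)), tolerance = 1e-6)
})

test_that("only migratory cancer cells move, at V = F/gamma", {
  cells <- list(
    cell_agent(1, "cancer", c(0, 0, 0), state = "migratory"),
    cell_agent(2, "cancer", c(30, 0, 0), state = "quiescent"),
    cell_agent(3, "caf", c(60, 0, 0)))
  F <- rbind(c(2, 0, 0), c(2, 0, 0), c(2, 0, 0))
  out <- advance_cells(cells, F, gamma_cs = 2, dt = 1)
  expect_equal(out[[1]]$position, c(1, 0, 0))
  expect_equal(out[[2]]$position, c(30, 0, 0))
  expect_equal(out[[3]]$position, c(60, 0, 0))
  expect_error(advance_cells(cells, F, gamma_cs = 0, dt = 1), "gamma")

  # zero net force: zero displacement
  out0 <- advance_cells(cells, matrix(0, 3, 3), 1, 5)
  expect_equal(out0[[1]]$position, c(0, 0, 0))
})

test_that("two equal overlapping migratory cells separate symmetrically", {
  m <- mechanics_params(W = 0)
  cells <- list(
    cell_agent(1, "cancer", c(-5, 0, 0), state = "migratory"),
    cell_agent(2, "cancer", c(5, 0, 0), state = "migratory"))
  F <- population_pairwise_forces(cells, m)
  out <- advance_cells(cells, F, 1, 1)
  d1 <- out[[1]]$position - c(-5, 0, 0)
  d2 <- out[[2]]$position - c(5, 0, 0)
  expect_equal(d1, -d2)
  expect_lt(d1[1], 0)   # pushed apart
})

test_that("division produces a quiescent daughter one radius away", {
  cell <- cell_agent(1, "cancer", c(10, 20, 30), state = "proliferative")
  set.seed(21)
  dv <- divide(cell, new_id = 99, time_h = 24)
  expect_equal(dv$daughter$id, 99)
  expect_equal(dv$daughter$state, "quiescent")
  expect_equal(sqrt(sum((dv$daughter$position - cell$position)^2)),
               cell$radius, tolerance = 1e-12)
  expect_equal(dv$daughter$intracellular, cell$intracellular)

  # seeded reproducibility of the placement direction
  set.seed(21)
  dv2 <- divide(cell, new_id = 99, time_h = 24)
  expect_identical(dv$daughter$position, dv2$daughter$position)

  expect_error(divide(cell_agent(2, "cancer", c(0, 0, 0)), 3),
               "proliferative")
})
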