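test_that("balanced production and degradation cancel in the assembled RHS", {
  net <- reaction_network(
    list(species_spec("x1", "internal", 1)),
    list(reaction("v1", rate_law("mass_action", "k1p", c(x1 = 1)),
                  c(x1 = 1)),
         reaction("v2", rate_law("mass_action", "k1m", c(x1 = 1)),
                  c(x1 = -1))),
    c(k1p = 0.2, k1m = 0.2))
  rhs <- assemble_rhs(net)
  for (x in c(0.1, 1, 5, 42))
    expect_equal(unname(rhs(0, x)), 0)
})

test_that("stoichiometric conservation holds for the binding pair", {
  net <- make_binding_network()
  rhs <- assemble_rhs(net)
  set.seed(7)
  for (i in 1:10) {
    x <- random_conc(c("x1", "xu3", "x2"))
    d <- rhs(0, x)
    expect_equal(unname(d["x1"] + 2 * d["x2"]), 0)
    expect_equal(unname(d["xu3"] + d["x2"]), 0)
  }
})

test_that("assembly is additive over reaction subsets", {
  spec <- build_cancer_cell_network()
  net <- spec$network
  set.seed(11)
  idx <- sample(length(net$reactions), 20)
  netA <- reaction_network(net$species, net$reactions[idx],
                           net$parameters)
  netB <- reaction_network(net$species, net$reactions[-idx],
                           net$parameters)
  rhs <- assemble_rhs(net); rhsA <- assemble_rhs(netA)
  rhsB <- assemble_rhs(netB)
  for (i in 1:5) {
    x <- random_conc(dynamical_species(net))
    u <- random_conc(input_species(net))
    expect_equal(rhs(0, x, u), rhsA(0, x, u) + rhsB(0, x, u))
  }
})

test_that("simulation reproduces analytic exponential decay", {
  net <- make_decay_network(k = 0.3)
  tr <- simulate_network(net, times = seq(0, 24, by = 0.5))
  expect_s3_class(tr, "Trajectory")
  rel <- abs(tr$values[, 1] - exp(-0.3 * tr$times)) /
    exp(-0.3 * tr$times)
  expect_lt(max(rel), 1e-6)
})

test_that("binding conservation drifts below 1e-6 relative over 72 h", {
  net <- make_binding_network()
  tr <- simulate_network(net, times = seq(0, 72, by = 4))
  q1 <- tr$values[, "x1"] + 2 * tr$values[, "x2"]
  q2 <- tr$values[, "xu3"] + tr$values[, "x2"]
  expect_lt(max(abs(q1 - q1[1])) / q1[1], 1e-6)
  expect_lt(max(abs(q2 - q2[1])) / q2[1], 1e-6)
})

test_that("identical simulation calls are bit-identical", {
  spec <- build_cancer_cell_network()
  inp <- c(xu3 = 1, xu4 = 1)
  t1 <- simulate_network(spec$network, inputs = inp,
                         times = seq(0, 24, by = 4))
  t2 <- simulate_network(spec$network, inputs = inp,
                         times = seq(0, 24, by = 4))
  expect_identical(t1, t2)
})

test_that("network validation reports undefined and duplicated symbols", {
  good <- make_binding_network()
  expect_true(check_network(good)$ok)

  bad <- reaction_network(
    list(species_spec("x1", "internal", 1)),
    list(reaction("r1", rate_law("mass_action", "k", c(x99 = 1)),
                  c(x1 = 1))),
    c(k = 1))
  chk <- check_network(bad)
  expect_false(chk$ok)
  expect_true("x99" %in% chk$undefined_species)

  # duplicate labels (as the CAF table prints two w3 routes) warn, not fail
  dup <- reaction_network(
    list(species_spec("x1", "internal", 1)),
    list(reaction("w3", rate_law("mass_action", "k", c(x1 = 1)),
                  c(x1 = -1)),
         reaction("w3", rate_law("mass_action", "k", c(x1 = 1)),
                  c(x1 = 1))),
    c(k = 1))
  chk <- check_network(dup)
  expect_true(chk$ok)
  expect_equal(chk$duplicated_reaction_names, "w3")
})

test_that("network definitions round-trip losslessly through disk", {
  net <- build_caf_network()$network
  path <- tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back, net)
  # shipped definition files match the builders
  ship <- read_network(network_definition_file("cancer"))
  expect_equal(ship, build_cancer_cell_network()$network)
})

test_that("state-length mismatch and bad inputs raise shape errors", {
  net <- make_binding_network()
  rhs <- assemble_rhs(net)
  expect_error(rhs(0, c(1, 2)), "length")
  expect_error(simulate_network(net, times = c(0, 0, 1)), "increasing")
  expect_error(simulate_network(net, x0 = c(x1 = -1, xu3 = 1, x2 = 0)),
               ">= 0")
})
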