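test_that("the sphere mask matches the ball volume fraction", {
  g <- build_domain(radius = 2, nodes_per_axis = 33)
  # node count times node volume vs the bounding cube (volume-ratio oracle)
  frac <- sum(g$mask) * g$spacing^3 / (2 * g$radius)^3
  expect_lt(abs(frac - pi / 6) / (pi / 6), 0.05)
  # center inside, corner outside
  mid <- (g$n + 1) / 2
  expect_true(g$mask[mid, mid, mid])
  expect_false(g$mask[1, 1, 1])
})

test_that("doubling resolution scales interior nodes by about 8", {
  n1 <- sum(build_domain(2, 17)$mask)
  n2 <- sum(build_domain(2, 33)$mask)
  expect_lt(abs(n2 / n1 - 8), 0.8)
})

test_that("invalid grids are rejected", {
  expect_error(build_domain(2, 32), "odd")
  expect_error(build_domain(2, 7), "odd integer >= 9")
})

test_that("a zero-coefficient step leaves the field unchanged", {
  g <- build_domain(2, 17, init = c(ECM = 1, CXCL12 = 0.5))
  g2 <- step_diffusion(g, "CXCL12", diffusion_spec(D = 0, decay = 0), 1)
  expect_identical(g2$fields$CXCL12, g$fields$CXCL12)
})

test_that("unstable explicit steps are rejected with a sub-step hint", {
  g <- build_domain(2, 17)
  spec <- diffusion_spec(D = 0.1)
  expect_error(step_diffusion(g, "CXCL12", spec, 1), "sub-steps")
  # automatic sub-stepping handles the same interval
  expect_s3_class(diffuse(g, "CXCL12", spec, 1), "FieldGrid")
})

test_that("the fundamental ball eigenmode decays at D*pi^2/R^2", {
  R <- 2; D <- 3.6e-3
  g <- build_domain(R, 33)
  r <- sqrt(outer(outer(g$axis^2, g$axis^2, `+`), g$axis^2, `+`))
  u <- array(0, dim(g$mask))
  u[g$mask] <- sin(pi * r[g$mask] / R) / (pi * r[g$mask] / R)
  u[!is.finite(u)] <- 1
  g$fields$SNAIL <- u
  spec <- diffusion_spec(D = D)
  dt <- 0.9 * g$spacing^2 / (6 * D)
  # burn-in to isolate the slowest mode, then measure the decay rate
  for (k in 1:400) g <- step_diffusion(g, "SNAIL", spec, dt)
  a1 <- max(g$fields$SNAIL)
  for (k in 1:200) g <- step_diffusion(g, "SNAIL", spec, dt)
  a2 <- max(g$fields$SNAIL)
  lam <- -log(a2 / a1) / (200 * dt)
  lam_true <- D * pi^2 / R^2
  expect_lt(abs(lam / lam_true - 1), 0.05)
})

test_that("field mass is non-increasing under absorbing boundaries", {
  g <- build_domain(2, 17, init = c(CXCL12 = 1))
  spec <- diffusion_spec(D = 3.6e-3, decay = 0.01)
  m0 <- field_mass(g, "CXCL12")
  masses <- numeric(10)
  for (k in 1:10) {
    g <- diffuse(g, "CXCL12", spec, 1)
    masses[k] <- field_mass(g, "CXCL12")
  }
  expect_true(all(diff(c(m0, masses)) <= 0))
  expect_true(all(g$fields$CXCL12 >= 0))
})

test_that("surface integration is exact for uniform and odd for linear fields", {
  g <- build_domain(2, 17, init = c(CXCL12 = 0))
  rc <- 8   # um
  area <- 4 * pi * um_to_cm(rc)^2

  # uniform field c integrates to c * 4 pi R^2
  g$fields$CXCL12[] <- 2.5
  got <- surface_uptake(g, "CXCL12", c(0, 0, 0), rc)
  expect_equal(got, 2.5 * area, tolerance = 1e-6)
  expect_equal(surface_mean(g, "CXCL12", c(0, 0, 0), rc), 2.5,
               tolerance = 1e-6)

  # zero field integrates to zero
  g$fields$CXCL12[] <- 0
  expect_equal(surface_uptake(g, "CXCL12", c(0, 0, 0), rc), 0)

  # linear field: odd part cancels by quadrature symmetry
  ax <- g$axis
  lin <- array(rep(ax, times = g$n^2), dim(g$mask))   # u = x (cm)
  g$fields$CXCL12 <- lin + 3
  got <- surface_uptake(g, "CXCL12", c(0, 0, 0), rc)
  expect_equal(got, 3 * area, tolerance = 1e-3)

  # a cell outside the domain is a geometry error
  expect_error(surface_uptake(g, "CXCL12", c(2e4, 0, 0), rc), "inside")
})

test_that("point-source deposition conserves the deposited mass", {
  g <- build_domain(2, 17)
  m0 <- field_mass(g, "TGFb_c")
  g2 <- deposit_secretion(g, "TGFb_c", c(123, -456, 789), rate = 0.7,
                          dt = 3)
  expect_equal(field_mass(g2, "TGFb_c") - m0, 0.7 * 3, tolerance = 1e-12)

  # zero rate deposits nothing
  expect_identical(deposit_secretion(g, "TGFb_c", c(0, 0, 0), 0, 3), g)

  # deposit exactly at a node center lands on that node alone
  p_node_cm <- c(g$axis[9], g$axis[9], g$axis[9])
  g3 <- deposit_secretion(g, "TGFb_c", cm_to_um(p_node_cm), 1, 1)
  changed <- which(g3$fields$TGFb_c != g$fields$TGFb_c)
  expect_length(changed, 1)
})

test_that("deposition is local: a far probe is unaffected", {
  g <- build_domain(2, 17)
  probe0 <- surface_uptake(g, "TGFb_c", c(-8000, 0, 0), 8)
  g2 <- deposit_secretion(g, "TGFb_c", c(8000, 0, 0), 5, 1)
  expect_identical(surface_uptake(g2, "TGFb_c", c(-8000, 0, 0), 8),
                   probe0)
})

test_that("ECM dynamics match their closed forms", {
  g <- build_domain(2, 17, init = c(ECM = 1))

  # no MMP, no generation: unchanged
  g1 <- update_ecm(g, a1 = 0, a2 = 0.5, dt = 1)
  expect_equal(g1$fields$ECM, g$fields$ECM)

  # constant MMP, pure decay: ECM(t) = exp(-a2*M*t) within 1%
  g$fields$MMP[g$mask] <- 2
  gd <- g
  for (k in 1:100) gd <- update_ecm(gd, 0, 0.05, dt = 0.1)
  inside <- gd$fields$ECM[g$mask]
  expect_lt(max(abs(inside - exp(-0.05 * 2 * 10))) / exp(-1), 0.01)

  # no MMP, pure generation: exponential growth within 1%
  gg <- build_domain(2, 17, init = c(ECM = 1))
  for (k in 1:100) gg <- update_ecm(gg, a1 = 0.05, a2 = 0, dt = 0.1)
  inside <- gg$fields$ECM[gg$mask]
  expect_lt(max(abs(inside - exp(0.05 * 10))) / exp(0.5), 0.01)
})

test_that("field tables round-trip node values", {
  g <- build_domain(2, 11, init = c(ECM = 1, SNAIL = 0.25))
  path <- tempfile(fileext = ".tsv")
  write_fields(g, path, signals = c("ECM", "SNAIL"))
  df <- read.delim(path)
  expect_equal(nrow(df), sum(g$mask))
  expect_equal(df$SNAIL, rep(0.25, nrow(df)))
})
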