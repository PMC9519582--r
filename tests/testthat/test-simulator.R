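# small, fast configurations keep these tests light; the full-scale
# scenario is exercised by the acceptance suite
small_cfg <- function(...) {
  sim_config(n_cancer = 3, n_caf = 3, nodes_per_axis = 11, n_steps = 2,
             seed = 42, ...)
}

test_that("initialization places the configured population in the sphere", {
  cfg <- sim_config(n_cancer = 20, n_caf = 20, nodes_per_axis = 11,
                    seed = 9)
  st <- initialize_simulation(cfg)
  kinds <- vapply(st$cells, `[[`, "", "kind")
  expect_equal(sum(kinds == "cancer"), 20)
  expect_equal(sum(kinds == "caf"), 20)
  expect_true(all(vapply(st$cells, function(ci)
    sqrt(sum(ci$position^2)) < 2e4, TRUE)))
  expect_true(all(vapply(st$cells, `[[`, "", "state") == "quiescent"))

  st2 <- initialize_simulation(cfg)
  expect_equal(cell_table(st$cells), cell_table(st2$cells))
})

test_that("infinite thresholds freeze states and positions", {
  cfg <- small_cfg(thresholds = thresholds(Inf, Inf, 0))
  res <- run_simulation(cfg)
  h0 <- res$history[res$history$step == 0, ]
  hN <- res$history[res$history$step == max(res$history$step), ]
  expect_equal(nrow(hN), nrow(h0))
  expect_equal(hN[, c("x", "y", "z")], h0[, c("x", "y", "z")],
               ignore_attr = TRUE)
  expect_true(all(hN$state == "quiescent"))
})

test_that("cell count is non-decreasing and divisions add cells", {
  # proliferation-only thresholds: CXCL12 triggers, SNAIL never does
  cfg <- sim_config(n_cancer = 3, n_caf = 3, nodes_per_axis = 11,
                    n_steps = 5, seed = 3,
                    thresholds = thresholds(T_CXCL12 = 1e-4,
                                            T_SNAIL = Inf, T_ECM = 10))
  res <- run_simulation(cfg)
  counts <- tapply(res$history$id, res$history$step, length)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[length(counts)], counts[1])   # 36 h span: divisions
  expect_true(all(res$history$state[res$history$id > 6 &
    res$history$step == 5] %in%
    c("quiescent", "proliferative", "migratory")))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "runA")
  d2 <- file.path(tempdir(), "runB")
  run_simulation(cfg, out_dir = d1)
  run_simulation(cfg, out_dir = d2)
  for (f in c("cell_history.tsv", "fields_final.tsv", "manifest.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
})

test_that("resuming a run reproduces the uninterrupted run exactly", {
  cfg <- sim_config(n_cancer = 3, n_caf = 3, nodes_per_axis = 11,
                    n_steps = 4, seed = 11,
                    thresholds = thresholds(1e-4, 1e-4, 10))
  full <- run_simulation(cfg)

  cfg2 <- cfg; cfg2$n_steps <- 2
  half <- run_simulation(cfg2)
  rest <- resume_simulation(half$state, cfg, 2)

  expect_identical(cell_table(full$state$cells),
                   cell_table(rest$state$cells))
  expect_identical(full$state$grid$fields, rest$state$grid$fields)
  expect_identical(full$state$rng, rest$state$rng)
})

test_that("a saved state resumes identically to the in-memory state", {
  cfg <- small_cfg()
  half <- run_simulation(cfg)
  path <- tempfile(fileext = ".rds")
  save_simulation_state(half$state, path)
  reloaded <- load_simulation_state(path)
  a <- resume_simulation(half$state, cfg, 2)
  b <- resume_simulation(reloaded, cfg, 2)
  expect_identical(a$history, b$history)
})

test_that("mean displacement matches hand-computed trajectories", {
  # three hand-placed cancer trajectories over two steps
  mk <- function(id, t, p, d) data.frame(
    id = id, kind = "cancer", state = "migratory",
    x = p[1], y = p[2], z = p[3], radius = 8, step = t / 7.2,
    time_h = t, displacement_um = d)
  h <- rbind(
    mk(1, 0, c(0, 0, 0), 0),    mk(1, 7.2, c(30, 0, 0), 30),
    mk(2, 0, c(0, 0, 0), 0),    mk(2, 7.2, c(0, 40, 0), 40),
    mk(3, 0, c(0, 0, 0), 0),    mk(3, 7.2, c(0, 0, 0), 0))
  md <- mean_displacement(h, c(0, 3.6, 7.2))
  expect_equal(md$mean_displacement_mm,
               c(0, mean(c(15, 20, 0)) / 1000,
                 mean(c(30, 40, 0)) / 1000),
               tolerance = 1e-12)

  # a single displaced cell among N static ones contributes d/N
  h2 <- rbind(mk(1, 0, c(0, 0, 0), 0), mk(1, 7.2, c(100, 0, 0), 100),
              mk(2, 0, c(0, 0, 0), 0), mk(2, 7.2, c(0, 0, 0), 0))
  md2 <- mean_displacement(h2, 7.2)
  expect_equal(md2$mean_displacement_mm, 0.05)

  expect_error(mean_displacement(h, 100), "span")
})

test_that("cumulative displacement is non-decreasing in a migration run", {
  cfg <- migration_preset(n_cancer = 4, n_caf = 4, nodes_per_axis = 11,
                          n_steps = 4, seed = 6)
  res <- run_simulation(cfg)
  md <- mean_displacement(res$history, seq(0, 4 * 7.2, by = 7.2))
  expect_true(all(diff(md$mean_displacement_mm) >= 0))
})
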