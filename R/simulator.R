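#' Multiscale simulation loop
#'
#' Orchestration of the macro-step cycle coupling the three levels: each
#' step (1) integrates every cell's intracellular ODE network with external
#' inputs read off the fields at the cell surface, (2) deposits secreted
#' signals (and MMP) as point sources, (3) diffuses the signal and SNAIL
#' fields, (4) updates the ECM under MMP attack, (5) re-classifies every
#' cancer cell from local CXCL12/SNAIL/ECM, (6) divides eligible
#' proliferative cells, and (7) moves migratory cells by the overdamped
#' force balance. End-of-step concentrations seed the next step.
#'
#' Two clocks are kept deliberately separate: `hours_per_step` is the
#' biological time advanced per macro-step (default 7.2 h, so ten steps
#' span a 72 h experiment), while `Ts` is the fast mechanical/diffusion
#' sub-step preset retained for compatibility with second-scale stepping;
#' diffusion is automatically sub-stepped to its stability bound
#' regardless.
#'
#' @name simulator
NULL

#' Simulation configuration
#'
#' @param n_cancer,n_caf initial cell counts (defaults 20 and 20).
#' @param radius_cm domain radius (cm, default 2).
#' @param nodes_per_axis diffusion grid resolution (default 33).
#' @param n_steps number of macro-steps (default 10).
#' @param hours_per_step biological hours per macro-step (default 7.2).
#' @param Ts fast mechanical sub-step (s); kept as a preset knob.
#' @param thresholds a [thresholds()] object.
#' @param mechanics a [mechanics_params()] object.
#' @param diffusion named list of [diffusion_spec()] per diffusing field;
#'   unnamed fields use the default spec.
#' @param ecm_a1,ecm_a2 ECM generation (1/h) and degradation
#'   (1/(a.u. h)) coefficients.
#' @param secretion_rate named vector: deposition rate constant (1/h) per
#'   secreted field; the point-source rate is this constant times the
#'   cell's intracellular level of the mapped species.
#' @param uptake_efficiency fraction of the surface-integrated signal
#'   removed from the field per step (cell-mediated uptake sink).
#' @param field_init named initial constant per field.
#' @param input_scale multiplier from mean surface concentration to
#'   intracellular external-input units.
#' @param division_period_h hours between divisions of a proliferative
#'   cell (default 24).
#' @param active_direction `"outward"` (from the population centroid,
#'   default), `"down_ecm"`, or `"random"` -- the active-force direction
#'   rule.
#' @param seed integer seed recorded in every output.
#' @return object of class `SimulationConfig`.
#' @export
sim_config <- function(n_cancer = 20, n_caf = 20, radius_cm = 2,
                       nodes_per_axis = 33, n_steps = 10,
                       hours_per_step = 7.2, Ts = 0.05,
                       thresholds = stromasim::thresholds(),
                       mechanics = mechanics_params(),
                       diffusion = list(),
                       ecm_a1 = 0, ecm_a2 = 0.02,
                       secretion_rate = c(TGFb_c = 0.1, LIF_c = 0.1,
                                          TGFb_f = 0.1, CXCL12 = 0.1,
                                          SNAIL = 0.1, MMP = 0.1),
                       uptake_efficiency = 1,
                       field_init = c(ECM = 1),
                       input_scale = 1,
                       division_period_h = 24,
                       active_direction = c("outward", "down_ecm",
                                            "random"),
                       seed = 1) {
  active_direction <- match.arg(active_direction)
  stopifnot(n_cancer >= 0, n_caf >= 0, n_steps >= 0, hours_per_step > 0)
  base_diff <- diffusion_spec()
  all_fields <- setdiff(default_field_names(), "ECM")
  dspec <- stats::setNames(
    lapply(all_fields, function(f)
      if (!is.null(diffusion[[f]])) diffusion[[f]] else base_diff),
    all_fields)
  structure(list(n_cancer = n_cancer, n_caf = n_caf, radius_cm = radius_cm,
                 nodes_per_axis = nodes_per_axis, n_steps = n_steps,
                 hours_per_step = hours_per_step, Ts = Ts,
                 thresholds = thresholds, mechanics = mechanics,
                 diffusion = dspec, ecm_a1 = ecm_a1, ecm_a2 = ecm_a2,
                 secretion_rate = secretion_rate,
                 uptake_efficiency = uptake_efficiency,
                 field_init = field_init, input_scale = input_scale,
                 division_period_h = division_period_h,
                 active_direction = active_direction, seed = seed),
            class = "SimulationConfig")
}

# which intracellular species feeds each secreted field, per cell kind
secretion_map <- function(kind) {
  if (kind == "cancer")
    c(TGFb_c = "xu1", LIF_c = "xu2", MMP = "x19")
  else
    c(TGFb_f = "xu3", CXCL12 = "xu4", SNAIL = "x22")
}

# which field feeds each external input, per cell kind
input_map <- function(kind) {
  if (kind == "cancer") c(xu3 = "TGFb_f", xu4 = "CXCL12")
  else c(xu1 = "TGFb_c", xu2 = "LIF_c")
}

#' Initialize a simulation
#'
#' Places the cells uniformly at random in the sphere (rejection sampling,
#' no two cells overlapping by more than half their summed radii), sets
#' every cancer cell quiescent, and fills the fields with their configured
#' initial constants.
#'
#' @param config a [sim_config()].
#' @return object of class `SimulationState` with elements `cells`,
#'   `grid`, `step`, `time_h`, `rng` (the captured random-stream state),
#'   and the cell models.
#' @export
initialize_simulation <- function(config) {
  set.seed(config$seed)
  cancer_spec <- build_cancer_cell_network()
  caf_spec <- build_caf_network()
  cancer_spec$rhs <- assemble_rhs(cancer_spec$network)
  caf_spec$rhs <- assemble_rhs(caf_spec$network)
  layout <- make_fixture_tumor(config$n_cancer, config$n_caf,
                               config$radius_cm, seed = config$seed)
  cells <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    kind <- layout$kind[i]
    spec <- if (kind == "cancer") cancer_spec else caf_spec
    cells[[i]] <- cell_agent(layout$id[i], kind,
                             c(layout$x[i], layout$y[i], layout$z[i]),
                             intracellular = initial_state(spec$network),
                             radius = layout$radius[i])
  }
  grid <- build_domain(config$radius_cm, config$nodes_per_axis,
                       init = config$field_init)
  structure(list(cells = cells, grid = grid, step = 0L, time_h = 0,
                 rng = .Random.seed,
                 models = list(cancer = cancer_spec, caf = caf_spec)),
            class = "SimulationState")
}

#' @export
print.SimulationState <- function(x, ...) {
  tab <- table(vapply(x$cells, `[[`, "", "kind"))
  st <- table(vapply(x$cells, `[[`, "", "state"))
  cat(sprintf("<SimulationState> step %d (t = %g h): %s; states: %s\n",
              x$step, x$time_h,
              paste(names(tab), tab, sep = "=", collapse = ", "),
              paste(names(st), st, sep = "=", collapse = ", ")))
  invisible(x)
}

# integrate one cell's intracellular network over dt with fixed inputs;
# the assembled rhs is cached on the spec by initialize_simulation
advance_intracellular <- function(spec, x, inputs, dt) {
  rhs <- if (!is.null(spec$rhs)) spec$rhs else assemble_rhs(spec$network)
  out <- deSolve::lsoda(y = x, times = c(0, dt),
                        func = function(t, y, p) list(rhs(t, y, inputs)),
                        parms = NULL, rtol = 1e-6, atol = 1e-8)
  if (nrow(out) < 2 || any(!is.finite(out)))
    stop("intracellular integration failed", call. = FALSE)
  xn <- out[2, -1]
  xn[xn < 0] <- 0
  xn
}

#' Advance the simulation by one macro-step
#'
#' @param state a [initialize_simulation()] state.
#' @param config the matching [sim_config()].
#' @return the updated state (the input state is left untouched if any
#'   sub-stage fails).
#' @export
sim_step <- function(state, config) {
  assign(".Random.seed", state$rng, envir = globalenv())
  dt <- config$hours_per_step
  cells <- state$cells
  grid <- state$grid
  models <- state$models

  # (1) intracellular dynamics with surface-level external inputs
  for (i in seq_along(cells)) {
    ci <- cells[[i]]
    spec <- models[[ci$kind]]
    im <- input_map(ci$kind)
    inputs <- vapply(im, function(f)
      config$input_scale *
        surface_mean(grid, f, ci$position, ci$radius), 0)
    names(inputs) <- names(im)
    cells[[i]]$intracellular <-
      advance_intracellular(spec, ci$intracellular, inputs, dt)
    # cell-mediated uptake sink on the fields
    if (config$uptake_efficiency > 0) {
      for (f in im) {
        amt <- config$uptake_efficiency *
          surface_uptake(grid, f, ci$position, ci$radius)
        grid <- remove_uptake(grid, f, ci$position, amt)
      }
    }
  }

  # (2) secretion deposits
  for (i in seq_along(cells)) {
    ci <- cells[[i]]
    sm <- secretion_map(ci$kind)
    for (f in names(sm)) {
      rate <- config$secretion_rate[[f]] * ci$intracellular[[sm[[f]]]]
      if (rate > 0)
        grid <- deposit_secretion(grid, f, ci$position, rate, dt)
    }
  }

  # (3) diffusion of every signal field (SNAIL included)
  for (f in names(config$diffusion))
    grid <- diffuse(grid, f, config$diffusion[[f]], dt)

  # (4) ECM dynamics, sub-stepped for accuracy
  nsub <- max(1L, ceiling(dt / 0.5))
  for (k in seq_len(nsub))
    grid <- update_ecm(grid, config$ecm_a1, config$ecm_a2, dt / nsub)

  # (5) classification of cancer cells
  for (i in seq_along(cells)) {
    ci <- cells[[i]]
    if (ci$kind != "cancer") next
    u_c <- surface_mean(grid, "CXCL12", ci$position, ci$radius)
    u_s <- surface_mean(grid, "SNAIL", ci$position, ci$radius)
    ecm_l <- field_at(grid, "ECM", ci$position)
    cells[[i]]$state <- classify_state(ci, u_c, u_s, ecm_l,
                                       config$thresholds)
  }

  # (6) division of eligible proliferative cells
  t_next <- state$time_h + dt
  next_id <- max(vapply(cells, `[[`, 0, "id")) + 1
  daughters <- list()
  for (i in seq_along(cells)) {
    ci <- cells[[i]]
    if (ci$kind == "cancer" && ci$state == "proliferative" &&
        t_next - ci$last_division_h >= config$division_period_h) {
      dv <- divide(ci, next_id, birth_step = state$step + 1L,
                   time_h = t_next)
      cells[[i]] <- dv$mother
      daughters[[length(daughters) + 1]] <- dv$daughter
      next_id <- next_id + 1
    }
  }
  cells <- c(cells, daughters)

  # (7) forces and motion of migratory cells
  anyone_moves <- any(vapply(cells, function(ci)
    ci$kind == "cancer" && ci$state == "migratory", TRUE))
  if (anyone_moves) {
    F <- population_pairwise_forces(cells, config$mechanics)
    centroid <- colMeans(do.call(rbind, lapply(cells, `[[`, "position")))
    for (i in seq_along(cells)) {
      ci <- cells[[i]]
      if (!(ci$kind == "cancer" && ci$state == "migratory")) next
      u_s <- surface_mean(grid, "SNAIL", ci$position, ci$radius)
      g <- field_gradient(grid, "ECM", ci$position)
      dirv <- switch(config$active_direction,
        outward = {
          v <- ci$position - centroid
          if (sum(v^2) == 0) c(1, 0, 0) else v / sqrt(sum(v^2))
        },
        down_ecm = {
          if (sum(g^2) == 0) c(1, 0, 0) else -g / sqrt(sum(g^2))
        },
        random = {
          v <- stats::rnorm(3); v / sqrt(sum(v^2))
        })
      F[i, ] <- F[i, ] + environment_force(ci, g, u_s, dirv,
                                           config$mechanics)
    }
    cells <- advance_cells(cells, F, config$mechanics$gamma_cs, dt)
    # keep every cell (and its surface quadrature) inside the domain
    R_um <- cm_to_um(config$radius_cm)
    for (i in seq_along(cells)) {
      ci <- cells[[i]]
      rmax <- R_um - 2 * ci$radius
      nrm <- sqrt(sum(ci$position^2))
      if (nrm > rmax) cells[[i]]$position <- ci$position * rmax / nrm
    }
  }

  state$cells <- cells
  state$grid <- grid
  state$step <- state$step + 1L
  state$time_h <- t_next
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

# snapshot of the population with per-cell displacement from origin
history_row <- function(state) {
  tab <- cell_table(state$cells)
  tab$step <- state$step
  tab$time_h <- state$time_h
  tab$displacement_um <- vapply(state$cells, function(ci)
    sqrt(sum((ci$position - ci$origin)^2)), 0)
  tab
}

#' Run a simulation
#'
#' Executes [initialize_simulation()] plus `n_steps` macro-steps,
#' recording a per-step cell table (with per-cell displacement), and
#' optionally writing per-step tables, field dumps and a manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @param keep_state return the final `SimulationState` (default TRUE).
#' @return list with `history` (row-bound per-step cell tables including
#'   the initial state), `state`, and `config`.
#' @export
run_simulation <- function(config, out_dir = NULL, keep_state = TRUE) {
  state <- initialize_simulation(config)
  history <- list(history_row(state))
  for (k in seq_len(config$n_steps)) {
    state <- sim_step(state, config)
    history[[k + 1]] <- history_row(state)
  }
  history <- do.call(rbind, history)
  res <- list(history = history,
              state = if (keep_state) state else NULL,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(history, file.path(out_dir, "cell_history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fields(state$grid, file.path(out_dir, "fields_final.tsv"))
    manifest <- list(seed = config$seed, n_steps = config$n_steps,
                     hours_per_step = config$hours_per_step,
                     n_cancer = config$n_cancer, n_caf = config$n_caf,
                     radius_cm = config$radius_cm,
                     nodes_per_axis = config$nodes_per_axis,
                     package_version =
                       as.character(utils::packageVersion("stromasim")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Resume a simulation
#'
#' Continues a saved state for additional macro-steps; with the same
#' config this reproduces an uninterrupted run exactly (the random-stream
#' state is carried inside the `SimulationState`).
#'
#' @param state a `SimulationState`.
#' @param config the matching [sim_config()].
#' @param n_more number of additional macro-steps.
#' @return list as in [run_simulation()] (history covers only the resumed
#'   steps plus the entry state).
#' @export
resume_simulation <- function(state, config, n_more) {
  history <- list(history_row(state))
  for (k in seq_len(n_more)) {
    state <- sim_step(state, config)
    history[[k + 1]] <- history_row(state)
  }
  list(history = do.call(rbind, history), state = state, config = config)
}

#' Mean cancer-cell displacement over time
#'
#' Mean over cancer cells of the straight-line displacement from each
#' cell's initial (birth) position, reported in millimeters; per-cell
#' displacement is linearly interpolated between recorded steps.
#'
#' @param history the `history` data.frame of [run_simulation()].
#' @param sample_hours times (h) at which to report; must lie within the
#'   recorded span.
#' @return data.frame with columns `time_h` and `mean_displacement_mm`.
#' @export
mean_displacement <- function(history, sample_hours) {
  times <- sort(unique(history$time_h))
  if (min(sample_hours) < min(times) || max(sample_hours) > max(times))
    stop("sample_hours outside the recorded span", call. = FALSE)
  out <- vapply(sample_hours, function(tt) {
    # per-cell interpolated displacement at tt, mean over cancer cells
    h <- history[history$kind == "cancer", ]
    ids <- unique(h$id)
    d <- vapply(ids, function(i) {
      hi <- h[h$id == i, ]
      if (nrow(hi) == 1) return(if (hi$time_h <= tt) hi$displacement_um
                                else NA_real_)
      if (tt < min(hi$time_h)) return(NA_real_)  # born later
      stats::approx(hi$time_h, hi$displacement_um, xout = tt,
                    rule = 2)$y
    }, 0)
    mean(d, na.rm = TRUE)
  }, 0)
  data.frame(time_h = sample_hours, mean_displacement_mm = out / 1000)
}

#' Save / load a simulation state
#'
#' Serializes the complete `SimulationState` (cells, fields, step counter
#' and random-stream state) so a run can be resumed later; resuming a
#' reloaded state reproduces the uninterrupted run exactly.
#'
#' @param state a `SimulationState`.
#' @param path file path (RDS).
#' @export
save_simulation_state <- function(state, path) {
  stopifnot(inherits(state, "SimulationState"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_simulation_state
#' @return `load_simulation_state()`: the restored `SimulationState`.
#' @export
load_simulation_state <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "SimulationState"))
  state
}

#' Migration-enabling configuration preset
#'
#' A [sim_config()] whose thresholds are low enough, relative to what the
#' default cell models secrete, that cancer cells near CAFs switch to the
#' proliferative and migratory states within a 72 h run -- the setting used
#' to study the displacement trend.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `SimulationConfig`.
#' @export
migration_preset <- function(...) {
  sim_config(thresholds = thresholds(T_CXCL12 = 1e-4, T_SNAIL = 1e-4,
                                     T_ECM = 10),
             ...)
}
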