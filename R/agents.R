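#' Cell agents: behavioral states and force-based mechanics
#'
#' Cancer cells and CAFs are spheres (radii 8 and 7 micrometer) whose
#' centers carry the forces. Each cancer cell is classified every
#' macro-step as quiescent, proliferative or migratory from the local
#' CXCL12, SNAIL and ECM levels; migratory cells move by an overdamped
#' force balance (Hertz repulsion, constant adhesion, haptotaxis down the
#' ECM gradient as printed, and a SNAIL-driven active force), proliferative
#' cells divide on a timer. CAFs are static: they neither move nor change
#' state.
#'
#' @name agents
NULL

#' Create a cell agent
#'
#' @param id unique identifier.
#' @param kind `"cancer"` or `"caf"`.
#' @param position length-3 position (micrometer).
#' @param intracellular named state vector of the cell's intracellular
#'   model.
#' @param radius sphere radius (micrometer); defaults 8 (cancer), 7 (CAF).
#' @param state behavioral state (cancer only; CAFs are always
#'   `"quiescent"`).
#' @param birth_step macro-step at which the cell appeared.
#' @return object of class `CellAgent`.
#' @export
cell_agent <- function(id, kind = c("cancer", "caf"), position,
                       intracellular = numeric(0),
                       radius = if (kind == "cancer") 8 else 7,
                       state = "quiescent", birth_step = 0L) {
  kind <- match.arg(kind)
  stopifnot(length(position) == 3, radius > 0,
            state %in% c("quiescent", "proliferative", "migratory"))
  structure(list(id = id, kind = kind, position = as.numeric(position),
                 radius = radius, state = state,
                 intracellular = intracellular,
                 birth_step = as.integer(birth_step),
                 origin = as.numeric(position),
                 last_division_h = 0),
            class = "CellAgent")
}

#' Behavioral thresholds
#'
#' Signal levels (mean surface concentration, a.u.) against which each
#' cancer cell's local CXCL12, SNAIL and ECM readings are compared.
#'
#' @param T_CXCL12 proliferation threshold on CXCL12.
#' @param T_SNAIL migration threshold on SNAIL.
#' @param T_ECM maximum local ECM compatible with detachment.
#' @return object of class `Thresholds`.
#' @export
thresholds <- function(T_CXCL12 = 0.05, T_SNAIL = 0.05, T_ECM = 1.5) {
  stopifnot(T_CXCL12 >= 0, T_SNAIL >= 0, T_ECM >= 0)
  structure(list(T_CXCL12 = T_CXCL12, T_SNAIL = T_SNAIL, T_ECM = T_ECM),
            class = "Thresholds")
}

#' Mechanical parameters of the force catalog
#'
#' @param E_hat effective pair modulus for Hertz repulsion (force /
#'   micrometer^2 in friction-normalized units).
#' @param W adhesion energy density; adhesion magnitude is `pi * W * Rhat`.
#' @param chi haptotaxis coefficient (force per a.u./micrometer); positive
#'   values move cells down the ECM gradient, as the force law is printed.
#' @param eta active-force scale (saturating in SNAIL).
#' @param A0 active-force half-saturation (a.u. of surface SNAIL).
#' @param n_hill Hill exponent of the active force (>= 1).
#' @param gamma_cs cell-substrate friction coefficient (> 0); velocities
#'   are force / gamma_cs, in micrometer/h.
#' @param adhesion_range gap beyond contact (micrometer) within which
#'   adhesion acts.
#' @return object of class `MechanicsParams`.
#' @export
mechanics_params <- function(E_hat = 1, W = 0.02, chi = 1, eta = 10,
                             A0 = 0.05, n_hill = 2, gamma_cs = 1,
                             adhesion_range = 2) {
  stopifnot(gamma_cs > 0, n_hill >= 1, adhesion_range >= 0)
  structure(list(E_hat = E_hat, W = W, chi = chi, eta = eta, A0 = A0,
                 n_hill = n_hill, gamma_cs = gamma_cs,
                 adhesion_range = adhesion_range),
            class = "MechanicsParams")
}

#' Classify a cancer cell's behavioral state
#'
#' Decision precedence: migratory (SNAIL at or above its threshold and
#' local ECM degraded to at or below its threshold) is checked first, then
#' proliferative (CXCL12 at or above threshold), else quiescent.
#'
#' @param cell a [cell_agent()] of kind `"cancer"`.
#' @param u_CXCL12,u_SNAIL mean surface signal levels (a.u., >= 0).
#' @param ecm_local local ECM concentration (a.u., >= 0).
#' @param thr a [thresholds()] object.
#' @return one of `"quiescent"`, `"proliferative"`, `"migratory"`.
#' @export
classify_state <- function(cell, u_CXCL12, u_SNAIL, ecm_local, thr) {
  if (cell$kind != "cancer")
    stop("classify_state applies to cancer cells only", call. = FALSE)
  stopifnot(u_CXCL12 >= 0, u_SNAIL >= 0, ecm_local >= 0)
  if (u_SNAIL >= thr$T_SNAIL && ecm_local <= thr$T_ECM) return("migratory")
  if (u_CXCL12 >= thr$T_CXCL12) return("proliferative")
  "quiescent"
}

#' Pairwise cell-cell force
#'
#' Hertz repulsion `(4/3) * E_hat * sqrt(Rhat) * delta^(3/2)` for overlap
#' `delta = Ri + Rj - |ri - rj| > 0` and constant-magnitude adhesion
#' `pi * W * Rhat` for `-adhesion_range < delta <= adhesion_range`, both
#' along the center line; `Rhat = Ri*Rj/(Ri+Rj)`. The force on the partner
#' is the exact negative.
#'
#' @param ci,cj distinct [cell_agent()]s.
#' @param mech a [mechanics_params()].
#' @return length-3 force on `ci`.
#' @export
pairwise_force <- function(ci, cj, mech) {
  d <- ci$position - cj$position
  dist <- sqrt(sum(d^2))
  if (dist == 0) {
    warning("coincident cell centers; repelling along a random direction")
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    delta <- ci$radius + cj$radius
    Rhat <- ci$radius * cj$radius / (ci$radius + cj$radius)
    return((4 / 3) * mech$E_hat * sqrt(Rhat) * delta^1.5 * u)
  }
  u <- d / dist
  delta <- ci$radius + cj$radius - dist
  Rhat <- ci$radius * cj$radius / (ci$radius + cj$radius)
  f <- 0
  if (delta > 0)
    f <- f + (4 / 3) * mech$E_hat * sqrt(Rhat) * delta^1.5
  if (delta > -mech$adhesion_range && delta <= mech$adhesion_range)
    f <- f - pi * mech$W * Rhat
  f * u
}

#' Environmental force on a cell
#'
#' Haptotaxis `-chi * grad(ECM)` plus the SNAIL-driven active force
#' `eta * A^n / (A^n + A0^n) * nhat`.
#'
#' @param cell a [cell_agent()].
#' @param ecm_grad local ECM gradient (a.u./micrometer, length-3).
#' @param u_SNAIL mean surface SNAIL level (the Hill input A).
#' @param direction unit direction of active motion.
#' @param mech a [mechanics_params()].
#' @return length-3 force.
#' @export
environment_force <- function(cell, ecm_grad, u_SNAIL, direction, mech) {
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-8) {
    warning("active-force direction is not a unit vector; normalizing")
    if (nrm == 0) stop("zero active-force direction", call. = FALSE)
    direction <- direction / nrm
  }
  A <- u_SNAIL
  hill <- if (A <= 0) 0 else
    A^mech$n_hill / (A^mech$n_hill + mech$A0^mech$n_hill)
  -mech$chi * ecm_grad + mech$eta * hill * direction
}

#' Sum of pairwise forces over a population
#'
#' @param cells list of [cell_agent()]s.
#' @param mech a [mechanics_params()].
#' @return n x 3 matrix of net pairwise forces (row i = force on cell i);
#'   rows sum to zero by symmetry.
#' @export
population_pairwise_forces <- function(cells, mech) {
  n <- length(cells)
  F <- matrix(0, n, 3)
  if (n < 2) return(F)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      f <- pairwise_force(cells[[i]], cells[[j]], mech)
      F[i, ] <- F[i, ] + f
      F[j, ] <- F[j, ] - f
    }
  }
  F
}

#' Advance cells by the overdamped motion law
#'
#' `V = F / gamma_cs`; only migratory cancer cells move
#' (`position <- position + V * dt`); quiescent and proliferative cells and
#' CAFs are unmoved.
#'
#' @param cells list of [cell_agent()]s.
#' @param net_forces n x 3 matrix of net forces.
#' @param gamma_cs friction coefficient (> 0).
#' @param dt time step (h).
#' @return updated list of cells.
#' @export
advance_cells <- function(cells, net_forces, gamma_cs, dt) {
  if (gamma_cs <= 0) stop("gamma_cs must be > 0", call. = FALSE)
  stopifnot(dt > 0, nrow(net_forces) == length(cells))
  for (i in seq_along(cells)) {
    c_i <- cells[[i]]
    if (c_i$kind == "cancer" && c_i$state == "migratory") {
      c_i$position <- c_i$position + net_forces[i, ] / gamma_cs * dt
      cells[[i]] <- c_i
    }
  }
  cells
}

#' Divide a proliferative cell
#'
#' The daughter is placed at one mother radius in a uniformly random
#' direction, inherits a copy of the intracellular state, and starts
#' quiescent.
#'
#' @param cell a proliferative cancer [cell_agent()].
#' @param new_id identifier for the daughter.
#' @param birth_step macro-step of the division.
#' @param time_h simulation time of the division (resets the mother's
#'   division timer).
#' @return list with elements `mother` and `daughter`.
#' @export
divide <- function(cell, new_id, birth_step = 0L, time_h = 0) {
  stopifnot(cell$state == "proliferative")
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2))
  daughter <- cell_agent(new_id, cell$kind,
                         cell$position + cell$radius * u,
                         intracellular = cell$intracellular,
                         radius = cell$radius,
                         state = "quiescent", birth_step = birth_step)
  daughter$last_division_h <- time_h
  cell$last_division_h <- time_h
  list(mother = cell, daughter = daughter)
}

#' Cell table of a population
#'
#' @param cells list of [cell_agent()]s.
#' @return data.frame with columns `id`, `kind`, `state`, `x`, `y`, `z`
#'   (micrometer), `radius`.
#' @export
cell_table <- function(cells) {
  do.call(rbind, lapply(cells, function(ci)
    data.frame(id = ci$id, kind = ci$kind, state = ci$state,
               x = ci$position[1], y = ci$position[2], z = ci$position[3],
               radius = ci$radius, stringsAsFactors = FALSE)))
}
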