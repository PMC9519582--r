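#' Spherical tumor microenvironment: diffusing fields and ECM
#'
#' The microenvironment is a sphere (default radius 2 cm) discretized on a
#' regular Cartesian grid with a sphere mask. Each secreted signal
#' (cancer-derived TGF-beta and LIF, CAF-derived TGF-beta and CXCL12,
#' SNAIL, MMP) and the ECM live as nodal concentration fields. Diffusion
#' uses explicit finite differences with an absorbing (Dirichlet) far
#' field held on the first layer of nodes outside the sphere; cells couple
#' to the fields by surface-integral uptake and trilinear point-source
#' deposition.
#'
#' Length units: the grid is in cm; cell positions and radii are in
#' micrometers and converted internally ([um_to_cm()]).
#'
#' @name spatial
NULL

#' Micrometer/centimeter conversion
#' @param um,cm values to convert.
#' @return converted value.
#' @export
um_to_cm <- function(um) um * 1e-4

#' @rdname um_to_cm
#' @export
cm_to_um <- function(cm) cm * 1e4

#' Default field names carried by the domain
#' @return character vector.
#' @export
default_field_names <- function()
  c("TGFb_c", "LIF_c", "TGFb_f", "CXCL12", "SNAIL", "ECM", "MMP")

#' Per-signal diffusion specification
#'
#' @param D diffusion coefficient (cm^2/h); the default 3.6e-3 cm^2/h
#'   (1e-6 cm^2/s) is an order-of-magnitude placeholder typical of small
#'   secreted proteins in tissue.
#' @param dirichlet_value far-field (boundary) concentration, default 0.
#' @param decay first-order sink rate (1/h).
#' @return object of class `DiffusionSpec`.
#' @export
diffusion_spec <- function(D = 3.6e-3, dirichlet_value = 0, decay = 0) {
  stopifnot(D >= 0, decay >= 0, dirichlet_value >= 0)
  structure(list(D = D, dirichlet_value = dirichlet_value, decay = decay),
            class = "DiffusionSpec")
}

# 6-neighbor sum by array shifting; edge replication is harmless because
# the outermost layer is always outside the sphere
neighbor_sum <- function(u) {
  n <- dim(u)[1]
  sh <- function(d, ax) {
    idx <- list(seq_len(n), seq_len(n), seq_len(n))
    idx[[ax]] <- pmin(pmax(seq_len(n) + d, 1L), n)
    u[idx[[1]], idx[[2]], idx[[3]]]
  }
  sh(1L, 1L) + sh(-1L, 1L) + sh(1L, 2L) + sh(-1L, 2L) +
    sh(1L, 3L) + sh(-1L, 3L)
}

shift_any <- function(m) {
  n <- dim(m)[1]
  sh <- function(d, ax) {
    idx <- list(seq_len(n), seq_len(n), seq_len(n))
    idx[[ax]] <- pmin(pmax(seq_len(n) + d, 1L), n)
    m[idx[[1]], idx[[2]], idx[[3]]]
  }
  sh(1L, 1L) | sh(-1L, 1L) | sh(1L, 2L) | sh(-1L, 2L) |
    sh(1L, 3L) | sh(-1L, 3L)
}

#' Build the discretized spherical domain
#'
#' @param radius domain radius in cm (default 2).
#' @param nodes_per_axis odd integer >= 9 (so a center node exists).
#' @param field_names fields to allocate.
#' @param init named vector of initial constant values per field (inside
#'   the sphere); unnamed fields start at 0.
#' @return object of class `FieldGrid`: axis coordinates, spacing, `mask`
#'   (inside-sphere indicator), `boundary` (first layer of outside nodes
#'   adjacent to the inside, which holds the Dirichlet value), and one 3-D
#'   nodal array per field.
#' @export
build_domain <- function(radius = 2, nodes_per_axis = 33,
                         field_names = default_field_names(),
                         init = c(ECM = 1)) {
  if (nodes_per_axis < 9 || nodes_per_axis %% 2 == 0)
    stop("nodes_per_axis must be an odd integer >= 9", call. = FALSE)
  ax <- seq(-radius, radius, length.out = nodes_per_axis)
  h <- ax[2] - ax[1]
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  mask <- array(sqrt(r2) < radius, dim = rep(nodes_per_axis, 3))
  boundary <- !mask & shift_any(mask)
  fields <- lapply(field_names, function(f) {
    u <- array(0, dim = dim(mask))
    v <- if (f %in% names(init)) init[[f]] else 0
    u[mask] <- v
    u
  })
  names(fields) <- field_names
  structure(list(radius = radius, n = nodes_per_axis, axis = ax,
                 spacing = h, mask = mask, boundary = boundary,
                 fields = fields),
            class = "FieldGrid")
}

#' @export
print.FieldGrid <- function(x, ...) {
  cat(sprintf("<FieldGrid> R = %g cm, %d^3 nodes (h = %.4g cm), %d inside; fields: %s\n",
              x$radius, x$n, x$spacing, sum(x$mask),
              paste(names(x$fields), collapse = ", ")))
  invisible(x)
}

#' Total mass of a field
#' @param grid a [build_domain()] grid.
#' @param signal field name.
#' @return sum of nodal values times the node volume (a.u. * cm^3).
#' @export
field_mass <- function(grid, signal)
  sum(grid$fields[[signal]]) * grid$spacing^3

#' One explicit diffusion step of a signal field
#'
#' Forward-Euler step of the reaction-diffusion equation
#' `du/dt = D * Laplacian(u) - decay * u` on the inside nodes, with the
#' Dirichlet value re-imposed outside the sphere. The explicit stability
#' bound `D*dt/h^2 <= 1/6` is enforced.
#'
#' @param grid a [build_domain()] grid.
#' @param signal field name.
#' @param spec a [diffusion_spec()].
#' @param dt time step (h).
#' @return the updated grid.
#' @export
step_diffusion <- function(grid, signal, spec, dt) {
  h <- grid$spacing
  if (spec$D * dt / h^2 > 1 / 6 + 1e-12)
    stop(sprintf("explicit diffusion step unstable: D*dt/h^2 = %.3g > 1/6; use %d sub-steps",
                 spec$D * dt / h^2,
                 ceiling(6 * spec$D * dt / h^2)), call. = FALSE)
  u <- grid$fields[[signal]]
  if (spec$D > 0 || spec$decay > 0) {
    lap <- (neighbor_sum(u) - 6 * u) / h^2
    un <- u + dt * (spec$D * lap - spec$decay * u)
    un[!grid$mask] <- spec$dirichlet_value
    un[un < 0] <- 0
    grid$fields[[signal]] <- un
  }
  grid
}

#' Diffuse a signal over an interval with automatic sub-stepping
#'
#' @inheritParams step_diffusion
#' @param dt_total interval length (h); split into the smallest number of
#'   equal sub-steps satisfying the stability bound.
#' @export
diffuse <- function(grid, signal, spec, dt_total) {
  if (dt_total <= 0) return(grid)
  h <- grid$spacing
  nsub <- max(1L, ceiling(6 * spec$D * dt_total / h^2 / 0.9))
  dt <- dt_total / nsub
  for (i in seq_len(nsub)) grid <- step_diffusion(grid, signal, spec, dt)
  grid
}

# trilinear interpolation cell and weights for a point given in cm
trilinear_weights <- function(grid, p_cm) {
  n <- grid$n; h <- grid$spacing
  f <- (p_cm - grid$axis[1]) / h
  i0 <- pmin(pmax(floor(f), 0), n - 2) # zero-based lower corner
  t <- f - i0
  i0 <- as.integer(i0)
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  w <- apply(corners, 1, function(cc)
    prod(ifelse(cc == 1, t, 1 - t)))
  idx <- sweep(corners, 2, i0 + 1L, `+`)   # 1-based node indices
  list(idx = idx, w = w)
}

# interpolated field value at a point (cm)
interp_field <- function(grid, signal, p_cm) {
  tw <- trilinear_weights(grid, p_cm)
  u <- grid$fields[[signal]]
  sum(tw$w * u[tw$idx])
}

#' Local field value at a cell center
#'
#' @param grid a [build_domain()] grid.
#' @param signal field name.
#' @param center_um cell center (micrometer, length-3).
#' @return trilinearly interpolated nodal value (a.u.).
#' @export
field_at <- function(grid, signal, center_um)
  interp_field(grid, signal, um_to_cm(center_um))

#' Field gradient at a cell center
#'
#' Central finite difference of the trilinear interpolant with step h/2.
#'
#' @inheritParams field_at
#' @return length-3 gradient in a.u. per micrometer.
#' @export
field_gradient <- function(grid, signal, center_um) {
  p <- um_to_cm(center_um)
  d <- grid$spacing / 2
  g_cm <- vapply(1:3, function(ax) {
    e <- c(0, 0, 0); e[ax] <- d
    (interp_field(grid, signal, p + e) -
       interp_field(grid, signal, p - e)) / (2 * d)
  }, 0)
  g_cm * 1e-4   # a.u./cm -> a.u./um
}

# 26 symmetric quadrature directions (face, edge, corner neighbors)
quad_directions <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  g / sqrt(rowSums(g^2))
}

#' Surface-integrated signal on a cell
#'
#' Approximates the integral of the field over the cell's spherical surface
#' with a 26-point symmetric quadrature (equal weights summing to the
#' surface area). A uniform field c integrates to `c * 4*pi*R^2`; linear
#' variation cancels by symmetry.
#'
#' @param grid a [build_domain()] grid.
#' @param signal field name.
#' @param center_um cell center (micrometer).
#' @param cell_radius_um cell radius (micrometer).
#' @return surface integral (a.u. * cm^2).
#' @export
surface_uptake <- function(grid, signal, center_um, cell_radius_um) {
  p <- um_to_cm(center_um)
  rc <- um_to_cm(cell_radius_um)
  if (sqrt(sum(p^2)) + rc >= grid$radius)
    stop("cell is not entirely inside the domain", call. = FALSE)
  dirs <- quad_directions()
  area <- 4 * pi * rc^2
  vals <- apply(dirs, 1, function(d) interp_field(grid, signal, p + rc * d))
  mean(vals) * area
}

#' Mean signal concentration on a cell surface
#'
#' [surface_uptake()] divided by the cell surface area: the quantity
#' compared against the behavioral thresholds and fed to the intracellular
#' models as external input.
#'
#' @inheritParams surface_uptake
#' @return mean surface concentration (a.u.).
#' @export
surface_mean <- function(grid, signal, center_um, cell_radius_um)
  surface_uptake(grid, signal, center_um, cell_radius_um) /
    (4 * pi * um_to_cm(cell_radius_um)^2)

#' Deposit a secreted amount as a point source
#'
#' Distributes `rate * dt` over the 8 nodes surrounding the cell center by
#' trilinear weights (divided by the node volume, so total field mass
#' increases by exactly `rate * dt`).
#'
#' @param grid a [build_domain()] grid.
#' @param signal field name.
#' @param center_um cell center (micrometer).
#' @param rate secretion rate (a.u./h).
#' @param dt interval (h).
#' @return the updated grid.
#' @export
deposit_secretion <- function(grid, signal, center_um, rate, dt) {
  if (rate == 0 || dt == 0) return(grid)
  p <- um_to_cm(center_um)
  if (sqrt(sum(p^2)) >= grid$radius)
    stop("cell is not inside the domain", call. = FALSE)
  tw <- trilinear_weights(grid, p)
  u <- grid$fields[[signal]]
  u[tw$idx] <- u[tw$idx] + tw$w * rate * dt / grid$spacing^3
  grid$fields[[signal]] <- u
  grid
}

#' Remove an uptaken amount from the field around a cell
#'
#' Mirrors [deposit_secretion()] with a negative amount, floored so nodal
#' values stay nonnegative.
#'
#' @inheritParams deposit_secretion
#' @param amount total amount to remove (a.u. * cm^3).
#' @export
remove_uptake <- function(grid, signal, center_um, amount) {
  if (amount <= 0) return(grid)
  p <- um_to_cm(center_um)
  tw <- trilinear_weights(grid, p)
  u <- grid$fields[[signal]]
  u[tw$idx] <- pmax(u[tw$idx] - tw$w * amount / grid$spacing^3, 0)
  grid$fields[[signal]] <- u
  grid
}

#' ECM generation/degradation step
#'
#' Per-node forward-Euler step of
#' `d[ECM]/dt = a1*[ECM] - a2*[MMP]*[ECM]` floored at zero.
#'
#' @param grid a [build_domain()] grid (must carry `ECM` and `MMP` fields).
#' @param a1 generation coefficient (1/h).
#' @param a2 degradation coefficient (1/(a.u.*h)).
#' @param dt time step (h).
#' @return the updated grid.
#' @export
update_ecm <- function(grid, a1, a2, dt) {
  stopifnot(dt > 0)
  ecm <- grid$fields[["ECM"]]
  mmp <- grid$fields[["MMP"]]
  ecm <- ecm + dt * (a1 * ecm - a2 * mmp * ecm)
  ecm[ecm < 0] <- 0
  grid$fields[["ECM"]] <- ecm
  grid
}

#' Dump fields as a flat table
#'
#' @param grid a [build_domain()] grid.
#' @param path output file (tab-separated); one row per inside node with
#'   columns `node`, `x`, `y`, `z` (cm) and one column per requested field.
#' @param signals fields to include (default: all).
#' @export
write_fields <- function(grid, path, signals = names(grid$fields)) {
  idx <- which(grid$mask, arr.ind = TRUE)
  df <- data.frame(node = seq_len(nrow(idx)),
                   x = grid$axis[idx[, 1]],
                   y = grid$axis[idx[, 2]],
                   z = grid$axis[idx[, 3]])
  for (s in signals) df[[s]] <- grid$fields[[s]][grid$mask]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
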