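#' Species, reactions and reaction networks
#'
#' A `ReactionNetwork` is the generic container from which the intracellular
#' ODE right-hand sides are assembled: a species list (each species either
#' `internal`, `secreted-signal`, or `external-input`), a reaction list with
#' structured rate laws and signed stoichiometry, and a parameter table.
#' External-input species carry no ODE of their own; their values are
#' supplied per evaluation (they are the diffusing signals arriving at the
#' cell surface).
#'
#' @name reaction-networks
NULL

#' Declare a species
#'
#' @param name species identifier (unique within a network).
#' @param role one of `"internal"`, `"secreted-signal"`, `"external-input"`.
#' @param initial_value nonnegative initial concentration (a.u.).
#' @param label optional human-readable name (e.g. `"pSMAD3"`).
#' @return object of class `SpeciesSpec`.
#' @export
species_spec <- function(name, role = c("internal", "secreted-signal",
                                        "external-input"),
                         initial_value = 0, label = name) {
  role <- match.arg(role)
  if (initial_value < 0) stop("initial_value must be >= 0", call. = FALSE)
  structure(list(name = name, role = role, initial_value = initial_value,
                 label = label), class = "SpeciesSpec")
}

#' Declare a reaction
#'
#' @param name reaction identifier (the v/w/z label).
#' @param rate a [rate_law()].
#' @param stoichiometry named numeric vector, consumed species negative,
#'   produced species positive; must be non-empty.
#' @param description free-text description of the interaction.
#' @param provenance `"printed"` for reactions taken directly from the
#'   published rate tables, `"reconstructed"` for reactions added to complete
#'   a pathway whose detailed listing is not public.
#' @return object of class `Reaction`.
#' @export
reaction <- function(name, rate, stoichiometry, description = "",
                     provenance = c("printed", "reconstructed")) {
  provenance <- match.arg(provenance)
  stopifnot(inherits(rate, "RateLaw"))
  if (length(stoichiometry) == 0L || is.null(names(stoichiometry)))
    stop("stoichiometry must be a non-empty named vector", call. = FALSE)
  structure(list(name = name, rate = rate, stoichiometry = stoichiometry,
                 description = description, provenance = provenance),
            class = "Reaction")
}

#' Build a reaction network
#'
#' @param species list of [species_spec()] objects.
#' @param reactions list of [reaction()] objects.
#' @param parameters named numeric vector of nonnegative parameter values.
#' @return object of class `ReactionNetwork`.
#' @export
reaction_network <- function(species, reactions, parameters) {
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop("duplicated species names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  parameters <- unlist(parameters)
  if (any(parameters < 0)) stop("parameters must be >= 0", call. = FALSE)
  structure(list(species = species, reactions = reactions,
                 parameters = parameters),
            class = "ReactionNetwork")
}

species_names <- function(network)
  vapply(network$species, `[[`, "", "name")

species_roles <- function(network)
  vapply(network$species, `[[`, "", "role")

#' Dynamical (non-input) species of a network
#' @param network a [reaction_network()].
#' @return character vector of species names that carry an ODE.
#' @export
dynamical_species <- function(network)
  species_names(network)[species_roles(network) != "external-input"]

#' External-input species of a network
#' @param network a [reaction_network()].
#' @return character vector of species names supplied per evaluation.
#' @export
input_species <- function(network)
  species_names(network)[species_roles(network) == "external-input"]

#' Default initial state of a network
#' @param network a [reaction_network()].
#' @return named numeric vector over the dynamical species.
#' @export
initial_state <- function(network) {
  dyn <- dynamical_species(network)
  x0 <- vapply(network$species, `[[`, 0, "initial_value")
  names(x0) <- species_names(network)
  x0[dyn]
}

#' Validate a reaction network
#'
#' Report-only structural check: undefined species or parameters referenced
#' by reactions, species never referenced by any reaction, and duplicated
#' reaction names (duplicates are a warning-level finding, not a failure --
#' the published rate tables themselves reuse a label for two association
#' routes).
#'
#' @param network a [reaction_network()].
#' @return a list of class `network_check` with elements
#'   `undefined_species`, `undefined_parameters`, `unreferenced_species`,
#'   `duplicated_reaction_names`, and logical `ok` (TRUE iff no undefined
#'   symbols; unreferenced species and duplicate names do not fail).
#' @export
check_network <- function(network) {
  sp <- species_names(network)
  undef_sp <- character(); undef_par <- character(); used <- character()
  for (r in network$reactions) {
    ref <- unique(c(names(r$rate$reactant_orders), r$rate$saturating_species,
                    names(r$stoichiometry)))
    used <- c(used, ref)
    undef_sp <- c(undef_sp, setdiff(ref, sp))
    pref <- c(r$rate$rate_constant, r$rate$half_constant)
    undef_par <- c(undef_par, setdiff(pref, names(network$parameters)))
  }
  rnames <- vapply(network$reactions, `[[`, "", "name")
  res <- list(
    undefined_species = unique(undef_sp),
    undefined_parameters = unique(undef_par),
    unreferenced_species = setdiff(sp, used),
    duplicated_reaction_names = unique(rnames[duplicated(rnames)]))
  res$ok <- length(res$undefined_species) == 0 &&
    length(res$undefined_parameters) == 0
  class(res) <- "network_check"
  res
}

#' @export
print.network_check <- function(x, ...) {
  cat("<network check>", if (x$ok) "OK" else "FAILED", "\n")
  for (f in c("undefined_species", "undefined_parameters",
              "unreferenced_species", "duplicated_reaction_names"))
    if (length(x[[f]]))
      cat("  ", f, ": ", paste(x[[f]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.ReactionNetwork <- function(x, ...) {
  roles <- species_roles(x)
  cat(sprintf("<ReactionNetwork> %d dynamical species (+%d external inputs), %d reactions, %d parameters\n",
              sum(roles != "external-input"), sum(roles == "external-input"),
              length(x$reactions), length(x$parameters)))
  invisible(x)
}

## --- compilation to an index-based form used by the RHS ------------------

compile_network <- function(network, parameters = NULL) {
  chk <- check_network(network)
  if (!chk$ok)
    stop("network fails validation: undefined symbols ",
         paste(c(chk$undefined_species, chk$undefined_parameters),
               collapse = ", "), call. = FALSE)
  pars <- if (is.null(parameters)) network$parameters else unlist(parameters)
  sp <- species_names(network)
  dyn <- dynamical_species(network)
  inp <- input_species(network)
  full_idx <- stats::setNames(seq_along(sp), sp)
  ns <- length(sp)
  nr <- length(network$reactions)
  S <- matrix(0, nrow = length(dyn), ncol = nr,
              dimnames = list(dyn, NULL))
  # each rate law expands into a fixed number of multiplicative factor
  # slots (a species index, or ns+1 pointing to a constant 1), plus an
  # optional saturating factor; evaluation is then fully vectorized
  max_deg <- max(1L, vapply(network$reactions, function(r)
    if (is.null(r$rate$reactant_orders)) 0L else
      as.integer(sum(r$rate$reactant_orders)), 0L))
  Fidx <- matrix(ns + 1L, nrow = nr, ncol = max_deg)
  k_vec <- numeric(nr)
  sat_idx <- integer(nr)          # 0 = no saturating factor
  K_vec <- numeric(nr)
  avail_rx <- integer(0)          # flux i consumes a species absent from
  avail_sp <- integer(0)          # its own rate law (inhibitory removals):
                                  # scale by smooth availability x/(x+delta)
  for (i in seq_len(nr)) {
    r <- network$reactions[[i]]
    st <- r$stoichiometry[names(r$stoichiometry) %in% dyn]
    if (length(st)) S[names(st), i] <- st
    rl <- r$rate
    k_vec[i] <- unname(pars[[rl$rate_constant]])
    if (!is.null(rl$reactant_orders)) {
      slots <- rep(unname(full_idx[names(rl$reactant_orders)]),
                   rl$reactant_orders)
      Fidx[i, seq_along(slots)] <- slots
    }
    if (!is.null(rl$saturating_species)) {
      sat_idx[i] <- unname(full_idx[[rl$saturating_species]])
      K_vec[i] <- unname(pars[[rl$half_constant]])
    }
    in_rate <- c(names(rl$reactant_orders), rl$saturating_species)
    blind <- setdiff(names(r$stoichiometry)[r$stoichiometry < 0], in_rate)
    if (length(blind)) {
      avail_rx <- c(avail_rx, rep(i, length(blind)))
      avail_sp <- c(avail_sp, unname(full_idx[blind]))
    }
  }
  has_sat <- which(sat_idx > 0L)
  list(S = S, dyn = dyn, inp = inp, sp = sp, ns = ns,
       dyn_idx = unname(full_idx[dyn]), inp_idx = unname(full_idx[inp]),
       k = k_vec, Fidx = Fidx, sat_idx = sat_idx, K = K_vec,
       has_sat = has_sat, avail_rx = avail_rx, avail_sp = avail_sp)
}

compiled_rates <- function(cm, xfull) {
  xe <- c(xfull, 1)
  v <- cm$k
  for (j in seq_len(ncol(cm$Fidx)))
    v <- v * xe[cm$Fidx[, j]]
  if (length(cm$has_sat)) {
    xs <- xfull[cm$sat_idx[cm$has_sat]]
    fac <- xs / (xs + cm$K[cm$has_sat])
    fac[!is.finite(fac)] <- 0
    v[cm$has_sat] <- v[cm$has_sat] * fac
  }
  if (length(cm$avail_rx)) {
    xa <- xfull[cm$avail_sp]
    v[cm$avail_rx] <- v[cm$avail_rx] * xa / (xa + 1e-6)
  }
  v
}

#' Assemble the ODE right-hand side of a network
#'
#' Returns `function(t, state, inputs)` where `state` is the vector over the
#' dynamical species (in [dynamical_species()] order) and `inputs` a named
#' vector over the external-input species. The derivative of species s is
#' the stoichiometry-weighted sum of all reaction fluxes. States are clipped
#' at zero inside the rate evaluation, and an outflux from an already-empty
#' species is suppressed, so trajectories remain nonnegative.
#'
#' @param network a [reaction_network()].
#' @param parameters optional parameter vector overriding the network's own.
#' @return derivative function `(t, state, inputs) -> named numeric vector`.
#' @export
assemble_rhs <- function(network, parameters = NULL) {
  cm <- compile_network(network, parameters)
  ns_full <- length(cm$sp)
  ndyn <- length(cm$dyn)
  dyn_names <- cm$dyn
  force(cm)
  # cache the input-name matching: callers almost always pass the same
  # named vector layout on every evaluation
  last_in_names <- NULL
  last_match <- integer(0)
  function(t, state, inputs = numeric(0)) {
    if (length(state) != ndyn)
      stop(sprintf("state vector length %d, expected %d", length(state), ndyn),
           call. = FALSE)
    state <- unname(state)
    xfull <- numeric(ns_full)
    xfull[cm$dyn_idx] <- state * (state > 0)
    if (length(cm$inp_idx) && length(inputs)) {
      inputs <- unlist(inputs)
      nmi <- names(inputs)
      if (!identical(nmi, last_in_names)) {
        last_in_names <<- nmi
        last_match <<- match(cm$inp, nmi)
      }
      m <- last_match
      ok <- !is.na(m)
      iv <- numeric(length(cm$inp_idx))
      vi <- inputs[m[ok]]
      iv[ok] <- vi * (vi > 0)
      xfull[cm$inp_idx] <- iv
    }
    v <- compiled_rates(cm, xfull)
    dx <- drop(cm$S %*% v)
    # one-sided guard: removal fluxes (e.g. inhibitory terms proportional to
    # another species) cannot drive an empty pool negative
    empty <- state <= 0 & dx < 0
    if (any(empty)) dx[empty] <- 0
    names(dx) <- dyn_names
    dx
  }
}

#' Simulate a reaction network
#'
#' Integrates the assembled ODE system with a stiff solver (`deSolve::lsoda`)
#' and returns a `Trajectory`: times (hours) by dynamical species matrix,
#' floored at zero where values fall below 1e-12 in magnitude.
#'
#' @param network a [reaction_network()].
#' @param x0 named initial state over the dynamical species (defaults to the
#'   network's declared initial values); all entries >= 0.
#' @param parameters optional parameter override.
#' @param inputs either a named numeric vector of constant external-input
#'   values or a function `t -> named vector`; defaults to all zero.
#' @param times increasing vector of output times (hours).
#' @param rtol,atol solver tolerances.
#' @return object of class `Trajectory`: list with `times` and `values`
#'   (time x species matrix).
#' @export
simulate_network <- function(network, x0 = NULL, parameters = NULL,
                             inputs = NULL, times = seq(0, 72, by = 1),
                             rtol = 1e-8, atol = 1e-10) {
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (is.null(x0)) x0 <- initial_state(network)
  if (any(x0 < 0)) stop("x0 must be >= 0", call. = FALSE)
  rhs <- assemble_rhs(network, parameters)
  dyn <- dynamical_species(network)
  x0 <- x0[dyn]
  input_fn <- if (is.null(inputs)) {
    function(t) numeric(0)
  } else if (is.function(inputs)) {
    inputs
  } else {
    force(inputs); function(t) inputs
  }
  out <- deSolve::lsoda(
    y = x0, times = times,
    func = function(t, y, parms) list(rhs(t, y, input_fn(t))),
    parms = NULL, rtol = rtol, atol = atol)
  if (nrow(out) < length(times) || any(!is.finite(out)))
    stop(sprintf("integrator failed; last good time %g h",
                 out[nrow(out), 1]), call. = FALSE)
  vals <- out[, -1, drop = FALSE]
  vals[abs(vals) < 1e-12] <- 0
  trajectory(times = out[, 1], values = vals)
}

#' Construct a trajectory object
#' @param times increasing time vector (hours).
#' @param values time x species matrix (a.u.).
#' @return object of class `Trajectory`.
#' @export
trajectory <- function(times, values) {
  values <- as.matrix(values)
  stopifnot(length(times) == nrow(values))
  structure(list(times = as.numeric(times), values = values),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d time points over [%g, %g] h, %d species\n",
              length(x$times), min(x$times), max(x$times), ncol(x$values)))
  invisible(x)
}

## --- serialization --------------------------------------------------------

#' Write a network definition to a structured text file
#'
#' JSON serialization with one block per species, one per reaction and a
#' parameter table; round-trips losslessly through [read_network()].
#'
#' @param network a [reaction_network()].
#' @param path output file path.
#' @export
write_network <- function(network, path) {
  doc <- list(
    species = lapply(network$species, function(s)
      list(name = s$name, role = s$role, initial_value = s$initial_value,
           label = s$label)),
    reactions = lapply(network$reactions, function(r)
      list(name = r$name, description = r$description,
           provenance = r$provenance,
           rate = list(kind = r$rate$kind,
                       rate_constant = r$rate$rate_constant,
                       reactant_orders = as.list(r$rate$reactant_orders),
                       saturating_species = r$rate$saturating_species,
                       half_constant = r$rate$half_constant),
           stoichiometry = as.list(r$stoichiometry))),
    parameters = as.list(network$parameters))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a network definition written by [write_network()]
#' @param path file path.
#' @return a [reaction_network()].
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path)
  species <- lapply(doc$species, function(s)
    species_spec(s$name, s$role, s$initial_value, s$label))
  reactions <- lapply(doc$reactions, function(r) {
    ro <- if (length(r$rate$reactant_orders))
      unlist(r$rate$reactant_orders) else NULL
    rl <- rate_law(r$rate$kind, r$rate$rate_constant, ro,
                   r$rate$saturating_species, r$rate$half_constant)
    reaction(r$name, rl, unlist(r$stoichiometry),
             description = r$description, provenance = r$provenance)
  })
  reaction_network(species, reactions, unlist(doc$parameters))
}
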