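#' Rate laws for biochemical reactions
#'
#' Constructors and evaluation for the three rate-law forms used across the
#' intracellular signaling networks: plain mass action
#' (`k * prod(x_i^order_i)`), a saturating (Michaelis--Menten style) form
#' (`k * prod(modifier_i^order_i) * x / (x + K)`), and a zero-order constant
#' source (`k`).
#'
#' @param kind one of `"mass_action"`, `"saturating"`, `"constant_source"`.
#' @param rate_constant name of the rate-constant parameter.
#' @param reactant_orders named integer vector mapping species to their
#'   kinetic order (all orders >= 1). For `"saturating"` these are the
#'   multiplicative modifier species in front of the saturating factor.
#' @param saturating_species species appearing as `x / (x + K)`
#'   (required for `kind = "saturating"`).
#' @param half_constant name of the half-saturation parameter `K`
#'   (required for `kind = "saturating"`).
#' @return an object of class `RateLaw`.
#' @examples
#' rl <- rate_law("mass_action", "k2p", c(xu3 = 1, x1 = 2))
#' evaluate_rate(rl, c(xu3 = 2, x1 = 3), c(k2p = 1))  # 1 * 2 * 9 = 18
#' @export
rate_law <- function(kind = c("mass_action", "saturating", "constant_source"),
                     rate_constant,
                     reactant_orders = NULL,
                     saturating_species = NULL,
                     half_constant = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(rate_constant), length(rate_constant) == 1L)
  if (!is.null(reactant_orders)) {
    if (is.null(names(reactant_orders)) || any(!nzchar(names(reactant_orders))))
      stop("reactant_orders must be a named vector", call. = FALSE)
    if (any(reactant_orders < 1))
      stop("all reactant orders must be >= 1", call. = FALSE)
  }
  if (kind == "saturating") {
    if (is.null(saturating_species) || is.null(half_constant))
      stop("saturating rate law needs 'saturating_species' and 'half_constant'",
           call. = FALSE)
  }
  structure(
    list(kind = kind,
         rate_constant = rate_constant,
         reactant_orders = reactant_orders,
         saturating_species = saturating_species,
         half_constant = half_constant),
    class = "RateLaw")
}

#' Evaluate a rate law at given concentrations
#'
#' @param rate a [rate_law()] object.
#' @param concentrations named numeric vector of species concentrations
#'   (a.u.); all values must be nonnegative.
#' @param parameters named numeric vector/list of parameter values.
#' @return flux in a.u./h (nonnegative scalar).
#' @export
evaluate_rate <- function(rate, concentrations, parameters) {
  stopifnot(inherits(rate, "RateLaw"))
  parameters <- unlist(parameters)
  need_par <- c(rate$rate_constant, rate$half_constant)
  miss <- setdiff(need_par, names(parameters))
  if (length(miss))
    stop("undefined parameter(s): ", paste(miss, collapse = ", "), call. = FALSE)
  need_sp <- c(names(rate$reactant_orders), rate$saturating_species)
  miss <- setdiff(need_sp, names(concentrations))
  if (length(miss))
    stop("undefined species: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(need_sp) && any(concentrations[need_sp] < 0))
    stop("negative concentration supplied to rate law", call. = FALSE)

  k <- parameters[[rate$rate_constant]]
  flux <- k
  if (!is.null(rate$reactant_orders))
    flux <- flux * prod(concentrations[names(rate$reactant_orders)] ^
                          rate$reactant_orders)
  if (rate$kind == "saturating") {
    x <- concentrations[[rate$saturating_species]]
    K <- parameters[[rate$half_constant]]
    denom <- x + K
    flux <- if (denom > 0) flux * x / denom else 0
  }
  as.numeric(flux)
}

#' @export
print.RateLaw <- function(x, ...) {
  fac <- if (is.null(x$reactant_orders)) "" else
    paste0(" * ", paste0(names(x$reactant_orders),
                         ifelse(x$reactant_orders > 1,
                                paste0("^", x$reactant_orders), ""),
                         collapse = " * "))
  sat <- if (x$kind == "saturating")
    sprintf(" * %s/(%s + %s)", x$saturating_species, x$saturating_species,
            x$half_constant) else ""
  cat(sprintf("<RateLaw %s> %s%s%s\n", x$kind, x$rate_constant, fac, sat))
  invisible(x)
}
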