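#' Morris elementary-effects sensitivity screening
#'
#' One-at-a-time global screening: for each of `r` random base points drawn
#' uniformly inside the parameter ranges, every parameter is perturbed by a
#' fixed fraction `delta` of its range and the elementary effect
#' `EE_i = (y(theta + Delta_i e_i) - y(theta)) / Delta_i` is recorded
#' (`Delta_i = delta * width_i`, in raw parameter units, so a linear model
#' `y = sum(a_i theta_i)` yields `mu_i = a_i`). Per parameter the mean
#' (`mu`, signed effect), mean absolute value (`mu_star`, overall
#' importance) and standard deviation (`sigma`, nonlinearity/interaction)
#' over the `r` trajectories are reported.
#'
#' @param model_fn function mapping a named parameter vector to a scalar
#'   output.
#' @param ranges named list of `c(lower, upper)` per parameter.
#' @param r number of trajectories (base points), >= 1.
#' @param delta step size as a fraction of each range, in (0, 1).
#' @param seed integer seed for the base-point draws.
#' @return object of class `MorrisResult`: data.frame with columns
#'   `parameter`, `mu`, `mu_star`, `sigma` and attribute `n_dropped`
#'   (trajectories discarded because the model returned a non-finite
#'   value).
#' @export
morris_screening <- function(model_fn, ranges, r = 10, delta = 0.5,
                             seed = 1) {
  stopifnot(r >= 1, delta > 0, delta < 1, length(ranges) >= 1)
  pnames <- names(ranges)
  if (is.null(pnames)) stop("ranges must be named", call. = FALSE)
  lo <- vapply(ranges, `[`, 0, 1)
  hi <- vapply(ranges, `[`, 0, 2)
  stopifnot(all(hi > lo))
  width <- hi - lo
  Delta <- delta * width
  p <- length(pnames)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  EE <- matrix(NA_real_, nrow = r, ncol = p, dimnames = list(NULL, pnames))
  dropped <- 0
  for (j in seq_len(r)) {
    # base point such that theta + Delta stays inside the range
    theta <- lo + stats::runif(p) * (width - Delta)
    names(theta) <- pnames
    y0 <- model_fn(theta)
    ok <- is.finite(y0)
    ee <- numeric(p)
    if (ok) {
      for (i in seq_len(p)) {
        th <- theta
        th[i] <- th[i] + Delta[i]
        yi <- model_fn(th)
        if (!is.finite(yi)) { ok <- FALSE; break }
        ee[i] <- (yi - y0) / Delta[i]
      }
    }
    if (ok) EE[j, ] <- ee else dropped <- dropped + 1
  }
  if (dropped > 0)
    warning(sprintf("%d of %d Morris trajectories returned non-finite output and were dropped",
                    dropped, r))
  EE <- EE[stats::complete.cases(EE), , drop = FALSE]
  if (nrow(EE) == 0) stop("all Morris trajectories failed", call. = FALSE)
  res <- data.frame(
    parameter = pnames,
    mu = colMeans(EE),
    mu_star = colMeans(abs(EE)),
    sigma = if (nrow(EE) > 1) apply(EE, 2, stats::sd) else rep(0, p),
    row.names = NULL)
  attr(res, "n_dropped") <- dropped
  class(res) <- c("MorrisResult", "data.frame")
  res
}

#' Sensitivity of a cell model's observable to its parameters
#'
#' Convenience wrapper running [morris_screening()] on a scalar summary of
#' a cell model: the fold change of one gene at a given time as selected
#' parameters vary over multiplicative ranges around their defaults.
#'
#' @param spec a [cell_model_spec()].
#' @param parameters names of the parameters to screen.
#' @param gene observable gene (default `"SMAD7"`).
#' @param time_h evaluation time in hours.
#' @param fold multiplicative half-range: each parameter varies in
#'   `[value/fold, value*fold]`.
#' @param inputs constant external inputs (default 1 for each).
#' @param r,delta,seed passed to [morris_screening()].
#' @return a `MorrisResult`.
#' @export
morris_cell_model <- function(spec, parameters, gene = "SMAD7",
                              time_h = 48, fold = 2, inputs = NULL,
                              r = 10, delta = 0.5, seed = 1) {
  stopifnot(inherits(spec, "CellModelSpec"),
            all(parameters %in% names(spec$network$parameters)))
  if (is.null(inputs))
    inputs <- stats::setNames(rep(1, length(spec$input_names)),
                              spec$input_names)
  base <- spec$network$parameters
  ranges <- lapply(parameters, function(p)
    c(base[[p]] / fold, base[[p]] * fold))
  names(ranges) <- parameters
  fn <- function(theta) {
    pars <- base
    pars[names(theta)] <- theta
    tr <- tryCatch(
      simulate_network(spec$network, parameters = pars, inputs = inputs,
                       times = c(0, time_h / 2, time_h), rtol = 1e-6,
                       atol = 1e-8),
      error = function(e) NULL)
    if (is.null(tr)) return(NA_real_)
    observables(spec, tr, times = c(0, time_h))[gene, 2]
  }
  morris_screening(fn, ranges, r = r, delta = delta, seed = seed)
}
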