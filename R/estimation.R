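#' Hybrid (continuous-discrete) unscented Kalman filtering
#'
#' Joint state/parameter estimation for the intracellular networks from
#' sparse fold-change time courses. The filter augments the dynamical state
#' with the logarithms of the free parameters (positivity by construction),
#' propagates sigma points through the continuous ODE dynamics between the
#' discrete measurement times (the "hybrid" in HUKF), and corrects with the
#' fold-change observable map. Several passes over the same short time
#' course, re-initializing the states but carrying the parameter statistics,
#' refine the estimate.
#'
#' @name hukf
NULL

#' Filter configuration
#'
#' @param alpha,beta,kappa scaled unscented-transform scalars
#'   (`alpha` in (0,1]).
#' @param process_noise random-walk process-noise intensity on the states
#'   (variance per hour).
#' @param param_process_noise process-noise intensity on the log-parameters
#'   (variance per hour).
#' @param measurement_noise measurement variance on each fold-change
#'   observation.
#' @param n_passes number of filtering passes over the time course.
#' @param free_parameters character vector of parameter names to estimate.
#' @param init_state_sd,init_param_sd prior standard deviations of the
#'   states and of the log-parameters.
#' @param ode_rtol,ode_atol solver tolerances used during sigma-point
#'   propagation.
#' @return object of class `FilterConfig`.
#' @export
filter_config <- function(alpha = 1e-3, beta = 2, kappa = 0,
                          process_noise = 1e-6,
                          param_process_noise = 1e-4,
                          measurement_noise = 1e-2,
                          n_passes = 10,
                          free_parameters = character(),
                          init_state_sd = 1e-2,
                          init_param_sd = 0.5,
                          ode_rtol = 1e-6, ode_atol = 1e-8) {
  stopifnot(alpha > 0, alpha <= 1, n_passes >= 1,
            process_noise > 0, param_process_noise > 0,
            measurement_noise >= 0)
  structure(list(alpha = alpha, beta = beta, kappa = kappa,
                 process_noise = process_noise,
                 param_process_noise = param_process_noise,
                 measurement_noise = measurement_noise,
                 n_passes = n_passes, free_parameters = free_parameters,
                 init_state_sd = init_state_sd,
                 init_param_sd = init_param_sd,
                 ode_rtol = ode_rtol, ode_atol = ode_atol),
            class = "FilterConfig")
}

# symmetric square root of (n+lambda) * P; Cholesky with eigen fallback
cov_sqrt <- function(P, scale) {
  P <- (P + t(P)) / 2
  M <- scale * P
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(ch)) return(t(ch))
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("covariance is not positive semi-definite", call. = FALSE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M)) %*% t(e$vectors)
}

#' Sigma points of the scaled unscented transform
#'
#' Generates the 2n+1 weighted points whose weighted mean reproduces `mean`
#' exactly and whose weighted spread reproduces `covariance` to numerical
#' precision.
#'
#' @param mean length-n mean vector.
#' @param covariance n x n positive semi-definite covariance.
#' @param cfg a [filter_config()] (only `alpha`, `beta`, `kappa` are used).
#' @return list with `points` ((2n+1) x n matrix, first row the mean),
#'   `wm` (mean weights) and `wc` (covariance weights).
#' @export
sigma_points <- function(mean, covariance, cfg = filter_config()) {
  n <- length(mean)
  covariance <- as.matrix(covariance)
  stopifnot(nrow(covariance) == n, ncol(covariance) == n)
  lambda <- cfg$alpha^2 * (n + cfg$kappa) - n
  S <- cov_sqrt(covariance, n + lambda)
  pts <- matrix(rep(mean, 2 * n + 1), nrow = 2 * n + 1, byrow = TRUE)
  for (i in seq_len(n)) {
    pts[1 + i, ] <- mean + S[, i]
    pts[1 + n + i, ] <- mean - S[, i]
  }
  wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + (1 - cfg$alpha^2 + cfg$beta)
  list(points = pts, wm = wm, wc = wc)
}

# weighted mean and covariance of transformed sigma points, accumulated in
# deviation form around the central point (the weights are large and of
# mixed sign for small alpha; centering avoids catastrophic cancellation)
ut_moments <- function(pts, wm, wc) {
  c0 <- pts[1, ]
  d <- sweep(pts, 2, c0)
  shift <- drop(wm %*% d)
  m <- c0 + shift
  dm <- sweep(d, 2, shift)
  P <- t(dm) %*% (dm * wc)
  list(mean = m, cov = (P + t(P)) / 2)
}

# re-impose symmetry and a small eigenvalue floor after each correction
psd_repair <- function(P, floor = 1e-12) {
  P <- (P + t(P)) / 2
  e <- eigen(P, symmetric = TRUE)
  if (min(e$values) < floor)
    P <- e$vectors %*% diag(pmax(e$values, floor), nrow(P)) %*% t(e$vectors)
  (P + t(P)) / 2
}

#' Joint state/parameter estimation with the hybrid UKF
#'
#' @param spec a [cell_model_spec()].
#' @param observations gene x time matrix of fold changes (as produced by
#'   [observables()] or [generate_timecourse()]); column names are the
#'   observation times in hours, which must include t = 0 and at least one
#'   later time.
#' @param cfg a [filter_config()]; `cfg$free_parameters` selects what is
#'   estimated.
#' @param inputs named constant external-input vector applied during
#'   propagation (default: 1 for every input of the model, the stimulated
#'   condition).
#' @param initial_parameters parameter vector used as the filter's starting
#'   point (defaults to the network's own table); free parameters enter the
#'   augmented mean as logarithms.
#' @param x0 initial state (defaults to the network's declared values).
#' @return object of class `EstimationResult`: `estimated_parameters`
#'   (all strictly positive), `fitted_trajectory`, `fit_statistics`
#'   (per-gene R^2/RMSE/MAE), `parameter_history` (per pass), and the final
#'   augmented `filter_state`.
#' @export
hukf_estimate <- function(spec, observations, cfg = filter_config(),
                          inputs = NULL, initial_parameters = NULL,
                          x0 = NULL) {
  stopifnot(inherits(spec, "CellModelSpec"))
  net <- spec$network
  obs_times <- as.numeric(colnames(observations))
  if (length(obs_times) < 2 || obs_times[1] != 0)
    stop("observations must cover t = 0 and at least one later time",
         call. = FALSE)
  free <- cfg$free_parameters
  if (!all(free %in% names(net$parameters)))
    stop("free_parameters not in the network parameter table", call. = FALSE)
  pars0 <- if (is.null(initial_parameters)) net$parameters else {
    p <- net$parameters; p[names(initial_parameters)] <- initial_parameters; p
  }
  if (is.null(x0)) x0 <- initial_state(net)
  dyn <- dynamical_species(net)
  x0 <- x0[dyn]
  if (is.null(inputs))
    inputs <- stats::setNames(rep(1, length(spec$input_names)),
                              spec$input_names)
  genes <- intersect(names(spec$observable_map), rownames(observations))
  obs_idx <- match(spec$observable_map[genes], dyn)
  baseline <- x0[obs_idx]
  if (any(baseline <= 0))
    stop("observable baseline must be positive to form fold changes",
         call. = FALSE)

  nx <- length(dyn); nf <- length(free)
  n <- nx + nf
  rhs <- NULL
  make_rhs <- function(theta) {
    p <- pars0
    if (nf) p[free] <- theta
    assemble_rhs(net, p)
  }
  propagate <- function(z, t0, t1) {
    # one augmented sigma point over [t0, t1]; returns z at t1 or NULL
    x <- pmax(z[seq_len(nx)], 0)
    theta <- if (nf) exp(z[nx + seq_len(nf)]) else numeric(0)
    f <- make_rhs(theta)
    out <- tryCatch(
      deSolve::lsoda(y = x, times = c(t0, t1),
                     func = function(t, y, parms) list(f(t, y, inputs)),
                     parms = NULL, rtol = cfg$ode_rtol, atol = cfg$ode_atol),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(out) || nrow(out) < 2 || any(!is.finite(out)))
      return(NULL)
    c(pmax(out[2, -1], 0), z[nx + seq_len(nf)][seq_len(nf)])
  }
  h_fn <- function(z) z[obs_idx] / baseline

  m_par <- if (nf) log(pars0[free]) else numeric(0)
  P_par <- diag(cfg$init_param_sd^2, nf)
  P0_state <- diag(cfg$init_state_sd^2, nx)
  R <- diag(cfg$measurement_noise, length(genes))
  par_history <- matrix(NA_real_, nrow = cfg$n_passes, ncol = nf,
                        dimnames = list(NULL, free))

  for (pass in seq_len(cfg$n_passes)) {
    m <- c(x0, m_par)
    P <- matrix(0, n, n)
    P[seq_len(nx), seq_len(nx)] <- P0_state
    if (nf) P[nx + seq_len(nf), nx + seq_len(nf)] <- P_par
    t_prev <- obs_times[1]
    for (k in seq_along(obs_times)) {
      tk <- obs_times[k]
      if (tk > t_prev) {          # prediction: continuous propagation
        sp <- sigma_points(m, P, cfg)
        prop <- matrix(NA_real_, nrow(sp$points), n)
        n_fail <- 0
        for (i in seq_len(nrow(sp$points))) {
          zi <- propagate(sp$points[i, ], t_prev, tk)
          if (is.null(zi)) { n_fail <- n_fail + 1; zi <- sp$points[1, ] }
          prop[i, ] <- zi
        }
        if (n_fail == nrow(sp$points))
          stop("all sigma points failed to integrate", call. = FALSE)
        if (n_fail > 0)
          warning(sprintf("%d sigma point(s) failed to integrate over [%g, %g] h; replaced by the prior mean",
                          n_fail, t_prev, tk))
        mom <- ut_moments(prop, sp$wm, sp$wc)
        m <- mom$mean
        dt <- tk - t_prev
        Qd <- diag(c(rep(cfg$process_noise, nx),
                     rep(cfg$param_process_noise, nf)) * dt, n)
        P <- psd_repair(mom$cov + Qd)
      }
      # correction with the fold-change measurement
      sp <- sigma_points(m, P, cfg)
      Y <- apply(sp$points, 1, h_fn)
      Y <- if (is.matrix(Y)) t(Y) else matrix(Y, ncol = 1)
      ym <- drop(sp$wm %*% Y)
      dy <- sweep(Y, 2, ym)
      dz <- sweep(sp$points, 2, m)
      Pyy <- t(dy) %*% (dy * sp$wc) + R
      Pzy <- t(dz) %*% (dy * sp$wc)
      K <- Pzy %*% solve(Pyy)
      innov <- observations[genes, k] - ym
      m <- m + drop(K %*% innov)
      P <- psd_repair(P - K %*% Pyy %*% t(K))
      t_prev <- tk
    }
    if (nf) {
      m_par <- m[nx + seq_len(nf)]
      P_par <- P[nx + seq_len(nf), nx + seq_len(nf), drop = FALSE]
      par_history[pass, ] <- exp(m_par)
    }
  }

  est <- pars0
  if (nf) est[free] <- exp(m_par)
  sim_times <- sort(unique(c(obs_times, seq(min(obs_times), max(obs_times),
                                            length.out = 25))))
  fitted <- simulate_network(net, x0 = x0, parameters = est,
                             inputs = inputs, times = sim_times)
  pred <- observables(spec, fitted, obs_times)
  stats_tab <- do.call(rbind, lapply(genes, function(g) {
    gof <- goodness_of_fit(pred[g, ], observations[g, ])
    data.frame(gene = g, r_squared = gof$r_squared, rmse = gof$rmse,
               mae = gof$mae)
  }))
  structure(list(estimated_parameters = est[if (nf) free else TRUE],
                 all_parameters = est,
                 fitted_trajectory = fitted,
                 predicted_observables = pred,
                 fit_statistics = stats_tab,
                 parameter_history = par_history,
                 filter_state = list(mean = m, covariance = P)),
            class = "EstimationResult")
}

#' @export
print.EstimationResult <- function(x, ...) {
  cat("<EstimationResult>\n  estimated parameters:\n")
  print(round(x$estimated_parameters, 5))
  cat("  fit statistics:\n")
  print(x$fit_statistics, row.names = FALSE)
  invisible(x)
}

#' Write an estimation report as structured text
#'
#' @param result an [hukf_estimate()] result.
#' @param path output file.
#' @param observations optional observation matrix to include Bland-Altman
#'   agreement numbers between observed and fitted fold changes.
#' @export
write_estimation_report <- function(result, path, observations = NULL) {
  doc <- list(estimated_parameters = as.list(result$estimated_parameters),
              fit_statistics = result$fit_statistics)
  if (!is.null(observations)) {
    pred <- result$predicted_observables
    g <- intersect(rownames(pred), rownames(observations))
    ba <- bland_altman(as.numeric(pred[g, ]), as.numeric(observations[g, ]))
    doc$bland_altman <- ba
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
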