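#' Synthetic inputs: expression time courses and fixture tumors
#'
#' Generators producing every input the rest of the package needs without
#' external downloads: four-time-point fold-change expression observations
#' of the measured genes (emulating sparse public time-course series) with
#' multiplicative log-normal noise, perturbed "truth" parameter sets for
#' estimation experiments, and seeded random cell arrangements.
#'
#' @name synthetic-data
NULL

# evaluate expr with a locally-set seed, restoring the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a noisy expression time course from a cell model
#'
#' Simulates the model under constant stimulation, maps the trajectory to
#' gene fold changes, and applies multiplicative log-normal noise
#' (expression data are ratio-scaled). The t = 0 column is re-anchored to
#' exactly 1 per gene, as fold-change data are reported.
#'
#' @param spec a [cell_model_spec()].
#' @param true_params optional parameter overrides defining the generating
#'   truth.
#' @param times observation times in hours (default `c(0, 24, 48, 72)`).
#' @param noise_sd standard deviation of the log-normal noise (0 = exact
#'   model output).
#' @param seed integer seed.
#' @param inputs constant external-input vector (default 1 per input).
#' @return gene x time fold-change matrix (class `TimecourseObservations`)
#'   with attributes `noise_sd` and `seed`; all values positive, t = 0
#'   column exactly 1.
#' @export
generate_timecourse <- function(spec, true_params = NULL,
                                times = c(0, 24, 48, 72),
                                noise_sd = 0.05, seed = 1, inputs = NULL) {
  stopifnot(inherits(spec, "CellModelSpec"), noise_sd >= 0)
  if (is.null(inputs))
    inputs <- stats::setNames(rep(1, length(spec$input_names)),
                              spec$input_names)
  pars <- spec$network$parameters
  if (!is.null(true_params)) pars[names(true_params)] <- true_params
  sim_times <- sort(unique(c(times, seq(min(times), max(times),
                                        length.out = 25))))
  traj <- simulate_network(spec$network, parameters = pars, inputs = inputs,
                           times = sim_times)
  fc <- observables(spec, traj, times)
  if (noise_sd > 0) {
    eps <- with_seed(seed,
      matrix(stats::rlnorm(length(fc), meanlog = 0, sdlog = noise_sd),
             nrow = nrow(fc)))
    fc <- fc * eps
  }
  fc[, 1] <- 1   # fold-change anchor
  structure(fc, noise_sd = noise_sd, seed = seed,
            class = c("TimecourseObservations", class(fc)))
}

#' Multiplicatively perturbed truth parameters
#'
#' Each selected parameter is multiplied by an independent uniform draw
#' from `factor_range`; used to create estimation test problems whose
#' ground truth is known.
#'
#' @param spec a [cell_model_spec()].
#' @param factor_range `c(lo, hi)` with `0 < lo <= hi`.
#' @param seed integer seed.
#' @param parameters names of parameters to perturb (default: all).
#' @return named numeric vector of perturbed (strictly positive) values.
#' @export
perturbed_truth <- function(spec, factor_range = c(0.5, 2), seed = 1,
                            parameters = NULL) {
  stopifnot(inherits(spec, "CellModelSpec"),
            factor_range[1] > 0, factor_range[2] >= factor_range[1])
  base <- spec$network$parameters
  if (is.null(parameters)) parameters <- names(base)
  stopifnot(all(parameters %in% names(base)))
  fac <- with_seed(seed,
    stats::runif(length(parameters), factor_range[1], factor_range[2]))
  stats::setNames(base[parameters] * fac, parameters)
}

# rejection-sample positions uniformly inside a sphere of radius R (same
# length unit as R), keeping pairwise center distances above
# 0.5*(r_i + r_j) and each whole cell (plus a one-radius margin) inside
# the sphere; radii supplied in the same unit as R
place_cells <- function(radii, R, max_tries = 1e4) {
  n <- length(radii)
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    Ri <- R - 2 * radii[i]
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3, -R, R)
      if (sum(p^2) >= Ri^2) next
      if (i > 1) {
        d <- sqrt(colSums((t(pos[seq_len(i - 1), , drop = FALSE]) - p)^2))
        if (any(d < 0.5 * (radii[seq_len(i - 1)] + radii[i]))) next
      }
      pos[i, ] <- p
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place cells without overlap: domain too dense",
           call. = FALSE)
  }
  pos
}

#' Seeded random tumor fixture
#'
#' Places cancer cells and CAFs uniformly at random (rejection sampling)
#' inside a sphere, with no two cells overlapping by more than half their
#' summed radii.
#'
#' @param n_cancer,n_caf cell counts (>= 0).
#' @param radius_cm domain radius in cm (default 2).
#' @param seed integer seed.
#' @param r_cancer_um,r_caf_um cell radii in micrometers (defaults 8, 7).
#' @return data.frame with columns `id`, `kind`, `x`, `y`, `z` (micrometer),
#'   `radius` (micrometer).
#' @export
make_fixture_tumor <- function(n_cancer, n_caf, radius_cm = 2, seed = 1,
                               r_cancer_um = 8, r_caf_um = 7) {
  stopifnot(n_cancer >= 0, n_caf >= 0)
  n <- n_cancer + n_caf
  kind <- rep(c("cancer", "caf"), c(n_cancer, n_caf))
  radii <- rep(c(r_cancer_um, r_caf_um), c(n_cancer, n_caf))
  R_um <- radius_cm * 1e4
  pos <- if (n > 0) with_seed(seed, place_cells(radii, R_um)) else
    matrix(numeric(0), 0, 3)
  data.frame(id = seq_len(n), kind = kind,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             radius = radii, stringsAsFactors = FALSE)
}

#' Read/write observation tables
#'
#' Delimited (tab-separated) long-format tables with columns `gene`,
#' `time_h`, `value` -- the interchange format between the synthetic-data
#' generator and the estimation machinery.
#'
#' @param observations gene x time fold-change matrix.
#' @param path file path.
#' @export
write_observations <- function(observations, path) {
  df <- data.frame(
    gene = rep(rownames(observations), ncol(observations)),
    time_h = rep(as.numeric(colnames(observations)),
                 each = nrow(observations)),
    value = as.numeric(observations))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @return `read_observations()`: gene x time matrix with times as column
#'   names.
#' @export
read_observations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "time_h", "value") %in% names(df)))
  genes <- unique(df$gene)
  times <- sort(unique(df$time_h))
  out <- matrix(NA_real_, length(genes), length(times),
                dimnames = list(genes, times))
  for (i in seq_len(nrow(df)))
    out[df$gene[i], as.character(df$time_h[i])] <- df$value[i]
  out
}
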