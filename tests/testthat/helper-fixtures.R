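# Small fixture models shared across tests; everything is built in code.

# one-species exponential decay network, dx/dt = -k x
make_decay_network <- function(k = 0.3, x0 = 1) {
  reaction_network(
    list(species_spec("x", "internal", x0)),
    list(reaction("d1", rate_law("mass_action", "k", c(x = 1)),
                  c(x = -1))),
    c(k = k))
}

# reversible receptor-ligand binding: 2 x1 + xu3 <-> x2, no other fluxes;
# conserves x1 + 2*x2 and xu3 + x2
make_binding_network <- function(kon = 0.1, koff = 0.05) {
  reaction_network(
    list(species_spec("x1", "internal", 1),
         species_spec("xu3", "internal", 2),
         species_spec("x2", "internal", 0)),
    list(reaction("v3", rate_law("mass_action", "k2p",
                                 c(xu3 = 1, x1 = 2)),
                  c(x1 = -2, xu3 = -1, x2 = 1)),
         reaction("v4", rate_law("mass_action", "k2m", c(x2 = 1)),
                  c(x2 = -1, x1 = 2, xu3 = 1))),
    c(k2p = kon, k2m = koff))
}

# 1-state linear cell model used for the Kalman-filter oracle
make_linear_model <- function(a = 0.3) {
  net <- make_decay_network(k = a)
  cell_model_spec(net, c(SMAD7 = "x"), character(0), "cancer")
}

# hand-rolled discrete Kalman filter on the exactly discretized scalar
# system x' = exp(-a dt) x, measurement y = x/x0, matching the hybrid
# filter's noise bookkeeping (process noise q per hour added at prediction)
scalar_kf <- function(a, times, obs, m0, P0, q, R, x0 = 1) {
  m <- m0; P <- P0; H <- 1 / x0
  for (k in seq_along(times)) {
    if (k > 1) {
      dt <- times[k] - times[k - 1]
      F <- exp(-a * dt)
      m <- F * m
      P <- F^2 * P + q * dt
    }
    S <- H^2 * P + R
    K <- P * H / S
    m <- m + K * (obs[k] - H * m)
    P <- P - K * S * K
  }
  list(mean = m, var = P)
}

# random nonnegative concentration vector over given names
random_conc <- function(names, max = 3) {
  stats::setNames(stats::runif(length(names), 0, max), names)
}
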