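# Independent oracle for the published rate tables: closed-form expression
# strings per printed reaction, evaluated with eval() on probe inputs and
# compared against evaluate_rate(). Duplicate labels (the two w3
# association routes) are listed in table order.

printed_rate_formulas <- function(cell_type) {
  if (cell_type == "cancer") list(
    v1 = "k1p*x1", v2 = "k1m*x1",
    v3 = "k2p*xu3*x1^2", v3p = "k2p*xu1*x1^2",
    v4 = "k2m*x2",
    v5 = "k3p*x3", v6 = "k3m*x3",
    v7 = "k4p*x5", v8 = "k4m*x5",
    v9 = "k5p*x2*x3/(x3+Ks1)", v10 = "k5m*x4",
    v11 = "k6p*x4*x5", v12 = "k6m*x6",
    v13 = "ki7*x6", v14 = "ke7*x7", v15 = "k7m*x7",
    v16 = "k8p*x7", v17 = "k8m*x8", v18 = "k8im*x8",
    v19 = "k9p*x7", v20 = "k9m*xu1",
    v21 = "k10p*x7", v22 = "k10m*xu2",
    v23 = "k11p*x7", v24 = "k11m*x9")
  else list(
    v23 = "k11p*x7", v24 = "k11m*xu4",
    w1 = "h1p*x10", w2 = "h1m*x10",
    w3 = c("h2p*x10*xu2", "h2p*x10*x9"),   # paracrine then autocrine route
    w4 = "h2m*x11",
    w5 = "h3p*x12", w6 = "h3m*x12",
    w7 = "h4p*x11*x12/(x12+Ks2)", w8 = "h4m*x13",
    w9 = "h5p*x14", w10 = "h5m*x14",
    w11 = "h6p*x14/(x14+Ks3)", w12 = "h6m*x15",
    w13 = "h7p*x16", w14 = "h7m*x17", w15 = "h7im*x17",
    w16 = "hi8*x15", w17 = "he8*x16",
    w18 = "h9p*x16", w19 = "h9m*x18",
    w20 = "h10p*x16", w22 = "h10im*x18",
    w23 = "h11p*x19", w24 = "h11m*x19", w25 = "h11im*x19",
    z1 = "g1p*x4*x15", z2 = "g1m*x20",
    z3 = "gi*x20", z4 = "ge*x21",
    z5 = "g2p*x21", z6 = "g2m*x22")
}

# check each printed reaction of a model against its formula string at
# several random probe points; returns number of rows checked
check_printed_rows <- function(spec, seed = 99) {
  net <- spec$network
  expected <- printed_rate_formulas(spec$cell_type)
  used <- stats::setNames(integer(length(expected)), names(expected))
  n_checked <- 0
  set.seed(seed)
  for (r in net$reactions) {
    if (r$provenance != "printed") next
    forms <- expected[[r$name]]
    if (is.null(forms)) stop("no printed formula listed for ", r$name)
    used[r$name] <- used[r$name] + 1
    form <- forms[used[r$name]]
    expr <- parse(text = form)[[1]]
    for (probe in 1:3) {
      conc <- random_conc(species_names(net))
      env <- as.list(c(conc, net$parameters))
      want <- eval(expr, env)
      got <- evaluate_rate(r$rate, conc, net$parameters)
      testthat::expect_equal(got, want, tolerance = 1e-12, label = r$name)
    }
    n_checked <- n_checked + 1
  }
  # every printed row must have been matched exactly as often as listed
  testthat::expect_equal(unname(used),
                         vapply(expected, length, 0, USE.NAMES = FALSE))
  n_checked
}
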