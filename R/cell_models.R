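#' Intracellular signaling models of the cancer cell and the CAF
#'
#' Builders for the two cell-type networks at the core of the simulator:
#'
#' * the cancer-cell model couples the TGF-beta/SMAD pathway (receptor,
#'   ligand-receptor complex, SMAD3 phosphorylation, pSMAD3-SMAD4 complex,
#'   nuclear import, SMAD7 negative feedback, and the TGF-beta / LIF / CXCR4
#'   target genes) to a CXCL12-CXCR4 -> PI3K/Akt -> NF-kB -> MMP cascade;
#'   21 dynamical states driven by two external inputs (CAF-derived
#'   TGF-beta `xu3` and CXCL12 `xu4`);
#' * the CAF model couples a TGF-beta/SMAD pathway mirror to the
#'   LIF -> JAK/STAT pathway with SOCS3/SHP1 negative regulation, STAT
#'   acetylation, and the pSMAD3-pSTAT crosstalk complex that drives SNAIL;
#'   26 dynamical states driven by cancer-derived TGF-beta `xu1` and LIF
#'   `xu2`.
#'
#' The downstream CXCL12 cascade in the cancer cell, and a handful of CAF
#' species, are not part of the published rate tables; those reactions are
#' flagged `provenance = "reconstructed"` in the network objects and in the
#' serialized definitions.
#'
#' @name cell-models
NULL

#' Construct a cell-model specification
#'
#' @param network a [reaction_network()].
#' @param observable_map named character vector mapping measured genes
#'   (`SMAD7`, `TGFb`, `LIF`, `CXCL12`) to network species.
#' @param input_names ordered external-input species.
#' @param cell_type `"cancer"` or `"caf"`.
#' @return object of class `CellModelSpec`.
#' @export
cell_model_spec <- function(network, observable_map, input_names,
                            cell_type = c("cancer", "caf")) {
  cell_type <- match.arg(cell_type)
  stopifnot(all(observable_map %in% species_names(network)),
            all(input_names %in% input_species(network)))
  structure(list(network = network, observable_map = observable_map,
                 input_names = input_names, cell_type = cell_type),
            class = "CellModelSpec")
}

#' @export
print.CellModelSpec <- function(x, ...) {
  cat(sprintf("<CellModelSpec %s> %d states, inputs: %s\n", x$cell_type,
              length(dynamical_species(x$network)),
              paste(x$input_names, collapse = ", ")))
  invisible(x)
}

# shorthand constructors used by the builders
.ma <- function(k, ...) {
  ord <- c(...)
  rate_law("mass_action", k, if (length(ord)) ord else NULL)
}
.sat <- function(k, modifiers, sat_sp, K)
  rate_law("saturating", k, modifiers, sat_sp, K)
.rx <- function(name, rate, stoich, desc, prov = "printed")
  reaction(name, rate, stoich, description = desc, provenance = prov)

# production term of the form k*x (self-proportional, as printed) or a
# zero-order source when constitutive_production is on
.prod_term <- function(k, sp, constitutive) {
  if (constitutive) rate_law("constant_source", k) else .ma(k, stats::setNames(1, sp))
}

#' Build the cancer-cell signaling network
#'
#' All published cancer-cell reactions (v1--v24 and the autocrine binding
#' route v3') plus the reconstructed CXCL12-CXCR4/PI3K/Akt/NF-kB/MMP
#' cascade; 21 dynamical species. Default kinetic constants are 0.1 (h^-1,
#' or a.u.^-1 h^-1 for bimolecular steps), half-constants 1.0 a.u.;
#' non-complex species start at 1.0 a.u., complexes at 0 -- placeholders to
#' be refined by estimation.
#'
#' @param constitutive_production if `TRUE`, production terms printed as
#'   proportional to their own product (e.g. receptor production `k1p*x1`)
#'   are replaced by zero-order sources of the same constant; default
#'   `FALSE` (rate laws exactly as printed).
#' @return a [cell_model_spec()] for the cancer cell.
#' @export
build_cancer_cell_network <- function(constitutive_production = FALSE) {
  cp <- constitutive_production
  species <- c(
    lapply(list(
      c("x1", "TGFbR", 1), c("x2", "TGFb.TGFbR", 0), c("x3", "SMAD3c", 1),
      c("x4", "pSMAD3", 0), c("x5", "SMAD4", 1), c("x6", "pSMAD3.4c", 0),
      c("x7", "pSMAD3.4n", 0), c("x8", "SMAD7", 1), c("x9", "CXCR4", 1)),
      function(s) species_spec(s[1], "internal", as.numeric(s[3]), s[2])),
    list(species_spec("xu1", "secreted-signal", 1, "TGFb (cancer)"),
         species_spec("xu2", "secreted-signal", 1, "LIF (cancer)")),
    lapply(list(
      c("x10", "CXCL12.CXCR4", 0), c("x11", "PI3K", 1), c("x12", "pPI3K", 0),
      c("x13", "Akt", 1), c("x14", "pAkt", 0), c("x15", "NFkBc", 1),
      c("x16", "NFkBn", 0), c("x17", "IkB", 1), c("x18", "MMPintra", 0)),
      function(s) species_spec(s[1], "internal", as.numeric(s[3]), s[2])),
    list(species_spec("x19", "secreted-signal", 0, "MMPsecreted"),
         species_spec("xu3", "external-input", 0, "TGFb (CAF)"),
         species_spec("xu4", "external-input", 0, "CXCL12")))

  rxs <- list(
    .rx("v1", .prod_term("k1p", "x1", cp), c(x1 = 1),
        "Production of TGFb receptor"),
    .rx("v2", .ma("k1m", x1 = 1), c(x1 = -1), "Degradation of TGFb receptor"),
    .rx("v3", .ma("k2p", xu3 = 1, x1 = 2), c(x1 = -2, x2 = 1),
        "Association of TGFb-TGFbR complex (paracrine)"),
    .rx("v3p", .ma("k2p", xu1 = 1, x1 = 2), c(xu1 = -1, x1 = -2, x2 = 1),
        "Association of TGFb-TGFbR complex (autocrine)"),
    .rx("v4", .ma("k2m", x2 = 1), c(x2 = -1, x1 = 2),
        "Dissociation of TGFb-receptor complex"),
    .rx("v5", .prod_term("k3p", "x3", cp), c(x3 = 1),
        "Production of cytoplasmic SMAD3"),
    .rx("v6", .ma("k3m", x3 = 1), c(x3 = -1),
        "Degradation of cytoplasmic SMAD3"),
    .rx("v7", .prod_term("k4p", "x5", cp), c(x5 = 1),
        "Production of cytoplasmic SMAD4"),
    .rx("v8", .ma("k4m", x5 = 1), c(x5 = -1),
        "Degradation of cytoplasmic SMAD4"),
    .rx("v9", .sat("k5p", c(x2 = 1), "x3", "Ks1"), c(x3 = -1, x4 = 1),
        "Phosphorylation of SMAD3"),
    .rx("v10", .ma("k5m", x4 = 1), c(x4 = -1, x3 = 1),
        "Dephosphorylation of SMAD3"),
    .rx("v11", .ma("k6p", x4 = 1, x5 = 1), c(x4 = -1, x5 = -1, x6 = 1),
        "Association of pSMAD3-4 complex"),
    .rx("v12", .ma("k6m", x6 = 1), c(x6 = -1, x4 = 1, x5 = 1),
        "Dissociation of pSMAD3-4 complex"),
    .rx("v13", .ma("ki7", x6 = 1), c(x6 = -1, x7 = 1),
        "Nuclear import of pSMAD3-4 complex"),
    .rx("v14", .ma("ke7", x7 = 1), c(x7 = -1, x6 = 1),
        "Nuclear export of pSMAD3-4 complex"),
    .rx("v15", .ma("k7m", x7 = 1), c(x7 = -1),
        "Degradation of pSMAD3-4 complex"),
    .rx("v16", .ma("k8p", x7 = 1), c(x8 = 1),
        "Production of SMAD7 in the pathway"),
    .rx("v17", .ma("k8m", x8 = 1), c(x8 = -1), "Degradation of SMAD7"),
    .rx("v18", .ma("k8im", x8 = 1), c(x4 = -1),
        "Inhibitory effect of SMAD7 on pSMAD3"),
    .rx("v19", .ma("k9p", x7 = 1), c(xu1 = 1),
        "Production of TGFb in the pathway"),
    .rx("v20", .ma("k9m", xu1 = 1), c(xu1 = -1), "Degradation of TGFb"),
    .rx("v21", .ma("k10p", x7 = 1), c(xu2 = 1),
        "Production of LIF in the pathway"),
    .rx("v22", .ma("k10m", xu2 = 1), c(xu2 = -1), "Degradation of LIF"),
    .rx("v23", .ma("k11p", x7 = 1), c(x9 = 1),
        "Production of CXCR4 in the pathway"),
    .rx("v24", .ma("k11m", x9 = 1), c(x9 = -1), "Degradation of CXCR4"),
    # --- reconstructed CXCL12 -> PI3K/Akt -> NF-kB -> MMP cascade ---
    .rx("v25", .ma("k12p", xu4 = 1, x9 = 1), c(x9 = -1, x10 = 1),
        "Association of CXCL12-CXCR4 complex", prov = "reconstructed"),
    .rx("v26", .ma("k12m", x10 = 1), c(x10 = -1, x9 = 1),
        "Dissociation of CXCL12-CXCR4 complex", prov = "reconstructed"),
    .rx("v27", .prod_term("k13p", "x11", cp), c(x11 = 1),
        "Production of PI3K", prov = "reconstructed"),
    .rx("v28", .ma("k13m", x11 = 1), c(x11 = -1),
        "Degradation of PI3K", prov = "reconstructed"),
    .rx("v29", .sat("k14p", c(x10 = 1), "x11", "Ks4"), c(x11 = -1, x12 = 1),
        "Phosphorylation of PI3K by CXCL12-CXCR4 complex",
        prov = "reconstructed"),
    .rx("v30", .ma("k14m", x12 = 1), c(x12 = -1, x11 = 1),
        "Dephosphorylation of pPI3K", prov = "reconstructed"),
    .rx("v31", .prod_term("k15p", "x13", cp), c(x13 = 1),
        "Production of Akt", prov = "reconstructed"),
    .rx("v32", .ma("k15m", x13 = 1), c(x13 = -1),
        "Degradation of Akt", prov = "reconstructed"),
    .rx("v33", .sat("k16p", c(x12 = 1), "x13", "Ks5"), c(x13 = -1, x14 = 1),
        "Phosphorylation of Akt by pPI3K", prov = "reconstructed"),
    .rx("v34", .ma("k16m", x14 = 1), c(x14 = -1, x13 = 1),
        "Dephosphorylation of pAkt", prov = "reconstructed"),
    .rx("v35", .sat("k17p", c(x14 = 1), "x15", "Ks6"), c(x15 = -1, x16 = 1),
        "Activation and nuclear import of NF-kB by pAkt",
        prov = "reconstructed"),
    .rx("v36", .ma("k17m", x16 = 1), c(x16 = -1, x15 = 1),
        "Nuclear export of NF-kB", prov = "reconstructed"),
    .rx("v37", .ma("k18p", x16 = 1), c(x17 = 1),
        "Production of IkB downstream the pathway", prov = "reconstructed"),
    .rx("v38", .ma("k18m", x17 = 1), c(x17 = -1),
        "Degradation of IkB", prov = "reconstructed"),
    .rx("v39", .ma("k18im", x17 = 1), c(x16 = -1),
        "Inhibitory effect of IkB on nuclear NF-kB", prov = "reconstructed"),
    .rx("v40", .ma("k19p", x16 = 1), c(x18 = 1),
        "Production of MMP in the pathway", prov = "reconstructed"),
    .rx("v41", .ma("k19m", x18 = 1), c(x18 = -1),
        "Degradation of intracellular MMP", prov = "reconstructed"),
    .rx("v42", .ma("k20p", x18 = 1), c(x18 = -1, x19 = 1),
        "Secretion of MMP", prov = "reconstructed"),
    .rx("v43", .ma("k20m", x19 = 1), c(x19 = -1),
        "Degradation of secreted MMP", prov = "reconstructed"))

  pars <- default_parameters("cancer")
  net <- reaction_network(species, rxs, pars)
  cell_model_spec(
    net,
    observable_map = c(SMAD7 = "x8", TGFb = "xu1", LIF = "xu2",
                       CXCL12 = "x9"),
    input_names = c("xu3", "xu4"),
    cell_type = "cancer")
}

#' Build the CAF signaling network
#'
#' All published CAF reactions (w1--w25 without the skipped w21, the
#' crosstalk reactions z1--z6, and the CXCL12 production/degradation pair)
#' over the LIF/JAK/STAT arm, plus a reconstructed TGF-beta/SMAD pathway
#' mirror (whose detailed listing is not published) terminating in the
#' CXCL12 and TGF-beta target genes, and a reconstructed pair of cytoplasmic
#' inhibitory complexes (SMAD7 bound to the receptor and to pSMAD3)
#' completing the 26 dynamical states.
#'
#' @inheritParams build_cancer_cell_network
#' @return a [cell_model_spec()] for the CAF.
#' @export
build_caf_network <- function(constitutive_production = FALSE) {
  cp <- constitutive_production
  species <- c(
    lapply(list(
      c("x1", "TGFbR_caf", 1), c("x2", "TGFb.TGFbR_caf", 0),
      c("x3", "SMAD3c_caf", 1), c("x4", "pSMAD3_caf", 0),
      c("x5", "SMAD4_caf", 1), c("x6", "pSMAD3.4c_caf", 0),
      c("x7", "pSMAD3.4n_caf", 0), c("x8", "SMAD7_caf", 1)),
      function(s) species_spec(s[1], "internal", as.numeric(s[3]), s[2])),
    list(species_spec("x9", "internal", 1, "LIFcaf")),
    lapply(list(
      c("x10", "LIFR", 1), c("x11", "LIF.LIFR", 0), c("x12", "JAK", 1),
      c("x13", "pJAK", 0), c("x14", "STAT", 1), c("x15", "pSTAT", 0),
      c("x16", "pSTATn", 0), c("x17", "pSTATn.ac", 0), c("x18", "SOCS3", 1),
      c("x19", "SHP1", 1), c("x20", "pSMAD3.pSTATc", 0),
      c("x21", "pSMAD3.pSTATn", 0), c("x22", "SNAIL", 1)),
      function(s) species_spec(s[1], "internal", as.numeric(s[3]), s[2])),
    list(species_spec("xu3", "secreted-signal", 1, "TGFb (CAF)"),
         species_spec("xu4", "secreted-signal", 1, "CXCL12"),
         species_spec("x23", "internal", 0, "SMAD7.TGFbR_caf"),
         species_spec("x24", "internal", 0, "pSMAD3.SMAD7_caf"),
         species_spec("xu1", "external-input", 0, "TGFb (cancer)"),
         species_spec("xu2", "external-input", 0, "LIF (cancer)")))

  rxs <- list(
    # --- published rows ---
    .rx("v23", .ma("k11p", x7 = 1), c(xu4 = 1),
        "Production of CXCL12 in the pathway"),
    .rx("v24", .ma("k11m", xu4 = 1), c(xu4 = -1), "Degradation of CXCL12"),
    .rx("w1", .prod_term("h1p", "x10", cp), c(x10 = 1),
        "Production of LIF receptor"),
    .rx("w2", .ma("h1m", x10 = 1), c(x10 = -1),
        "Degradation of LIF receptor"),
    .rx("w3", .ma("h2p", x10 = 1, xu2 = 1), c(x10 = -1, x11 = 1),
        "Association of LIF-LIFreceptor complex (paracrine)"),
    .rx("w3", .ma("h2p", x10 = 1, x9 = 1), c(x10 = -1, x9 = -1, x11 = 1),
        "Association of LIFcaf-LIFreceptor complex (autocrine)"),
    .rx("w4", .ma("h2m", x11 = 1), c(x11 = -1, x10 = 1),
        "Dissociation of LIF-LIFreceptor complex"),
    .rx("w5", .prod_term("h3p", "x12", cp), c(x12 = 1), "Production of JAK"),
    .rx("w6", .ma("h3m", x12 = 1), c(x12 = -1), "Degradation of JAK"),
    .rx("w7", .sat("h4p", c(x11 = 1), "x12", "Ks2"), c(x12 = -1, x13 = 1),
        "Phosphorylation of JAK by LIF-receptor complex"),
    .rx("w8", .ma("h4m", x13 = 1), c(x13 = -1, x12 = 1),
        "Dephosphorylation of pJAK"),
    .rx("w9", .prod_term("h5p", "x14", cp), c(x14 = 1), "Production of STAT"),
    .rx("w10", .ma("h5m", x14 = 1), c(x14 = -1), "Degradation of STAT"),
    .rx("w11", .sat("h6p", NULL, "x14", "Ks3"), c(x14 = -1, x15 = 1),
        "Phosphorylation of STAT by pJAK"),
    .rx("w12", .ma("h6m", x15 = 1), c(x15 = -1, x14 = 1),
        "Dephosphorylation of pSTAT"),
    .rx("w13", .ma("h7p", x16 = 1), c(x16 = -1, x17 = 1),
        "Acetylation of pSTATn"),
    .rx("w14", .ma("h7m", x17 = 1), c(x17 = -1, x16 = 1),
        "Deacetylation of pSTATn"),
    .rx("w15", .ma("h7im", x17 = 1), c(x19 = -1),
        "Inhibitory effect of pSTATnac on SHP1"),
    .rx("w16", .ma("hi8", x15 = 1), c(x15 = -1, x16 = 1),
        "Nuclear import of pSTAT"),
    .rx("w17", .ma("he8", x16 = 1), c(x16 = -1, x15 = 1),
        "Nuclear export of pSTAT"),
    .rx("w18", .ma("h9p", x16 = 1), c(x18 = 1),
        "Production of SOCS3 downstream the pathway"),
    .rx("w19", .ma("h9m", x18 = 1), c(x18 = -1), "Degradation of SOCS3"),
    .rx("w20", .ma("h10p", x16 = 1), c(x8 = 1),
        "Production of SMAD7 downstream the pathway"),
    .rx("w22", .ma("h10im", x18 = 1), c(x15 = -1),
        "Inhibitory effect of SOCS3 on STAT phosphorylation"),
    .rx("w23", .prod_term("h11p", "x19", cp), c(x19 = 1),
        "Production of SHP1"),
    .rx("w24", .ma("h11m", x19 = 1), c(x19 = -1), "Degradation of SHP1"),
    .rx("w25", .ma("h11im", x19 = 1), c(x15 = -1),
        "Inhibitory effect of SHP1 on STAT phosphorylation"),
    .rx("z1", .ma("g1p", x4 = 1, x15 = 1), c(x4 = -1, x15 = -1, x20 = 1),
        "pSMAD3-pSTAT binding"),
    .rx("z2", .ma("g1m", x20 = 1), c(x20 = -1, x4 = 1, x15 = 1),
        "pSMAD3-pSTAT unbinding"),
    .rx("z3", .ma("gi", x20 = 1), c(x20 = -1, x21 = 1),
        "Translocation of pSMAD3-pSTAT to nucleus"),
    .rx("z4", .ma("ge", x21 = 1), c(x21 = -1, x20 = 1),
        "Translocation of pSMAD3-pSTAT to cytoplasm"),
    .rx("z5", .ma("g2p", x21 = 1), c(x22 = 1),
        "Production of SNAIL in the pathway"),
    .rx("z6", .ma("g2m", x22 = 1), c(x22 = -1), "Degradation of SNAIL"),
    # --- reconstructed TGF-beta pathway mirror ---
    .rx("m1", .prod_term("b1p", "x1", cp), c(x1 = 1),
        "Production of TGFb receptor (CAF)", prov = "reconstructed"),
    .rx("m2", .ma("b1m", x1 = 1), c(x1 = -1),
        "Degradation of TGFb receptor (CAF)", prov = "reconstructed"),
    .rx("m3", .ma("b2p", xu1 = 1, x1 = 2), c(x1 = -2, x2 = 1),
        "Association of TGFb-TGFbR complex (paracrine, CAF)",
        prov = "reconstructed"),
    .rx("m3p", .ma("b2p", xu3 = 1, x1 = 2), c(xu3 = -1, x1 = -2, x2 = 1),
        "Association of TGFb-TGFbR complex (autocrine, CAF)",
        prov = "reconstructed"),
    .rx("m4", .ma("b2m", x2 = 1), c(x2 = -1, x1 = 2),
        "Dissociation of TGFb-receptor complex (CAF)",
        prov = "reconstructed"),
    .rx("m5", .prod_term("b3p", "x3", cp), c(x3 = 1),
        "Production of cytoplasmic SMAD3 (CAF)", prov = "reconstructed"),
    .rx("m6", .ma("b3m", x3 = 1), c(x3 = -1),
        "Degradation of cytoplasmic SMAD3 (CAF)", prov = "reconstructed"),
    .rx("m7", .prod_term("b4p", "x5", cp), c(x5 = 1),
        "Production of cytoplasmic SMAD4 (CAF)", prov = "reconstructed"),
    .rx("m8", .ma("b4m", x5 = 1), c(x5 = -1),
        "Degradation of cytoplasmic SMAD4 (CAF)", prov = "reconstructed"),
    .rx("m9", .sat("b5p", c(x2 = 1), "x3", "Ks7"), c(x3 = -1, x4 = 1),
        "Phosphorylation of SMAD3 (CAF)", prov = "reconstructed"),
    .rx("m10", .ma("b5m", x4 = 1), c(x4 = -1, x3 = 1),
        "Dephosphorylation of SMAD3 (CAF)", prov = "reconstructed"),
    .rx("m11", .ma("b6p", x4 = 1, x5 = 1), c(x4 = -1, x5 = -1, x6 = 1),
        "Association of pSMAD3-4 complex (CAF)", prov = "reconstructed"),
    .rx("m12", .ma("b6m", x6 = 1), c(x6 = -1, x4 = 1, x5 = 1),
        "Dissociation of pSMAD3-4 complex (CAF)", prov = "reconstructed"),
    .rx("m13", .ma("bi7", x6 = 1), c(x6 = -1, x7 = 1),
        "Nuclear import of pSMAD3-4 complex (CAF)", prov = "reconstructed"),
    .rx("m14", .ma("be7", x7 = 1), c(x7 = -1, x6 = 1),
        "Nuclear export of pSMAD3-4 complex (CAF)", prov = "reconstructed"),
    .rx("m15", .ma("b7m", x7 = 1), c(x7 = -1),
        "Degradation of pSMAD3-4 complex (CAF)", prov = "reconstructed"),
    .rx("m16", .ma("b8p", x7 = 1), c(x8 = 1),
        "Production of SMAD7 in the pathway (CAF)", prov = "reconstructed"),
    .rx("m17", .ma("b8m", x8 = 1), c(x8 = -1),
        "Degradation of SMAD7 (CAF)", prov = "reconstructed"),
    .rx("m18", .ma("b8im", x8 = 1), c(x4 = -1),
        "Inhibitory effect of SMAD7 on pSMAD3 (CAF)",
        prov = "reconstructed"),
    .rx("m19", .ma("b9p", x7 = 1), c(xu3 = 1),
        "Production of TGFb in the pathway (CAF)", prov = "reconstructed"),
    .rx("m20", .ma("b9m", xu3 = 1), c(xu3 = -1),
        "Degradation of TGFb (CAF)", prov = "reconstructed"),
    .rx("m21", .ma("b10p", x7 = 1), c(x9 = 1),
        "Production of LIF in the pathway (CAF, autocrine)",
        prov = "reconstructed"),
    .rx("m22", .ma("b10m", x9 = 1), c(x9 = -1),
        "Degradation of LIFcaf", prov = "reconstructed"),
    # --- reconstructed cytoplasmic inhibitory complex pair ---
    .rx("m23", .ma("c1p", x1 = 1, x8 = 1), c(x1 = -1, x8 = -1, x23 = 1),
        "Association of SMAD7-TGFbR inhibitory complex",
        prov = "reconstructed"),
    .rx("m24", .ma("c1m", x23 = 1), c(x23 = -1, x1 = 1, x8 = 1),
        "Dissociation of SMAD7-TGFbR inhibitory complex",
        prov = "reconstructed"),
    .rx("m25", .ma("c2p", x4 = 1, x8 = 1), c(x4 = -1, x8 = -1, x24 = 1),
        "Association of pSMAD3-SMAD7 inhibitory complex",
        prov = "reconstructed"),
    .rx("m26", .ma("c2m", x24 = 1), c(x24 = -1, x4 = 1, x8 = 1),
        "Dissociation of pSMAD3-SMAD7 inhibitory complex",
        prov = "reconstructed"),
    .rx("m27", .ma("c3m", x23 = 1), c(x23 = -1),
        "Degradation of SMAD7-TGFbR complex", prov = "reconstructed"),
    .rx("m28", .ma("c4m", x24 = 1), c(x24 = -1),
        "Degradation of pSMAD3-SMAD7 complex", prov = "reconstructed"))

  pars <- default_parameters("caf")
  net <- reaction_network(species, rxs, pars)
  cell_model_spec(
    net,
    observable_map = c(SMAD7 = "x8", TGFb = "xu3", LIF = "x9",
                       CXCL12 = "xu4"),
    input_names = c("xu1", "xu2"),
    cell_type = "caf")
}

#' Default kinetic parameter tables
#'
#' Versioned placeholder defaults used until estimation. The baseline is
#' 0.1 for every rate constant (h^-1; a.u.^-1 h^-1 for bimolecular steps)
#' and 1.0 a.u. for every half-constant, adjusted so that the networks show
#' the qualitative behavior expected of stimulated cells: receptor and
#' substrate synthesis slightly exceeds turnover (so ligand binding does
#' not exhaust the pools), phosphorylation/complex-formation steps are an
#' order of magnitude faster than the baseline, and target-gene production
#' outweighs target-gene decay (so SMAD7, TGF-beta, LIF and CXCL12 rise
#' above baseline under stimulation instead of draining away).
#'
#' @param cell_type `"cancer"` or `"caf"`.
#' @return named numeric vector of parameter values.
#' @export
default_parameters <- function(cell_type = c("cancer", "caf")) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "cancer") {
    ks <- c("Ks1", "Ks4", "Ks5", "Ks6")
    rates <- c("k1p", "k1m", "k2p", "k2m", "k3p", "k3m", "k4p", "k4m",
               "k5p", "k5m", "k6p", "k6m", "ki7", "ke7", "k7m", "k8p",
               "k8m", "k8im", "k9p", "k9m", "k10p", "k10m", "k11p", "k11m",
               "k12p", "k12m", "k13p", "k13m", "k14p", "k14m", "k15p",
               "k15m", "k16p", "k16m", "k17p", "k17m", "k18p", "k18m",
               "k18im", "k19p", "k19m", "k20p", "k20m")
    overrides <- c(
      # sustained receptor / substrate pools
      k1p = 0.15, k1m = 0.05, k3p = 0.12, k3m = 0.05, k4p = 0.12,
      k4m = 0.05, k13p = 0.12, k13m = 0.05, k15p = 0.12, k15m = 0.05,
      # fast activation steps, slow nuclear export/decay
      k5p = 1.0, k6p = 1.0, ki7 = 0.5, ke7 = 0.05, k7m = 0.05,
      k14p = 1.0, k16p = 1.0, k17p = 1.0,
      # target genes: production above decay
      k8p = 1.0, k8m = 0.05, k9p = 1.0, k9m = 0.05, k10p = 1.0,
      k10m = 0.05, k11p = 1.0, k11m = 0.05, k19p = 1.0, k19m = 0.05,
      k20p = 0.2, k20m = 0.05,
      # weak inhibitory removal fluxes
      k8im = 0.01, k18im = 0.01)
  } else {
    ks <- c("Ks2", "Ks3", "Ks7")
    rates <- c("k11p", "k11m", "h1p", "h1m", "h2p", "h2m", "h3p", "h3m",
               "h4p", "h4m", "h5p", "h5m", "h6p", "h6m", "h7p", "h7m",
               "h7im", "hi8", "he8", "h9p", "h9m", "h10p", "h10im", "h11p",
               "h11m", "h11im", "g1p", "g1m", "gi", "ge", "g2p", "g2m",
               "b1p", "b1m", "b2p", "b2m", "b3p", "b3m", "b4p", "b4m",
               "b5p", "b5m", "b6p", "b6m", "bi7", "be7", "b7m", "b8p",
               "b8m", "b8im", "b9p", "b9m", "b10p", "b10m", "c1p", "c1m",
               "c2p", "c2m", "c3m", "c4m")
    overrides <- c(
      b1p = 0.15, b1m = 0.05, b3p = 0.12, b3m = 0.05, b4p = 0.12,
      b4m = 0.05, h1p = 0.15, h1m = 0.05, h5p = 0.12, h5m = 0.05,
      b5p = 1.0, b6p = 1.0, bi7 = 0.5, be7 = 0.05, b7m = 0.05,
      h4p = 1.0, h6p = 0.3,
      b8p = 1.0, b8m = 0.05, b9p = 1.0, b9m = 0.05, b10p = 1.0,
      b10m = 0.05, k11p = 1.0, k11m = 0.05,
      g1p = 0.5, gi = 0.5, ge = 0.05, g2p = 1.0, g2m = 0.05,
      b8im = 0.01, h7im = 0.01, h10im = 0.05, h11im = 0.05)
  }
  pars <- stats::setNames(c(rep(0.1, length(rates)), rep(1.0, length(ks))),
                          c(rates, ks))
  pars[names(overrides)] <- overrides
  pars
}

#' Map a trajectory to measured-gene fold changes
#'
#' Applies the model's observable map and normalizes each gene to its value
#' at the first requested time (fold change), matching how sparse expression
#' time courses are reported.
#'
#' @param spec a [cell_model_spec()].
#' @param traj a `Trajectory` covering the requested times.
#' @param times observation times in hours (default `c(0, 24, 48, 72)`).
#' @return gene x time matrix of fold changes (rows `SMAD7`, `TGFb`, `LIF`,
#'   `CXCL12`; columns named by time).
#' @export
observables <- function(spec, traj, times = c(0, 24, 48, 72)) {
  stopifnot(inherits(spec, "CellModelSpec"), inherits(traj, "Trajectory"))
  if (min(times) < min(traj$times) || max(times) > max(traj$times))
    stop("trajectory does not cover the requested times", call. = FALSE)
  genes <- names(spec$observable_map)
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(times),
                dimnames = list(genes, times))
  for (g in genes) {
    sp <- spec$observable_map[[g]]
    y <- stats::approx(traj$times, traj$values[, sp], xout = times)$y
    if (y[1] <= 0)
      stop(sprintf("zero baseline for gene %s: cannot form fold changes", g),
           call. = FALSE)
    out[g, ] <- y / y[1]
  }
  out
}

#' Reaction table of a cell model
#'
#' @param spec a [cell_model_spec()].
#' @return data.frame with one row per reaction: name, description,
#'   provenance, rate-law kind and rate constant.
#' @export
reaction_table <- function(spec) {
  net <- if (inherits(spec, "CellModelSpec")) spec$network else spec
  do.call(rbind, lapply(net$reactions, function(r)
    data.frame(name = r$name, description = r$description,
               kind = r$rate$kind, rate_constant = r$rate$rate_constant,
               provenance = r$provenance, stringsAsFactors = FALSE)))
}
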