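# Bundled network reconstruction, flux presets, and toy networks.

#' The bundled C. glutamicum central-metabolism network
#'
#' Loads the reconstructed atom-mapped network of C. glutamicum central
#' carbon metabolism (glycolysis, PPP, TCA cycle, anaplerosis, glyoxylate
#' shunt, protocatechuate degradation, amino acid synthesis, growth-scaled
#' biomass drains). After scrambling expansion the model has 87 reactions
#' (22 bidirectional), 45 balanced and 4 non-balanced pools, and 27 free
#' fluxes (7 net + 20 exchange) once uptakes and drains are fixed.
#'
#' @param expanded expand scrambling variants (default FALSE).
#' @return an `mfa_network`.
#' @export
cg_network <- function(expanded = FALSE) {
  path <- system.file("extdata", "cglutamicum_ccm_reconstruction.yaml",
                      package = "emuflux")
  if (!nzchar(path)) stop2("bundled network file not found")
  net <- load_network(path)
  if (expanded) net <- expand_scrambling(net)
  net
}

#' Fixed fluxes of the chemostat condition
#'
#' Biomass drains are the demand coefficients scaled by the growth rate;
#' uptake fluxes are the measured rates.
#'
#' @param model an `mfa_network` with a biomass demand table.
#' @param mu growth rate (1/h).
#' @param uptakes named vector of uptake fluxes (umol/gCDW/h) for the
#'   model's `fixed_uptakes`.
#' @return named vector of fixed net fluxes.
#' @export
fixed_fluxes <- function(model, mu, uptakes) {
  dem <- unlist(model$biomass$demand)
  drains <- if (length(dem)) {
    setNames(dem * mu, paste0(names(dem), "_bm"))
  } else numeric(0)
  need <- unlist(model$biomass$fixed_uptakes)
  if (!all(need %in% names(uptakes))) {
    stop2("uptakes must name: ", paste(need, collapse = ", "))
  }
  c(uptakes[need], drains)
}

#' Paper-like chemostat flux preset
#'
#' Free-flux values reproducing the reported flux map of the labeling
#' experiment at D = 0.4 1/h: one third of glucose routed through the
#' oxidative PPP, anaplerosis through pyruvate carboxylase with moderate
#' PEP carboxykinase back-cycling, inactive glyoxylate shunt and malic
#' enzyme, and moderate exchange fluxes on isomerases, transaminases and
#' the lower TCA cycle.
#'
#' @param basis `flux_basis` of [cg_network()].
#' @param mu growth rate (default 0.41 1/h).
#' @param v_glc glucose uptake (default 4086 umol/gCDW/h).
#' @param v_pca protocatechuate uptake (default 13 umol/gCDW/h).
#' @return a `flux_state`.
#' @export
cg_preset_flux <- function(basis, mu = 0.41, v_glc = 4086, v_pca = 13) {
  model <- cg_network()
  free <- c(zwf = 0.316 * v_glc, pck = 120, ppc = 0, mez = 0, aceA = 6,
            fbp = 0, co2_in = 50)
  exch <- c(pgi = 1000, fda = 500, tpi = 2000, gapdh = 2000, eno = 2000,
            rpe = 500, rpi = 500, tkt1 = 200, tal = 200, tkt2 = 200,
            acn = 500, sdh = 300, fumh = 1000, mqo = 1000, glyA = 100,
            gdh = 500, ala_ta = 300, asp_ta = 300, mez = 50, gcv = 20)
  fixed <- fixed_fluxes(model, mu, c(glc_upt = v_glc, pca_upt = v_pca))
  realize_fluxes(basis, free_net = free[basis$free_net], fixed = fixed,
                 exchange = exch[basis$free_exchange])
}

#' The default measured-metabolite panel
#'
#' 28 intracellular metabolites whose full backbones give 164 mass traces.
#'
#' @return character vector of metabolite ids.
#' @export
cg_panel <- function() cg_fragment_table()$metabolite

# ---- toy networks for verification -----------------------------------------

#' Toy networks
#'
#' Small atom-mapped networks used for verification against the isotopomer
#' oracle and for fast statistical simulations:
#' `toy_linear()` a two-reaction chain; `toy_split()` a branched network
#' whose single free net flux (the cleavage-route split) and single
#' exchange flux are labeling-identifiable; `toy_cycle()` a futile cycle
#' with identical atom maps whose cycle flux is structurally
#' non-identifiable.
#'
#' @return an `mfa_network`.
#' @export
toy_linear <- function() {
  load_network(list(
    metabolites = list(
      list(id = "Sin", carbons = 2, role = "input"),
      list(id = "A", carbons = 2), list(id = "B", carbons = 2),
      list(id = "P", carbons = 2, role = "output")),
    reactions = list(
      list(id = "upt", equation = "Sin#ab -> A#ab"),
      list(id = "r1", equation = "A#ab -> B#ab"),
      list(id = "out", equation = "B#ab -> P#ab")),
    biomass = list(fixed_uptakes = list("upt")),
    tracer_inputs = list(glucose = "Sin")))
}

#' @rdname toy_linear
#' @export
toy_split <- function() {
  load_network(list(
    metabolites = list(
      list(id = "Sin", carbons = 3, role = "input"),
      list(id = "A", carbons = 3), list(id = "D", carbons = 2),
      list(id = "E", carbons = 1), list(id = "F", carbons = 2),
      list(id = "P", carbons = 1, role = "output"),
      list(id = "Q", carbons = 2, role = "output")),
    reactions = list(
      list(id = "upt", equation = "Sin#abc -> A#abc"),
      list(id = "r1", equation = "A#abc -> D#ab + E#c"),
      list(id = "r2", equation = "A#abc -> D#bc + E#a"),
      list(id = "iso", equation = "D#ab <-> F#ab"),
      list(id = "out_e", equation = "E#a -> P#a"),
      list(id = "out_f", equation = "F#ab -> Q#ab")),
    biomass = list(fixed_uptakes = list("upt")),
    tracer_inputs = list(glucose = "Sin"),
    preferred_free = list("r2")))
}

#' @rdname toy_linear
#' @export
toy_cycle <- function() {
  load_network(list(
    metabolites = list(
      list(id = "Sin", carbons = 2, role = "input"),
      list(id = "A", carbons = 2), list(id = "B", carbons = 2),
      list(id = "P", carbons = 2, role = "output")),
    reactions = list(
      list(id = "upt", equation = "Sin#ab -> A#ab"),
      list(id = "f1", equation = "A#ab -> B#ab"),
      list(id = "f2", equation = "B#ab -> A#ab"),
      list(id = "out", equation = "B#ab -> P#ab")),
    biomass = list(fixed_uptakes = list("upt")),
    tracer_inputs = list(glucose = "Sin"),
    preferred_free = list("f2")))
}

#' Random toy network generator for oracle cross-checks
#'
#' Draws a random small network (linear chains, cleavages, condensations,
#' bidirectional isomerizations, optionally a symmetric pool) with random
#' feasible fluxes and a random tracer, for property testing of the EMU
#' simulator against the isotopomer oracle.
#'
#' @param seed integer seed.
#' @return list with `model`, `flux` (a `flux_state`), `tracer`
#'   (input labeling) and `basis`.
#' @export
random_toy_case <- function(seed) {
  set.seed(seed)
  nIn <- sample(2:4, 1)  # input carbons
  sym <- runif(1) < 0.4
  model <- load_network(list(
    metabolites = list(
      list(id = "Sin", carbons = nIn, role = "input"),
      list(id = "A", carbons = nIn),
      list(id = "B", carbons = nIn - 1), list(id = "C", carbons = 1),
      list(id = "D", carbons = 2 * (nIn - 1), symmetric = sym),
      list(id = "E", carbons = nIn - 1),
      list(id = "P", carbons = 1, role = "output"),
      list(id = "Q", carbons = 2 * (nIn - 1), role = "output")),
    reactions = list(
      list(id = "upt", equation = sprintf("Sin#%s -> A#%s",
        paste(letters[1:nIn], collapse = ""),
        paste(letters[1:nIn], collapse = ""))),
      list(id = "cleave", equation = sprintf("A#%s -> B#%s + C#%s",
        paste(letters[1:nIn], collapse = ""),
        paste(letters[1:(nIn - 1)], collapse = ""), letters[nIn])),
      list(id = "cleave2", equation = sprintf("A#%s -> B#%s + C#%s",
        paste(letters[1:nIn], collapse = ""),
        paste(letters[2:nIn], collapse = ""), letters[1])),
      list(id = "iso", equation = sprintf("B#%s <-> E#%s",
        paste(letters[1:(nIn - 1)], collapse = ""),
        paste(rev(letters[1:(nIn - 1)]), collapse = ""))),
      list(id = "cond", equation = sprintf("B#%s + E#%s -> D#%s",
        paste(letters[1:(nIn - 1)], collapse = ""),
        paste(letters[nIn:(2 * nIn - 2)], collapse = ""),
        paste(letters[1:(2 * nIn - 2)], collapse = ""))),
      list(id = "out_c", equation = "C#a -> P#a"),
      list(id = "out_d", equation = sprintf("D#%s -> Q#%s",
        paste(letters[1:(2 * nIn - 2)], collapse = ""),
        paste(letters[1:(2 * nIn - 2)], collapse = "")))),
    biomass = list(fixed_uptakes = list("upt")),
    tracer_inputs = list(glucose = "Sin"),
    preferred_free = list("cleave2")))
  basis <- build_flux_basis(model, fixed = "upt")
  u <- runif(1, 1, 10)
  split <- runif(1, 0.05, 0.95) * u
  fs <- realize_fluxes(basis,
                       free_net = setNames(split, basis$free_net),
                       fixed = c(upt = u),
                       exchange = setNames(runif(length(basis$free_exchange),
                                                 0, 2 * u),
                                           basis$free_exchange))
  k <- sample(1:3, 1)
  pats <- matrix(runif(k * nIn) < 0.5, k, nIn) * 1
  fr <- runif(k); fr <- fr / sum(fr)
  mix <- tracer_mixture(pats, fr)
  tr <- input_labeling(model, mix, natural_abundance = runif(1) < 0.3,
                       glucose = "Sin")
  list(model = model, basis = basis, flux = fs, tracer = tr)
}
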