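# Synthetic ground-truth datasets with the statistical structure the
# analysis assumes: known fluxes, simulated MIDs with flat Gaussian noise
# (default SD 2.5 mol%), and noisy extracellular rates.

#' Sample a random feasible flux state
#'
#' Uniform rejection sampling of free net fluxes in their boxes and
#' exchange transforms in [0, 1); a draw is accepted when every
#' unidirectional flux of the realized state is non-negative.
#'
#' @param basis a `flux_basis`.
#' @param fixed named fixed fluxes (uptakes + drains).
#' @param seed integer seed.
#' @param net_box named list of c(lo, hi) boxes for free net fluxes;
#'   defaults as in [random_starts()].
#' @param exchange_scale exchange at x01 = 0.5.
#' @param max_tries rejection cap.
#' @return a `flux_state`.
#' @export
sample_true_fluxes <- function(basis, fixed, seed = 1, net_box = NULL,
                               exchange_scale = NULL, max_tries = 1000) {
  set.seed(seed)
  ref <- max(abs(fixed), 1)
  exchange_scale <- exchange_scale %||% (0.1 * ref)
  uni <- names(basis$bidirectional)[!basis$bidirectional]
  for (tr in seq_len(max_tries)) {
    free <- vapply(basis$free_net, function(f) {
      b <- if (!is.null(net_box) && !is.null(net_box[[f]])) net_box[[f]]
      else if (basis$bidirectional[f]) c(-0.2, 0.4) * ref else c(0, 0.6) * ref
      runif(1, b[1], b[2])
    }, 0)
    x01 <- runif(length(basis$free_exchange), 0, 0.9)
    st <- tryCatch(
      realize_fluxes(basis, free, fixed,
                     setNames(exchange_from_x01(x01, exchange_scale),
                              basis$free_exchange)),
      error = function(e) NULL)
    if (!is.null(st) && all(st$net[uni] >= 0)) return(st)
  }
  stop2("no feasible flux state found in ", max_tries, " draws")
}

#' Define a synthetic labeling scenario
#'
#' @param model an `mfa_network`.
#' @param flux true `flux_state`.
#' @param mu growth rate.
#' @param tracer a `tracer_mixture`.
#' @param panel measured metabolites (full backbones).
#' @param mid_sd flat MID noise SD in mol fraction (default 0.025).
#' @param rate_sd named SDs of the rate measurements.
#' @param fragments fragment table (metabolite, backbone_size, formula);
#'   default [cg_fragment_table()] restricted to the panel.
#' @param seed integer seed.
#' @return a `synthetic_scenario`.
#' @export
synthetic_scenario <- function(model, flux, mu, tracer, panel,
                               mid_sd = 0.025,
                               rate_sd = c(mu = 0.03, r_GLC = 150,
                                           r_CO2 = 760, r_PCA = 1,
                                           r_O2 = 150, r_BMC = 500),
                               fragments = NULL, seed = 1) {
  if (is.null(fragments)) {
    ft <- cg_fragment_table()
    fragments <- ft[ft$metabolite %in% panel, ]
    missing <- setdiff(panel, fragments$metabolite)
    if (length(missing)) {
      nc <- setNames(model$metabolites$carbons, model$metabolites$id)
      fragments <- rbind(fragments, data.frame(
        metabolite = missing, backbone_size = nc[missing],
        formula = paste0("C", nc[missing]), stringsAsFactors = FALSE))
    }
  }
  structure(list(model = model, flux = flux, mu = mu, tracer = tracer,
                 panel = panel, mid_sd = mid_sd, rate_sd = rate_sd,
                 fragments = fragments, seed = seed),
            class = "synthetic_scenario")
}

#' The default chemostat labeling scenario
#'
#' Paper-like conditions of the carbon labeling experiment: the bundled
#' network at its preset flux map (mu = 0.41 1/h, glucose uptake 4086
#' umol/gCDW/h), the 67/33 U-13C/1-13C glucose mixture, the 28-metabolite
#' panel (164 mass traces) and flat 2.5 mol% MID noise.
#'
#' @param seed integer seed.
#' @param mid_sd MID noise SD (default 0.025).
#' @return a `synthetic_scenario`.
#' @export
cg_scenario <- function(seed = 1, mid_sd = 0.025) {
  model <- cg_network(expanded = TRUE)
  basis <- build_flux_basis(model)
  flux <- cg_preset_flux(basis)
  synthetic_scenario(model, flux, mu = 0.41, tracer = cg_tracer_mixture(),
                     panel = cg_panel(), mid_sd = mid_sd, seed = seed)
}

#' Simulate a noisy measurement dataset from a scenario
#'
#' Simulates steady-state MIDs at the true fluxes, adds independent
#' Gaussian noise per mass trace (truncated to [0, 1], renormalized per
#' metabolite), and noisy rate measurements. The ground truth is attached
#' as `attr(, "truth")`.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [fit_dataset()].
#' @export
simulate_dataset <- function(scenario) {
  model <- expand_scrambling(scenario$model)
  sys <- decompose(model, backbone_emus(model, scenario$panel))
  tr <- input_labeling(model, scenario$tracer)
  mids <- simulate_mids(sys, scenario$flux, tr)
  set.seed(scenario$seed)
  rows <- list()
  for (i in seq_len(nrow(scenario$fragments))) {
    m <- scenario$fragments$metabolite[i]
    nb <- scenario$fragments$backbone_size[i]
    v <- mids[[emu_key(m, seq_len(nb))]]
    if (scenario$mid_sd > 0) {
      v <- v + rnorm(length(v), 0, scenario$mid_sd)
      v <- pmin(pmax(v, 0), 1)
      v <- v / sum(v)
    }
    rows[[i]] <- data.frame(
      metabolite = m, formula = scenario$fragments$formula[i],
      backbone_size = nb, group = m, mass_shift = seq_along(v) - 1L,
      value = v, sd = scenario$mid_sd %||% 0.025,
      stringsAsFactors = FALSE)
  }
  mtab <- do.call(rbind, rows)
  if (scenario$mid_sd == 0) mtab$sd <- 0.025  # weights stay defined
  true_rates <- c(model_rates(model, scenario$flux, scenario$mu),
                  scenario$flux$net)
  rsd <- scenario$rate_sd
  rsd <- rsd[names(rsd) %in% names(true_rates)[!is.na(true_rates)]]
  noise <- if (scenario$mid_sd > 0) rnorm(length(rsd), 0, rsd) else 0
  rtab <- data.frame(name = names(rsd),
                     value = unname(true_rates[names(rsd)] + noise),
                     sd = unname(rsd), stringsAsFactors = FALSE)
  ds <- fit_dataset(mtab, rtab, scenario$tracer)
  attr(ds, "truth") <- list(flux = scenario$flux, mu = scenario$mu,
                            rates = true_rates)
  ds
}
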