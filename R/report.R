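# Flux map normalization, NADPH and carbon accounting, model rates.

#' Normalize a flux map to a reference flux
#'
#' @param net named net flux vector (or a `flux_state`).
#' @param reference reaction id (default `glc_upt`).
#' @param sd optional named SD vector, scaled identically.
#' @return data frame with reaction, percent (and sd_percent).
#' @export
normalize_map <- function(net, reference = "glc_upt", sd = NULL) {
  if (inherits(net, "flux_state")) net <- net$net
  if (!reference %in% names(net)) stop2("reference flux not found: ", reference)
  ref <- net[[reference]]
  if (ref == 0) stop2("reference flux is zero")
  out <- data.frame(reaction = names(net),
                    percent = 100 * unname(net) / ref,
                    stringsAsFactors = FALSE)
  if (!is.null(sd)) {
    out$sd_percent <- 100 * unname(sd[out$reaction]) / abs(ref)
  }
  out
}

#' De-normalize a percent flux map
#'
#' @param map data frame from [normalize_map()].
#' @param reference_value absolute value of the reference flux.
#' @return named absolute flux vector.
#' @export
denormalize_map <- function(map, reference_value) {
  setNames(map$percent * reference_value / 100, map$reaction)
}

#' NADPH source/demand accounting
#'
#' Production is the sum of NADPH-generating fluxes (oxidative PPP counts
#' twice via G6P dehydrogenase + 6-phosphogluconate dehydrogenase, plus
#' isocitrate dehydrogenase and malic enzyme), expressed as percent of the
#' glucose uptake. The growth requirement is
#' `100 * coefficient * mu / v_glc`; the gap is requirement minus
#' production.
#'
#' @param map either a named percent vector (reaction -> percent of glucose
#'   uptake) or the data frame from [normalize_map()].
#' @param mu growth rate (1/h).
#' @param nadph_coefficient NADPH demand per biomass (umol/gCDW).
#' @param v_glc glucose uptake rate (umol/gCDW/h).
#' @param sources named coefficients (mol NADPH per unit flux); default the
#'   three central NADPH reactions with the oxidative PPP lumped on `gnd`.
#' @return a `nadph_balance` list: per-source percents, production,
#'   requirement and gap (all percent of glucose uptake).
#' @export
nadph_balance <- function(map, mu, nadph_coefficient, v_glc,
                          sources = c(gnd = 2, icd = 1, mez = 1)) {
  if (is.data.frame(map)) map <- setNames(map$percent, map$reaction)
  per_source <- vapply(names(sources), function(r) {
    sources[[r]] * (map[[r]] %||% 0)
  }, 0)
  production <- sum(per_source)
  requirement <- 100 * nadph_coefficient * mu / v_glc
  structure(list(per_source = per_source, production = production,
                 requirement = requirement, gap = requirement - production),
            class = "nadph_balance")
}

#' @export
print.nadph_balance <- function(x, ...) {
  cat(sprintf(paste0("NADPH balance (%% of glucose uptake):\n",
                     "  production  %6.1f  [%s]\n",
                     "  requirement %6.1f\n  gap         %6.1f\n"),
              x$production,
              paste(sprintf("%s %.1f", names(x$per_source), x$per_source),
                    collapse = ", "),
              x$requirement, x$gap))
  invisible(x)
}

#' Carbon output partitioning
#'
#' Carbon-weighted fate of the substrate carbon: fraction leaving as CO2
#' versus fraction incorporated into biomass (and any other outputs), plus
#' the molar CO2 yield per glucose.
#'
#' @param model an `mfa_network`.
#' @param flux a `flux_state` or named net flux vector.
#' @param warn_tol relative carbon imbalance above which a warning with
#'   per-pool residuals is raised.
#' @return a `carbon_balance` list with `biomass_percent`, `co2_percent`,
#'   `co2_per_glucose`, `carbon_in`, `carbon_out`.
#' @export
carbon_balance <- function(model, flux, warn_tol = 0.01) {
  net <- if (inherits(flux, "flux_state")) flux$net else flux
  nc <- setNames(model$metabolites$carbons, model$metabolites$id)
  role <- setNames(model$metabolites$role, model$metabolites$id)
  parents <- list()
  for (r in model$reactions) {
    if (r$variant_of %in% names(parents)) next
    parents[[r$variant_of]] <- r
  }
  c_in <- 0; c_co2 <- 0; c_bm <- 0
  for (id in names(parents)) {
    v <- net[[id]]
    if (is.null(v) || is.na(v)) stop2("missing net flux for ", id)
    r <- parents[[id]]
    for (tm in r$educts) {
      if (role[[tm$met]] == "input") c_in <- c_in + v * nc[[tm$met]]
    }
    for (tm in r$products) {
      if (role[[tm$met]] == "input") c_in <- c_in - v * nc[[tm$met]]
      if (role[[tm$met]] == "output") {
        contrib <- if (is.null(tm$atoms)) {
          sum(vapply(r$educts, function(e) nc[[e$met]], 0)) -
            sum(vapply(r$products, function(p) {
              if (is.null(p$atoms)) 0 else length(p$atoms)
            }, 0))
        } else length(tm$atoms)
        c_bm <- c_bm + v * contrib
      }
    }
  }
  # CO2 leaving: transport into the external CO2 pool (counted above as
  # negative input when CO2_ext is an input pool) -- recompute explicitly
  co2_ext <- model$metabolites$id[model$metabolites$carbons == 1 &
                                    model$metabolites$role == "input"]
  c_co2 <- 0
  for (id in names(parents)) {
    r <- parents[[id]]; v <- net[[id]]
    for (tm in r$products) if (tm$met %in% co2_ext) c_co2 <- c_co2 + v
    for (tm in r$educts) if (tm$met %in% co2_ext) c_co2 <- c_co2 - v
  }
  c_in <- c_in + c_co2  # CO2_ext flows were double-counted as negative input
  resid <- c_in - c_co2 - c_bm
  if (abs(resid) > warn_tol * max(c_in, 1)) {
    warning(sprintf("carbon imbalance %.2f%% of input",
                    100 * resid / c_in), call. = FALSE)
  }
  glc <- net[["glc_upt"]] %||% NA_real_
  structure(list(biomass_percent = 100 * c_bm / c_in,
                 co2_percent = 100 * c_co2 / c_in,
                 co2_per_glucose = if (is.na(glc)) NA_real_ else c_co2 / glc,
                 carbon_in = c_in, carbon_out = c_co2 + c_bm),
            class = "carbon_balance")
}

#' @export
print.carbon_balance <- function(x, ...) {
  cat(sprintf(paste0("carbon partitioning: biomass %.1f%%, CO2 %.1f%%",
                     " (%.2f mol CO2 / mol glucose)\n"),
              x$biomass_percent, x$co2_percent, x$co2_per_glucose))
  invisible(x)
}

#' Model-predicted extracellular rates
#'
#' The measurable biomass-specific rates implied by a flux state: growth
#' rate, glucose and protocatechuate uptake, net CO2 evolution, oxygen
#' uptake from the electron balance (0.5 NADH-equivalents, plus direct O2
#' consumers), and biomass carbon formation rate.
#'
#' @param model an `mfa_network` with cofactor annotations.
#' @param flux a `flux_state`.
#' @param mu growth rate (1/h).
#' @return named vector (mu 1/h, others umol/gCDW/h).
#' @export
model_rates <- function(model, flux, mu) {
  net <- flux$net
  nv <- function(n, default = NA_real_) {
    if (n %in% names(net)) net[[n]] else default
  }
  nadh <- 0; o2 <- 0
  for (rid in names(model$cofactors)) {
    cf <- model$cofactors[[rid]]
    v <- nv(rid, 0)
    nadh <- nadh + (cf$nadh %||% 0) * v
    o2 <- o2 + (cf$o2 %||% 0) * v
  }
  r_o2 <- 0.5 * (nadh - model$nadh_biomass * mu) + o2
  nc <- setNames(model$metabolites$carbons, model$metabolites$id)
  dem <- unlist(model$biomass$demand)
  r_bmc <- mu * sum(dem * nc[names(dem)])
  c(mu = mu,
    r_GLC = nv("glc_upt"),
    r_CO2 = nv("co2_out") - nv("co2_in", 0),
    r_PCA = nv("pca_upt", 0),
    r_O2 = r_o2,
    r_BMC = r_bmc)
}
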