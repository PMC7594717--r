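# Steady-state chemostat balances, respiratory rates and Pirt regression.

#' Chemostat observation
#'
#' @param D dilution rate (1/h).
#' @param c_X biomass concentration (gCDW/L).
#' @param c_feed glucose feed concentration (g/L).
#' @param gas optional list: `y_o2_in`, `y_co2_in`, `y_o2_out`, `y_co2_out`
#'   (molar fractions), `flow` (mol gas/h), `volume` (L).
#' @param tic total inorganic carbon in the broth (mmol/L), carried out with
#'   the harvest stream.
#' @param replicate replicate id.
#' @return a `chemostat_obs`.
#' @export
chemostat_obs <- function(D, c_X, c_feed, gas = NULL, tic = 0,
                          replicate = NA) {
  if (D < 0) stop2("D must be >= 0")
  if (c_X <= 0) stop2("c_X must be > 0")
  structure(list(D = D, c_X = c_X, c_feed = c_feed, gas = gas, tic = tic,
                 replicate = replicate), class = "chemostat_obs")
}

#' Growth rate of a steady-state chemostat
#'
#' At metabolic steady state the growth rate equals the dilution rate.
#'
#' @param obs a [chemostat_obs()] or a dilution rate.
#' @return mu (1/h).
#' @export
growth_rate <- function(obs) {
  if (inherits(obs, "chemostat_obs")) obs$D else obs
}

#' Biomass-specific glucose consumption rate
#'
#' `q_GLC = D * c_feed / c_X` (g/gCDW/h); residual glucose is assumed below
#' detection.
#'
#' @param obs a [chemostat_obs()].
#' @return q_GLC (g/gCDW/h).
#' @export
specific_glucose_uptake <- function(obs) {
  if (obs$c_X == 0) stop2("c_X is zero")
  obs$D * obs$c_feed / obs$c_X
}

#' Biomass-glucose yield
#'
#' `Y_X,GLC = c_X / c_feed = D / q_GLC` (g/g).
#'
#' @param obs a [chemostat_obs()].
#' @return yield (g/g).
#' @export
biomass_yield <- function(obs) {
  if (obs$c_feed == 0) stop2("zero feed concentration")
  obs$c_X / obs$c_feed
}

#' Biomass-specific respiratory rates from gas balances
#'
#' Molar balances over the gas phase: consumption/emission is the
#' difference of inlet and outlet molar flows divided by biomass; the CO2
#' emission rate is augmented by the dissolved inorganic carbon carried out
#' with the harvest stream (`D * TIC / c_X`).
#'
#' @param obs a [chemostat_obs()] with a `gas` list.
#' @return list with `q_o2`, `q_co2` (mmol/gCDW/h) and `rq`.
#' @export
respiratory_rates <- function(obs) {
  g <- obs$gas
  if (is.null(g)) stop2("no gas data in observation")
  if (g$y_o2_out > g$y_o2_in) stop2("outlet O2 above inlet O2")
  # inert balance: N2 flow constant -> outlet total flow
  inert_in <- g$flow * (1 - g$y_o2_in - g$y_co2_in)
  flow_out <- inert_in / (1 - g$y_o2_out - g$y_co2_out)
  o2 <- g$flow * g$y_o2_in - flow_out * g$y_o2_out          # mol/h
  co2 <- flow_out * g$y_co2_out - g$flow * g$y_co2_in       # mol/h
  vx <- obs$c_X * g$volume                                  # gCDW
  q_o2 <- 1000 * o2 / vx
  q_co2 <- 1000 * co2 / vx + obs$D * obs$tic / obs$c_X
  list(q_o2 = q_o2, q_co2 = q_co2,
       rq = if (q_o2 > 0) q_co2 / q_o2 else NA_real_)
}

#' Pirt maintenance regression
#'
#' Ordinary least squares of `q_GLC = (1/Y_real) * mu + m_S` over steady
#' states at different growth rates: the intercept is the non-growth
#' associated maintenance coefficient m_S, the slope the growth-coupled
#' demand 1/Y_real.
#'
#' @param mu growth rates (1/h).
#' @param q_glc glucose consumption rates (mmol/gCDW/h).
#' @return a `pirt_result`: `m_s`, `inv_y_real`, standard errors, and the
#'   underlying `lm` fit.
#' @export
pirt_regression <- function(mu, q_glc) {
  if (length(unique(mu)) < 2) stop2("need at least 2 distinct growth rates")
  fit <- lm(q_glc ~ mu)
  cf <- summary(fit)$coefficients
  structure(list(m_s = unname(cf[1, 1]), inv_y_real = unname(cf[2, 1]),
                 m_s_se = unname(cf[1, 2]), inv_y_real_se = unname(cf[2, 2]),
                 fit = fit), class = "pirt_result")
}

#' @export
print.pirt_result <- function(x, ...) {
  cat(sprintf(paste0("Pirt regression: q_GLC = %.3f * mu + %.3f\n",
                     "  1/Y_real = %.2f +- %.2f mmol/gCDW\n",
                     "  m_S      = %.3f +- %.3f mmol/gCDW/h\n"),
              x$inv_y_real, x$m_s, x$inv_y_real, x$inv_y_real_se,
              x$m_s, x$m_s_se))
  invisible(x)
}

#' Glucose molar mass (g/mol) used for unit conversions
#' @export
GLUCOSE_MOLAR_MASS <- 180.16

#' Printed chemostat process table of the triplicate runs
#'
#' Mean kinetic parameters (D, c_X, q_GLC, yield, q_O2, q_CO2) of the three
#' steady states, with the feed concentration, as printed in the study's
#' process table.
#'
#' @return data frame.
#' @export
cg_process_table <- function() {
  data.frame(
    D = c(0.20, 0.30, 0.40),
    c_X = c(5.87, 6.09, 6.43),
    c_feed = 12.47,
    q_glc = c(0.42, 0.62, 0.77),
    yield = c(0.47, 0.49, 0.52),
    q_o2 = c(5.36, 7.16, 8.15),
    q_co2 = c(5.64, 7.30, 7.94))
}

#' Carbon recovery of a chemostat steady state
#'
#' Ratio of carbon leaving (biomass + CO2 + organic carbon in the filtrate)
#' to carbon entering (glucose + protocatechuate feed), in percent.
#'
#' @param c_in carbon inflow (mmol C/h).
#' @param c_biomass,c_co2,c_toc carbon outflows (mmol C/h).
#' @return percent recovery.
#' @export
carbon_recovery <- function(c_in, c_biomass, c_co2, c_toc = 0) {
  100 * (c_biomass + c_co2 + c_toc) / c_in
}
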