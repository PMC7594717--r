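# Measurement tables, groups and scale factors.
#
# MID measurements live in a long-format table with one row per mass trace:
# metabolite, formula, backbone_size, group, mass_shift, value, sd.
# Measurements of one group share a multiplicative scale factor omega,
# estimated analytically inside every objective evaluation (variable
# projection); extracellular rate measurements are rows (name, value, sd).

#' Assemble a fit dataset
#'
#' @param mids long-format MID measurement table (columns metabolite,
#'   formula, backbone_size, group, mass_shift, value, sd).
#' @param rates data frame with columns name, value, sd. Names must be
#'   measurable model quantities (see [model_rates()]).
#' @param tracer a `tracer_mixture`.
#' @return a `fit_dataset`.
#' @export
fit_dataset <- function(mids, rates, tracer) {
  need <- c("metabolite", "backbone_size", "group", "mass_shift", "value", "sd")
  if (!all(need %in% names(mids))) {
    stop2("mids table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(mids$sd <= 0) || any(rates$sd <= 0)) stop2("all SDs must be > 0")
  structure(list(mids = mids, rates = rates, tracer = tracer,
                 n_meas = nrow(mids) + nrow(rates),
                 n_groups = length(unique(mids$group))),
            class = "fit_dataset")
}

#' @export
print.fit_dataset <- function(x, ...) {
  cat(sprintf("fit_dataset: %d measurements (%d MID values in %d groups + %d rates)\n",
              x$n_meas, nrow(x$mids), x$n_groups, nrow(x$rates)))
  invisible(x)
}

#' Read / write measurement CSV
#'
#' @param file CSV path.
#' @return measurement table.
#' @export
read_measurements <- function(file) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  tab
}

#' @rdname read_measurements
#' @param mids measurement table.
#' @export
write_measurements <- function(mids, file) {
  write.csv(mids, file, row.names = FALSE)
  invisible(file)
}

#' Optimal scale factor of a measurement group
#'
#' Closed-form minimizer of the group's weighted squared residual
#' `sum(((omega * s - m) / sd)^2)`:
#' `omega = sum(s * m / sd^2) / sum(s^2 / sd^2)`.
#'
#' @param simulated simulated values of the group's mass traces.
#' @param measured measured values.
#' @param sd per-trace standard deviations.
#' @return the scale factor omega.
#' @export
fit_group_scale <- function(simulated, measured, sd) {
  den <- sum(simulated^2 / sd^2)
  if (den <= 0) stop2("all simulated group values are zero")
  sum(simulated * measured / sd^2) / den
}

#' Default fragment formulas of the measured metabolite panel
#'
#' Neutral elemental formulas of the 28 intracellular metabolites whose full
#' carbon backbones constitute the default measurement panel (164 mass
#' traces).
#'
#' @return data frame with metabolite, backbone_size, formula.
#' @export
cg_fragment_table <- function() {
  tab <- rbind(
    c("G6P", 6, "C6H13O9P"),  c("F6P", 6, "C6H13O9P"),
    c("FBP", 6, "C6H14O12P2"), c("DHAP", 3, "C3H7O6P"),
    c("PG3", 3, "C3H7O7P"),   c("PEP", 3, "C3H5O6P"),
    c("CIT", 6, "C6H8O7"),    c("AKG", 5, "C5H6O5"),
    c("SUC", 4, "C4H6O4"),    c("FUM", 4, "C4H4O4"),
    c("MAL", 4, "C4H6O5"),    c("R5P", 5, "C5H11O8P"),
    c("S7P", 7, "C7H15O10P"), c("ALA", 3, "C3H7NO2"),
    c("LEU", 6, "C6H13NO2"),  c("VAL", 5, "C5H11NO2"),
    c("ASP", 4, "C4H7NO4"),   c("TYR", 9, "C9H11NO3"),
    c("LYS", 6, "C6H14N2O2"), c("THR", 4, "C4H9NO3"),
    c("ILE", 6, "C6H13NO2"),  c("MET", 5, "C5H11NO2S"),
    c("SER", 3, "C3H7NO3"),   c("GLY", 2, "C2H5NO2"),
    c("GLU", 5, "C5H9NO4"),   c("GLN", 5, "C5H10N2O3"),
    c("ARG", 6, "C6H14N4O2"), c("PRO", 5, "C5H9NO2"))
  data.frame(metabolite = tab[, 1], backbone_size = as.integer(tab[, 2]),
             formula = tab[, 3], stringsAsFactors = FALSE)
}
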