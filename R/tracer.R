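# Tracer mixtures and input-pool labeling.

#' Define a tracer mixture over labeled species
#'
#' @param patterns matrix (one row per species) or list of binary 0/1 vectors
#'   marking the 13C-labeled carbon positions of each species.
#' @param fractions mole fractions (>= 0, sum 1).
#' @return a `tracer_mixture`.
#' @export
tracer_mixture <- function(patterns, fractions) {
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  patterns <- as.matrix(patterns)
  if (any(!patterns %in% c(0, 1))) stop2("label patterns must be binary")
  if (any(fractions < 0)) stop2("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9) stop2("fractions must sum to 1")
  if (nrow(patterns) != length(fractions)) stop2("patterns/fractions mismatch")
  structure(list(patterns = patterns, fractions = as.numeric(fractions)),
            class = "tracer_mixture")
}

#' Glucose tracer species patterns
#'
#' Binary 6-carbon label patterns of the candidate glucose tracers:
#' `U12` (unlabeled), `U13` (uniformly labeled), `C1`, `C12` (carbons 1+2),
#' `C6`, `C56` (carbons 5+6).
#'
#' @return named list of binary 6-vectors.
#' @export
glucose_tracers <- function() {
  list(U12 = rep(0, 6), U13 = rep(1, 6),
       C1  = c(1, 0, 0, 0, 0, 0), C12 = c(1, 1, 0, 0, 0, 0),
       C6  = c(0, 0, 0, 0, 0, 1), C56 = c(0, 0, 0, 0, 1, 1))
}

#' The chemostat labeling experiment glucose mixture
#'
#' 67% uniformly 13C-labeled plus 33% 1-13C glucose, the mixture fed in the
#' carbon labeling experiment at D = 0.4 1/h.
#'
#' @return a `tracer_mixture`.
#' @export
cg_tracer_mixture <- function() {
  tr <- glucose_tracers()
  tracer_mixture(list(tr$U13, tr$C1), c(0.67, 0.33))
}

#' Labeling state of all input pools
#'
#' Builds the tracer-input object consumed by [simulate_mids()] and
#' [isotopomer_oracle()]: the glucose input carries the tracer mixture, every
#' other input pool (protocatechuate, external CO2) is unlabeled. With
#' `natural_abundance = TRUE` all positions not fixed by a tracer pattern
#' carry 13C at natural abundance.
#'
#' @param model an `mfa_network`.
#' @param mixture a `tracer_mixture` for the glucose input.
#' @param natural_abundance logical.
#' @param abundance 13C natural abundance (default 0.0107).
#' @param glucose id of the glucose input pool (default from the model's
#'   `tracer_inputs$glucose`, falling back to `"GLC_ext"`).
#' @return named list, one labeling spec per input pool.
#' @export
input_labeling <- function(model, mixture, natural_abundance = FALSE,
                           abundance = 0.0107,
                           glucose = NULL) {
  glucose <- glucose %||% (model$tracer_inputs$glucose %||% "GLC_ext")
  inputs <- model$metabolites[model$metabolites$role == "input", ]
  if (!glucose %in% inputs$id) {
    stop2("tracer-carrying input pool '", glucose, "' not in model inputs (",
          paste(inputs$id, collapse = ", "), ")")
  }
  out <- list()
  for (i in seq_len(nrow(inputs))) {
    m <- inputs$id[i]; nc <- inputs$carbons[i]
    if (m == glucose) {
      if (ncol(mixture$patterns) != nc) {
        stop2("tracer patterns have ", ncol(mixture$patterns),
              " carbons, glucose pool has ", nc)
      }
      out[[m]] <- list(patterns = mixture$patterns,
                       fractions = mixture$fractions,
                       na = natural_abundance, abundance = abundance)
    } else {
      out[[m]] <- list(patterns = matrix(0, 1, nc), fractions = 1,
                       na = natural_abundance, abundance = abundance)
    }
  }
  out
}

#' MID of an input-pool EMU
#'
#' Marginalizes the tracer mixture of an input pool onto an atom subset:
#' for each species the labeled count within the subset is deterministic,
#' and unlabeled positions contribute binomial natural abundance when
#' enabled.
#'
#' @param tracer_input object from [input_labeling()].
#' @param met input pool id.
#' @param atoms 1-based carbon positions of the EMU.
#' @return MID vector of length `length(atoms) + 1`.
#' @export
tracer_input_mids <- function(tracer_input, met, atoms) {
  spec <- tracer_input[[met]]
  if (is.null(spec)) stop2("no tracer input for pool ", met)
  k <- length(atoms)
  mid <- numeric(k + 1)
  for (s in seq_along(spec$fractions)) {
    l <- sum(spec$patterns[s, atoms])
    if (isTRUE(spec$na) && spec$abundance > 0) {
      u <- k - l
      contrib <- numeric(k + 1)
      contrib[(l + 1):(l + u + 1)] <- dbinom(0:u, u, spec$abundance)
      mid <- mid + spec$fractions[s] * contrib
    } else {
      mid[l + 1] <- mid[l + 1] + spec$fractions[s]
    }
  }
  mid
}

input_emu_mid <- tracer_input_mids

# Positional isotopomer distribution (length 2^n) of an input pool;
# bit b-1 of the index marks a 13C at position b.
input_isotopomer_dist <- function(tracer_input, met, n) {
  spec <- tracer_input[[met]]
  if (is.null(spec)) stop2("no tracer input for pool ", met)
  a <- if (isTRUE(spec$na)) spec$abundance else 0
  dist <- numeric(2^n)
  for (s in seq_along(spec$fractions)) {
    d <- 1
    for (p in seq_len(n)) {
      pos <- if (spec$patterns[s, p] == 1) c(0, 1) else c(1 - a, a)
      d <- as.vector(outer(d, pos))
    }
    dist <- dist + spec$fractions[s] * d
  }
  dist
}
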