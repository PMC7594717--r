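# Free-flux parameterization (net/exchange) of the balanced network.
#
# Net fluxes live on parent reactions; steady state requires S v = 0 over all
# balanced pools. Measured uptakes and the growth-scaled biomass drains are
# fixed; the remaining null-space directions are parameterized by a
# deterministic choice of free net fluxes. Exchange fluxes (>= 0) exist for
# every bidirectional parent reaction except those listed in the model's
# `fixed_exchange` (held at zero).

#' Build the net/exchange flux basis
#'
#' Selects a deterministic set of free net fluxes spanning the null space of
#' the balanced stoichiometric matrix after fixing the given reactions, and
#' precomputes the linear map from (free values, fixed values) to the full
#' net flux vector. Reactions named in `model$preferred_free` are chosen as
#' free fluxes whenever the column ordering permits.
#'
#' @param model an `mfa_network`.
#' @param fixed character vector of reaction ids whose net flux is fixed
#'   (measured uptakes, biomass drains). Defaults to all drain reactions
#'   (`*_bm`) plus any reaction ids in `model$biomass$fixed_uptakes`.
#' @return an object of class `flux_basis` with elements `free_net`,
#'   `free_exchange`, `fixed`, and the dependency matrices.
#' @export
build_flux_basis <- function(model, fixed = default_fixed(model)) {
  S <- balanced_stoichiometry(model)
  parents <- colnames(S)
  if (!all(fixed %in% parents)) {
    stop2("fixed reactions not in model: ",
          paste(setdiff(fixed, parents), collapse = ", "))
  }
  unknown <- setdiff(parents, fixed)
  Su <- S[, unknown, drop = FALSE]
  Sf <- S[, fixed, drop = FALSE]

  # independent balance rows
  qr_rows <- qr(t(Su))
  rows <- sort(qr_rows$pivot[seq_len(qr_rows$rank)])
  Su_r <- Su[rows, , drop = FALSE]
  Sf_r <- Sf[rows, , drop = FALSE]
  rank <- qr_rows$rank

  # greedy deterministic selection: non-preferred columns enter the dependent
  # basis first, so preferred branch-point fluxes end up free.
  pref <- intersect(model$preferred_free, unknown)
  order_cols <- c(setdiff(unknown, pref), pref)
  dep <- character()
  Q <- matrix(0, length(rows), 0)
  for (cn in order_cols) {
    if (length(dep) == rank) break
    cand <- cbind(Q, Su_r[, cn])
    if (qr(cand)$rank > ncol(Q)) {
      Q <- cand
      dep <- c(dep, cn)
    }
  }
  if (length(dep) < rank) stop2("could not span balance constraints")
  free_net <- setdiff(unknown, dep)
  Sd <- Su_r[, dep, drop = FALSE]
  # v_dep = -Sd^{-1} (S_free v_free + S_fixed v_fixed)
  Minv <- solve(Sd)
  M_free <- -Minv %*% Su_r[, free_net, drop = FALSE]
  M_fixed <- -Minv %*% Sf_r

  # consistency of dropped (dependent) balance rows is checked at realization
  bid <- parent_directions(model)
  free_ex <- setdiff(names(bid)[bid], model$fixed_exchange)

  structure(list(
    model_parents = parents, free_net = free_net,
    free_exchange = free_ex, fixed = fixed, dep = dep,
    M_free = M_free, M_fixed = M_fixed, S = S,
    bidirectional = bid
  ), class = "flux_basis")
}

default_fixed <- function(model) {
  parents <- unique(vapply(model$reactions, `[[`, "", "variant_of"))
  drains <- grep("_bm$", parents, value = TRUE)
  c(unlist(model$biomass$fixed_uptakes) %||% character(), drains)
}

#' @export
print.flux_basis <- function(x, ...) {
  cat(sprintf("flux_basis: %d free net + %d free exchange fluxes (%d fixed)\n",
              length(x$free_net), length(x$free_exchange), length(x$fixed)))
  cat("  free net:", paste(x$free_net, collapse = ", "), "\n")
  invisible(x)
}

#' Realize a full flux state from free values
#'
#' @param basis a `flux_basis`.
#' @param free_net named numeric vector over `basis$free_net` (any order).
#' @param fixed named numeric vector over `basis$fixed` (uptake rates and
#'   biomass drains, umol/gCDW/h).
#' @param exchange named numeric vector (>= 0) over (a subset of)
#'   `basis$free_exchange`; missing entries are zero.
#' @param tol relative balance tolerance.
#' @return a `flux_state` with `net`, `exchange`, `forward`, `backward`.
#' @export
realize_fluxes <- function(basis, free_net = numeric(), fixed,
                           exchange = numeric(), tol = 1e-6) {
  if (!all(basis$free_net %in% names(free_net)) && length(basis$free_net)) {
    stop2("free_net must name all free fluxes: ",
          paste(basis$free_net, collapse = ", "))
  }
  if (!all(basis$fixed %in% names(fixed))) {
    stop2("fixed must name all fixed fluxes")
  }
  if (length(exchange) && any(exchange < 0)) stop2("exchange fluxes must be >= 0")
  if (!all(names(exchange) %in% basis$free_exchange)) {
    stop2("exchange given for non-exchange reaction: ",
          paste(setdiff(names(exchange), basis$free_exchange), collapse = ", "))
  }
  vf <- free_net[basis$free_net]
  vx <- fixed[basis$fixed]
  vdep <- drop(basis$M_free %*% vf + basis$M_fixed %*% vx)
  net <- setNames(numeric(length(basis$model_parents)), basis$model_parents)
  net[basis$free_net] <- vf
  net[basis$fixed] <- vx
  net[basis$dep] <- vdep
  # residuals over every balanced pool (including rows dropped as redundant)
  res <- drop(basis$S %*% net)
  scale <- max(abs(net), 1)
  if (max(abs(res)) > tol * scale) {
    bad <- names(res)[abs(res) > tol * scale]
    stop2("flux balances inconsistent at pools: ", paste(bad, collapse = ", "))
  }
  ex <- setNames(numeric(length(basis$free_exchange)), basis$free_exchange)
  ex[names(exchange)] <- exchange
  flux_state(net, ex, basis)
}

#' Construct a flux state
#'
#' @param net named net fluxes per parent reaction.
#' @param exchange named exchange fluxes (>= 0) per free bidirectional parent.
#' @param basis the `flux_basis` (used for direction flags).
#' @return a `flux_state`.
#' @export
flux_state <- function(net, exchange, basis) {
  fwd <- pmax(net, 0)
  bwd <- pmax(-net, 0)
  if (length(exchange)) {
    fwd[names(exchange)] <- fwd[names(exchange)] + exchange
    bwd[names(exchange)] <- bwd[names(exchange)] + exchange
  }
  bid <- basis$bidirectional
  uni <- names(bid)[!bid]
  if (any(net[uni] < -1e-9 * max(abs(net), 1))) {
    stop2("negative net flux on unidirectional reaction: ",
          paste(uni[net[uni] < 0], collapse = ", "))
  }
  bwd[uni] <- 0
  fwd[uni] <- net[uni]
  structure(list(net = net, exchange = exchange, forward = fwd, backward = bwd),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("flux_state over", length(x$net), "reactions; |net| range",
      sprintf("[%.3g, %.3g]\n", min(abs(x$net)), max(abs(x$net))))
  invisible(x)
}

#' Extract free values from a flux state
#'
#' Projection inverse of [realize_fluxes()]: returns the free net values,
#' fixed values and exchange values that reproduce `state`.
#'
#' @param basis a `flux_basis`.
#' @param state a `flux_state`.
#' @return list with `free_net`, `fixed`, `exchange`.
#' @export
extract_free <- function(basis, state) {
  list(free_net = state$net[basis$free_net],
       fixed = state$net[basis$fixed],
       exchange = state$exchange[basis$free_exchange])
}

#' Bounded transform for exchange fluxes
#'
#' Optimizer variables use the bounded transform `x01 = x / (1 + x)` in
#' `[0, 1)`; `x = x01 / (1 - x01)` recovers the raw exchange flux. The scale
#' parameter sets the exchange magnitude mapped to x01 = 0.5.
#'
#' @param x01 transformed value(s) in `[0, 1)`.
#' @param scale exchange flux at x01 = 0.5 (default 1).
#' @return raw exchange flux(es).
#' @export
exchange_from_x01 <- function(x01, scale = 1) {
  stopifnot(all(x01 >= 0), all(x01 < 1))
  scale * x01 / (1 - x01)
}

#' @rdname exchange_from_x01
#' @param x raw exchange flux(es) (>= 0).
#' @export
x01_from_exchange <- function(x, scale = 1) {
  stopifnot(all(x >= 0))
  (x / scale) / (1 + x / scale)
}
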