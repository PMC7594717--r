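# Full positional-isotopomer steady-state solver.
#
# Independent verification oracle for the EMU simulator: solves the complete
# positional isotopomer balance of every balanced pool by fixed-point
# iteration and marginalizes to MIDs. Exponential in pool size, so intended
# for networks with small pools.

#' Steady-state MIDs by full isotopomer enumeration
#'
#' @param model an `mfa_network` (expanded automatically).
#' @param flux a `flux_state`.
#' @param tracer_input object from [input_labeling()].
#' @param tol fixed-point convergence tolerance (max absolute change).
#' @param max_iter iteration cap.
#' @param max_joint largest admissible joint educt isotopomer space.
#' @return named list: per balanced metabolite the full-backbone MID; the
#'   positional isotopomer distributions are attached as
#'   `attr(, "isotopomers")`.
#' @export
isotopomer_oracle <- function(model, flux, tracer_input, tol = 1e-13,
                              max_iter = 50000, max_joint = 2^18) {
  model <- expand_scrambling(model)
  mets <- model$metabolites
  role <- setNames(mets$role, mets$id)
  ncarb <- setNames(mets$carbons, mets$id)
  instances <- directed_instances(model)
  fdir <- instance_fluxes(instances, flux)

  bal <- mets$id[mets$role == "balanced"]
  if (sum(2^ncarb[bal]) > 2^20) stop2("network too large for the isotopomer oracle")

  # fixed input distributions
  dists <- list()
  for (m in mets$id[mets$role == "input"]) {
    dists[[m]] <- input_isotopomer_dist(tracer_input, m, ncarb[[m]])
  }
  for (m in bal) dists[[m]] <- c(1, numeric(2^ncarb[[m]] - 1))

  # precompute contributions: per balanced pool, list of
  # (instance, educt mets in order, index map joint -> product index)
  contribs <- setNames(vector("list", length(bal)), bal)
  outflux <- setNames(numeric(length(bal)), bal)
  for (i in seq_along(instances)) {
    ins <- instances[[i]]
    if (fdir[i] == 0) next
    emets <- vapply(ins$educts, `[[`, "", "met")
    for (em in emets) if (em %in% bal) outflux[em] <- outflux[em] + fdir[i]
    esizes <- ncarb[emets]
    E <- sum(esizes)
    if (2^E > max_joint) stop2("joint educt space too large in reaction ", ins$parent)
    # bit offset of each educt term
    offs <- cumsum(c(0, esizes[-length(esizes)]))
    # letter -> joint bit index
    letter_bit <- list()
    for (t in seq_along(ins$educts)) {
      at <- ins$educts[[t]]$atoms
      for (p in seq_along(at)) letter_bit[[at[p]]] <- offs[t] + p
    }
    J <- 0:(2^E - 1)
    for (pt in ins$products) {
      if (is.null(pt$atoms) || !(pt$met %in% bal)) next
      np <- ncarb[[pt$met]]
      idx <- integer(length(J))
      for (p in seq_len(np)) {
        b <- letter_bit[[pt$atoms[p]]]
        bit <- (J %/% 2^(b - 1)) %% 2
        idx <- idx + bit * 2^(p - 1)
      }
      contribs[[pt$met]][[length(contribs[[pt$met]]) + 1]] <-
        list(inst = i, emets = emets, idx = idx + 1L, np = np)
    }
  }
  for (m in bal) {
    if (!length(contribs[[m]])) stop2("pool ", m, " has no producing flux")
    if (outflux[m] <= 0) stop2("pool ", m, " has zero outflux")
  }

  for (it in seq_len(max_iter)) {
    delta <- 0
    for (m in bal) {
      acc <- numeric(2^ncarb[[m]])
      for (cb in contribs[[m]]) {
        joint <- 1
        for (em in cb$emets) joint <- as.vector(outer(joint, dists[[em]]))
        marg <- numeric(2^cb$np)
        tmp <- rowsum(joint, cb$idx)
        marg[as.integer(rownames(tmp))] <- tmp
        acc <- acc + fdir[cb$inst] * marg
      }
      newd <- acc / outflux[m]
      # project back onto the simplex: condensation terms square tiny
      # normalization errors, which would otherwise grow multiplicatively
      newd <- newd / sum(newd)
      delta <- max(delta, max(abs(newd - dists[[m]])))
      dists[[m]] <- newd
    }
    if (delta < tol) break
  }
  if (delta >= tol) stop2("isotopomer oracle did not converge (delta ", delta, ")")

  mids <- list()
  for (m in bal) {
    n <- ncarb[[m]]
    mass <- bit_count(0:(2^n - 1))
    mid <- numeric(n + 1)
    for (k in 0:n) mid[k + 1] <- sum(dists[[m]][mass == k])
    mids[[m]] <- mid
  }
  attr(mids, "isotopomers") <- dists
  mids
}
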