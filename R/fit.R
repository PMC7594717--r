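# Variance-weighted least-squares flux estimation.
#
# Parameters are the free net fluxes plus the bounded exchange transform
# x01 = x/(1+x) of every free exchange flux. Measurement-group scale factors
# are projected out analytically inside each objective evaluation (variable
# projection), which is equivalent to carrying them as optimizer variables
# and keeps the reported parameter count at free fluxes + groups.

#' Precompute the fitting context
#'
#' @param model an `mfa_network`.
#' @param dataset a [fit_dataset()].
#' @param mu growth rate fixing the biomass drains (1/h).
#' @param uptake_free named starting/reference values for the fixed uptake
#'   fluxes; the uptakes stay fixed at these values during the fit (they are
#'   also rate measurements, entering the objective through `r_GLC` etc.).
#' @param exchange_scale exchange flux mapped to x01 = 0.5.
#' @param natural_abundance simulate with natural-abundance inputs
#'   (default FALSE: measured MIDs are assumed abundance-corrected).
#' @return a `fit_context`.
#' @export
fit_context <- function(model, dataset, mu, uptake_free,
                        exchange_scale = NULL, natural_abundance = FALSE) {
  model <- expand_scrambling(model)
  basis <- build_flux_basis(model)
  mets <- unique(dataset$mids$metabolite)
  sys <- decompose(model, backbone_emus(model, mets))
  tracer <- input_labeling(model, dataset$tracer,
                           natural_abundance = natural_abundance)
  nc <- setNames(model$metabolites$carbons, model$metabolites$id)
  keys <- vapply(seq_len(nrow(dataset$mids)), function(i) {
    m <- dataset$mids$metabolite[i]
    emu_key(m, seq_len(dataset$mids$backbone_size[i]))
  }, "")
  fixed <- fixed_fluxes(model, mu, uptake_free)
  scale_ref <- max(abs(uptake_free))
  structure(list(model = model, basis = basis, system = sys,
                 tracer = tracer, dataset = dataset, mu = mu,
                 fixed = fixed, keys = keys,
                 exchange_scale = exchange_scale %||% (0.1 * scale_ref),
                 scale_ref = scale_ref,
                 n_params = length(basis$free_net) +
                   length(basis$free_exchange) + dataset$n_groups),
            class = "fit_context")
}

# parameter vector <-> flux state
theta_names <- function(ctx) {
  ex <- ctx$basis$free_exchange
  c(ctx$basis$free_net,
    if (length(ex)) paste0("x01_", ex) else character(0))
}

theta_to_flux <- function(ctx, theta, check = TRUE) {
  nn <- length(ctx$basis$free_net)
  free <- setNames(theta[seq_len(nn)] * ctx$scale_ref, ctx$basis$free_net)
  x01 <- theta[-seq_len(nn)]
  ex <- setNames(exchange_from_x01(pmin(pmax(x01, 0), 1 - 1e-12),
                                   ctx$exchange_scale),
                 ctx$basis$free_exchange)
  if (check) {
    realize_fluxes(ctx$basis, free, ctx$fixed, ex)
  } else {
    b <- ctx$basis
    vdep <- drop(b$M_free %*% free + b$M_fixed %*% ctx$fixed[b$fixed])
    net <- setNames(numeric(length(b$model_parents)), b$model_parents)
    net[b$free_net] <- free; net[b$fixed] <- ctx$fixed[b$fixed]
    net[b$dep] <- vdep
    list(net = net, exchange = ex)
  }
}

flux_to_theta <- function(ctx, flux) {
  fe <- ctx$basis$free_exchange
  ex <- flux$exchange[fe]
  c(flux$net[ctx$basis$free_net] / ctx$scale_ref,
    if (length(fe)) {
      setNames(x01_from_exchange(ex, ctx$exchange_scale),
               paste0("x01_", fe))
    } else numeric(0))
}

# Residual vector at theta: MID residuals (after group scale projection),
# rate residuals, then smooth feasibility penalties (zero on the feasible
# set): negative unidirectional net fluxes and out-of-range exchange
# transforms. Keeping the penalties as residuals makes the objective smooth
# for Levenberg-Marquardt steps that graze the boundary.
fit_residuals <- function(ctx, theta, detail = FALSE) {
  n_res <- ctx$dataset$n_meas
  if (any(!is.finite(theta))) {
    return(structure(list(penalty = 1, residuals = rep(1e3, n_res)),
                     class = "infeasible"))
  }
  nn <- length(ctx$basis$free_net)
  x01 <- theta[-seq_len(nn)]
  pen_x <- sum(pmax(x01 - 0.995, 0)) + sum(pmax(-x01, 0))
  theta[-seq_len(nn)] <- pmin(pmax(x01, 0), 0.995)
  raw <- theta_to_flux(ctx, theta, check = FALSE)
  uni <- names(ctx$basis$bidirectional)[!ctx$basis$bidirectional]
  viol <- pmax(0, -raw$net[uni]) / ctx$scale_ref
  if (sum(viol) > 0.2) {  # far outside: simulation pointless
    return(structure(list(penalty = sum(viol) + pen_x,
                          residuals = rep(1e3 * (1 + sum(viol) + pen_x),
                                          n_res)),
                     class = "infeasible"))
  }
  net <- raw$net
  net[uni][net[uni] < 0] <- 0
  fs <- flux_state(net, raw$exchange, ctx$basis)
  feasible <- sum(viol) == 0 && pen_x == 0
  mids <- tryCatch(
    simulate_mids(ctx$system, fs, ctx$tracer, strict = feasible),
    error = function(e) NULL)
  if (is.null(mids)) {
    return(structure(list(penalty = sum(viol) + pen_x + 1e-3,
                          residuals = rep(1e3 * (1 + sum(viol) + pen_x),
                                          n_res)),
                     class = "infeasible"))
  }
  md <- ctx$dataset$mids
  sim <- vapply(seq_len(nrow(md)), function(i) {
    mids[[ctx$keys[i]]][md$mass_shift[i] + 1]
  }, 0)
  omega <- setNames(numeric(ctx$dataset$n_groups),
                    unique(md$group))
  res_mid <- numeric(nrow(md))
  for (g in names(omega)) {
    ix <- which(md$group == g)
    omega[g] <- fit_group_scale(sim[ix], md$value[ix], md$sd[ix])
    res_mid[ix] <- (omega[g] * sim[ix] - md$value[ix]) / md$sd[ix]
  }
  rt <- ctx$dataset$rates
  pred <- c(model_rates(ctx$model, fs, ctx$mu), fs$net)
  if (!all(rt$name %in% names(pred))) {
    stop2("unknown rate measurement: ",
          paste(setdiff(rt$name, names(pred)), collapse = ", "))
  }
  res_rate <- (pred[rt$name] - rt$value) / rt$sd
  pen <- 1e3 * c(viol, pen_x)
  if (detail) {
    list(residuals = c(res_mid, res_rate), omega = omega, flux = fs,
         sim = sim, rates = pred, feasible = feasible)
  } else {
    c(res_mid, res_rate, pen)
  }
}

#' Variance-weighted sum of squared residuals
#'
#' The fitting objective: squared deviations between simulated and measured
#' MIDs (after analytic per-group scale factors) and extracellular rates,
#' each weighted by its measurement SD. Infeasible flux states (negative
#' unidirectional net fluxes) return a large penalty.
#'
#' @param theta parameter vector: free net fluxes then x01-transformed
#'   exchange fluxes (see [fit_context()] / `theta_names`).
#' @param ctx a [fit_context()].
#' @return scalar SSR.
#' @export
weighted_ssr <- function(theta, ctx) {
  r <- fit_residuals(ctx, theta)
  if (inherits(r, "infeasible")) return(1e6 * (1 + r$penalty))
  sum(r^2)
}

#' Chi-square acceptance threshold
#'
#' Upper-alpha quantile of the chi-square distribution with
#' `n_meas - n_params` degrees of freedom: a fit is statistically acceptable
#' when its SSR stays below this value.
#'
#' @param n_meas number of measurements.
#' @param n_params number of fitted parameters (free fluxes + scale factors).
#' @param alpha significance level (default 0.05).
#' @return the SSR threshold.
#' @export
chi2_acceptance <- function(n_meas, n_params, alpha = 0.05) {
  dof <- n_meas - n_params
  if (dof <= 0) stop2("non-positive degrees of freedom (", dof, ")")
  qchisq(1 - alpha, df = dof)
}

#' Random feasible starting points
#'
#' Free net fluxes are drawn uniformly in their box, exchange transforms
#' uniformly in [0, 1); draws whose dependent unidirectional fluxes turn
#' negative are rejected.
#'
#' @param ctx a [fit_context()].
#' @param n number of starts.
#' @param net_box matrix (2 x free net) or named list of c(lo, hi) boxes;
#'   default: [0, 0.6]*reference for unidirectional free fluxes,
#'   [-0.2, 0.4]*reference for bidirectional ones.
#' @param max_tries rejection cap per start.
#' @return matrix (n x n_theta) of feasible parameter vectors.
#' @export
random_starts <- function(ctx, n, net_box = NULL, max_tries = 200) {
  nn <- length(ctx$basis$free_net)
  ref <- ctx$scale_ref
  box <- matrix(NA_real_, 2, nn,
                dimnames = list(NULL, ctx$basis$free_net))
  for (f in ctx$basis$free_net) {
    if (!is.null(net_box) && !is.null(net_box[[f]])) {
      box[, f] <- net_box[[f]]
    } else if (ctx$basis$bidirectional[f]) {
      box[, f] <- c(-0.2, 0.4) * ref
    } else {
      box[, f] <- c(0, 0.6) * ref
    }
  }
  out <- matrix(NA_real_, n, nn + length(ctx$basis$free_exchange))
  colnames(out) <- theta_names(ctx)
  uni <- names(ctx$basis$bidirectional)[!ctx$basis$bidirectional]
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      th <- c(runif(nn, box[1, ], box[2, ]) / ctx$scale_ref,
              runif(length(ctx$basis$free_exchange), 0, 0.9))
      raw <- theta_to_flux(ctx, th, check = FALSE)
      if (all(raw$net[uni] >= 0)) { ok <- TRUE; break }
    }
    if (!ok) stop2("could not draw a feasible start after ", max_tries,
                   " tries")
    out[i, ] <- th
  }
  out
}

#' Estimate fluxes by multi-start weighted least squares
#'
#' Each start runs a gradient-free simplex polish followed by a
#' derivative-based refinement; the best local minimum over all starts is
#' refined once more and reported, together with the chi-square acceptance
#' verdict and the full multi-start trace. Deterministic for a given seed.
#'
#' @param dataset a [fit_dataset()].
#' @param model an `mfa_network`.
#' @param mu growth rate fixing the biomass drains.
#' @param uptakes named fixed uptake fluxes.
#' @param n_starts number of random starts (>= 1).
#' @param seed integer seed controlling the start stream.
#' @param net_box optional start boxes, see [random_starts()].
#' @param nm_iter simplex iteration cap per start.
#' @param alpha significance level of the acceptance test.
#' @param n_jitter jittered refinement restarts around the winner, used to
#'   escape shallow side minima of the sloppy least-squares valley.
#' @param jitter_sd jitter SD in scaled parameter units.
#' @param ctx optional prebuilt [fit_context()] (overrides model/mu/uptakes).
#' @return a `fit_result`.
#' @export
fit_fluxes <- function(dataset, model, mu, uptakes, n_starts = 20, seed = 1,
                       net_box = NULL, nm_iter = 150, alpha = 0.05,
                       n_jitter = 8, jitter_sd = 0.02, ctx = NULL) {
  if (n_starts < 1) stop2("n_starts must be >= 1")
  if (is.null(ctx)) ctx <- fit_context(model, dataset, mu, uptakes)
  set.seed(seed)
  starts <- random_starts(ctx, n_starts, net_box)
  nn <- length(ctx$basis$free_net)
  lower <- c(ifelse(ctx$basis$bidirectional[ctx$basis$free_net], -2, 0),
             rep(0, length(ctx$basis$free_exchange)))
  upper <- c(rep(2, nn), rep(0.995, length(ctx$basis$free_exchange)))
  trace <- data.frame(start = seq_len(n_starts), ssr = NA_real_)
  resid_fn <- function(th) {
    r <- fit_residuals(ctx, th)
    if (inherits(r, "infeasible")) return(r$residuals)
    r
  }
  lm_stage <- function(par, maxiter, ptol = 1e-12) {
    o <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par, lower = lower, upper = upper, fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ftol = 1e-15, ptol = ptol))),
      error = function(e) NULL)
    if (is.null(o)) return(NULL)
    list(par = o$par, objective = sum(resid_fn(o$par)^2))
  }
  best <- NULL
  simplex <- function(th, maxit) {
    if (length(th) == 1) {
      optim(th, weighted_ssr, ctx = ctx, method = "Brent",
            lower = lower, upper = upper)
    } else {
      optim(th, weighted_ssr, ctx = ctx, method = "Nelder-Mead",
            control = list(maxit = maxit))
    }
  }
  for (i in seq_len(n_starts)) {
    th <- starts[i, ]
    o1 <- simplex(th, nm_iter)
    o2 <- lm_stage(o1$par, 80) %||% list(par = o1$par, objective = o1$value)
    trace$ssr[i] <- o2$objective
    if (is.null(best) || o2$objective < best$objective) best <- o2
  }
  # final polish of the winner: a deep LM round, then jittered LM restarts
  # around the incumbent to escape shallow side minima
  fin <- best
  cand <- lm_stage(fin$par, 400, ptol = 1e-15)
  if (!is.null(cand) && cand$objective < fin$objective) fin <- cand
  for (j in seq_len(n_jitter)) {
    if (fin$objective < 1e-10) break
    thj <- pmin(pmax(fin$par + rnorm(length(fin$par), 0, jitter_sd),
                     lower + 1e-9), upper - 1e-4)
    cand <- lm_stage(thj, 300, ptol = 1e-14)
    if (!is.null(cand) && cand$objective < fin$objective) fin <- cand
  }
  det <- fit_residuals(ctx, fin$par, detail = TRUE)
  if (inherits(det, "infeasible") || !isTRUE(det$feasible)) {
    stop2("best fit is infeasible")
  }
  n_meas <- ctx$dataset$n_meas
  thr <- chi2_acceptance(n_meas, ctx$n_params, alpha)
  structure(list(theta = setNames(fin$par, theta_names(ctx)),
                 flux = det$flux, omega = det$omega,
                 residuals = det$residuals, ssr = sum(det$residuals^2),
                 n_meas = n_meas, n_params = ctx$n_params,
                 dof = n_meas - ctx$n_params,
                 chi2_threshold = thr, accepted = sum(det$residuals^2) <= thr,
                 alpha = alpha, trace = trace, ctx = ctx),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("fit_result: SSR %.3f vs chi2 threshold %.1f ",
                     "(dof %d) -> %s\n"),
              x$ssr, x$chi2_threshold, x$dof,
              if (x$accepted) "accepted" else "rejected"))
  cat(sprintf("  %d measurements, %d parameters, best of %d starts\n",
              x$n_meas, x$n_params, nrow(x$trace)))
  invisible(x)
}

#' Simultaneous confidence intervals for free net fluxes
#'
#' Profile mode re-optimizes the remaining parameters while walking each
#' flux away from its optimum until the SSR exceeds
#' `SSR* + qchisq(1 - alpha, n_params)` (simultaneous intervals); searches
#' that leave the admissible range without reaching the threshold are
#' flagged non-identifiable. Linearized mode uses the scaled Jacobian at the
#' optimum and the same quantile; singular curvature falls back to profile
#' with a warning.
#'
#' @param fit a `fit_result`.
#' @param alpha significance level.
#' @param mode `"profile"` (default) or `"linearized"`.
#' @param params free net fluxes to profile (default all).
#' @param max_expand search range in multiples of the reference flux.
#' @return data frame: reaction, lower, upper, non_identifiable.
#' @export
confidence_intervals <- function(fit, alpha = 0.05, mode = c("profile",
                                                             "linearized"),
                                 params = NULL, max_expand = 2) {
  mode <- match.arg(mode)
  ctx <- fit$ctx
  params <- params %||% ctx$basis$free_net
  q <- qchisq(1 - alpha, df = fit$n_params)
  if (mode == "linearized") {
    J <- numDeriv_jacobian(ctx, fit$theta)
    H <- crossprod(J)
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev)) {
      warning("singular curvature; falling back to profile intervals",
              call. = FALSE)
      return(confidence_intervals(fit, alpha, "profile", params, max_expand))
    }
    V <- solve(H)
    idx <- match(params, theta_names(ctx))
    hw <- sqrt(q) * sqrt(diag(V)[idx])
    return(data.frame(reaction = params,
                      lower = (fit$theta[idx] - hw) * ctx$scale_ref,
                      upper = (fit$theta[idx] + hw) * ctx$scale_ref,
                      non_identifiable = FALSE, row.names = NULL))
  }
  out <- lapply(params, function(p) {
    i <- match(p, theta_names(ctx))
    lims <- vapply(c(-1, 1), function(sgn) {
      profile_limit(ctx, fit, i, sgn, fit$ssr + q, max_expand)
    }, 0) * ctx$scale_ref
    data.frame(reaction = p, lower = lims[1], upper = lims[2],
               non_identifiable = any(is.infinite(lims)))
  })
  do.call(rbind, out)
}

# finite-difference Jacobian of the residual vector (central differences)
numDeriv_jacobian <- function(ctx, theta, h_rel = 1e-5) {
  r0 <- fit_residuals(ctx, theta)
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- h_rel * max(abs(theta[j]), 1)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    rp <- fit_residuals(ctx, tp); rm <- fit_residuals(ctx, tm)
    if (inherits(rp, "infeasible") || inherits(rm, "infeasible")) {
      rp <- fit_residuals(ctx, tp <- theta)  # one-sided fallback
      h2 <- h
      tp[j] <- theta[j] + h2
      rp <- fit_residuals(ctx, tp)
      J[, j] <- (rp - r0) / h2
    } else {
      J[, j] <- (rp - rm) / (2 * h)
    }
  }
  J
}

# walk parameter i in direction sgn until SSR crosses the target;
# re-optimizing the others at each step. Returns the crossing point or
# +-Inf when the admissible range is exhausted (non-identifiable).
profile_limit <- function(ctx, fit, i, sgn, target, max_expand) {
  nn <- length(ctx$basis$free_net)
  lower <- c(ifelse(ctx$basis$bidirectional[ctx$basis$free_net], -2, 0),
             rep(0, length(ctx$basis$free_exchange)))
  upper <- c(rep(2, nn), rep(0.995, length(ctx$basis$free_exchange)))
  limit <- if (sgn < 0) lower[i] else upper[i]
  range_cap <- fit$theta[i] + sgn * max_expand
  limit <- if (sgn < 0) max(limit, range_cap) else min(limit, range_cap)
  prof_ssr <- function(v, start) {
    if (length(fit$theta) == 1) {
      return(list(ssr = weighted_ssr(v, ctx), theta = v))
    }
    obj <- function(rest) {
      th <- numeric(length(fit$theta)); th[i] <- v; th[-i] <- rest
      weighted_ssr(th, ctx)
    }
    o <- tryCatch(nlminb(start[-i], obj, lower = lower[-i], upper = upper[-i],
                         control = list(rel.tol = 1e-8, iter.max = 120)),
                  error = function(e) list(objective = Inf,
                                           par = start[-i]))
    th <- numeric(length(fit$theta)); th[i] <- v; th[-i] <- o$par
    list(ssr = o$objective, theta = th)
  }
  step <- 0.02 * max(abs(fit$theta[i]), 0.05)
  v <- fit$theta[i]; cur <- list(ssr = fit$ssr, theta = fit$theta)
  prev_v <- v; prev_ssr <- fit$ssr
  repeat {
    v_new <- v + sgn * step
    crossed_limit <- (sgn < 0 && v_new < limit) || (sgn > 0 && v_new > limit)
    if (crossed_limit) v_new <- limit
    res <- prof_ssr(v_new, cur$theta)
    if (res$ssr > target) {
      # bisect between prev_v and v_new
      lo <- prev_v; hi <- v_new; th <- cur$theta
      for (k in 1:20) {
        mid <- (lo + hi) / 2
        rm <- prof_ssr(mid, th)
        if (rm$ssr > target) hi <- mid else { lo <- mid; th <- rm$theta }
        if (abs(hi - lo) < 1e-4 * max(abs(v), 0.01)) break
      }
      return((lo + hi) / 2)
    }
    if (crossed_limit) return(sgn * Inf)
    prev_v <- v_new; prev_ssr <- res$ssr
    cur <- res; v <- v_new
    step <- step * 1.8
  }
}
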