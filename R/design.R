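# A priori tracer experiment design: Fisher information of a candidate
# tracer mixture at a prior flux state, D/A-optimality scores, and an
# exhaustive simplex-grid search over candidate mixtures.

#' Fisher information of a measurement configuration
#'
#' `J = S' Sigma^-1 S` with `S` the sensitivity of the simulated
#' measurements (MID mass traces of the panel, plus any rate measurements)
#' with respect to the free parameters, computed by central finite
#' differences at the prior flux state.
#'
#' @param ctx a [fit_context()] whose dataset holds the measurement
#'   configuration (values are ignored; SDs define Sigma).
#' @param theta parameter vector at which to evaluate (prior flux state).
#' @param h_rel relative step for the finite differences.
#' @return symmetric PSD matrix (n_params x n_params over free fluxes).
#' @export
fisher_information <- function(ctx, theta, h_rel = 1e-5) {
  J <- numDeriv_jacobian(ctx, theta, h_rel = h_rel)
  0.5 * (crossprod(J) + t(crossprod(J)))
}

#' D- or A-optimality score of an information matrix
#'
#' D: log pseudo-determinant (sum of log eigenvalues above a rank
#' tolerance); A: trace of the pseudo-inverse. Higher D (lower A) means a
#' more informative design.
#'
#' @param J information matrix.
#' @param criterion `"D"` or `"A"`.
#' @param tol relative eigenvalue tolerance defining the identifiable block.
#' @return scalar score.
#' @export
design_score <- function(J, criterion = c("D", "A"), tol = 1e-9) {
  criterion <- match.arg(criterion)
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  keep <- ev > tol * max(ev, 0)
  if (!any(keep)) return(if (criterion == "D") -Inf else Inf)
  if (criterion == "D") sum(log(ev[keep])) else sum(1 / ev[keep])
}

#' Enumerate mixture fractions on a simplex grid
#'
#' @param k number of candidates.
#' @param step grid step (default 0.01 as percent steps).
#' @return matrix, one row per mixture, rows sum to 1.
#' @export
simplex_grid <- function(k, step = 0.01) {
  n <- round(1 / step)
  if (k == 1) return(matrix(1, 1, 1))
  if (k == 2) {
    a <- seq(0, n) / n
    return(cbind(a, 1 - a, deparse.level = 0))
  }
  if (k == 3) {
    rows <- list()
    for (i in 0:n) for (j in 0:(n - i)) {
      rows[[length(rows) + 1]] <- c(i, j, n - i - j) / n
    }
    return(do.call(rbind, rows))
  }
  stop2("grid search supports at most 3 active tracers")
}

#' Optimal tracer mixture by exhaustive grid search
#'
#' Scores every candidate mixture on the simplex grid by the chosen
#' optimality criterion of its Fisher information at the prior flux state
#' and returns the best (ties broken lexicographically by fraction vector).
#'
#' @param model an `mfa_network`.
#' @param flux prior `flux_state`.
#' @param mu growth rate fixing the drains.
#' @param uptakes named fixed uptake fluxes.
#' @param candidates named list of binary label patterns (see
#'   [glucose_tracers()]); at least 2 unless a single candidate is given.
#' @param panel measured metabolites.
#' @param mid_sd measurement SD for all mass traces.
#' @param step simplex grid step (default 0.05).
#' @param criterion `"D"` or `"A"`.
#' @return a `design_result`: best mixture, score, and the full ranking.
#' @export
optimize_mixture <- function(model, flux, mu, uptakes, candidates,
                             panel, mid_sd = 0.025, step = 0.05,
                             criterion = "D") {
  if (!length(candidates)) stop2("empty candidate set")
  model <- expand_scrambling(model)
  grid <- simplex_grid(length(candidates), step)
  pats <- do.call(rbind, candidates)
  nc <- setNames(model$metabolites$carbons, model$metabolites$id)
  rows <- do.call(rbind, lapply(panel, function(m) {
    data.frame(metabolite = m, formula = NA, backbone_size = nc[[m]],
               group = m, mass_shift = 0:nc[[m]], value = 0.5, sd = mid_sd,
               stringsAsFactors = FALSE)
  }))
  rates <- data.frame(name = character(), value = numeric(), sd = numeric())
  scores <- numeric(nrow(grid))
  ctx0 <- NULL
  for (i in seq_len(nrow(grid))) {
    w <- grid[i, ]
    keep <- w > 0
    mix <- tracer_mixture(pats[keep, , drop = FALSE], w[keep])
    ds <- fit_dataset(rows, rates, mix)
    ctx <- fit_context(model, ds, mu, uptakes)
    if (is.null(ctx0)) ctx0 <- ctx
    th <- flux_to_theta(ctx, flux)
    Jm <- fisher_information(ctx, th)
    scores[i] <- design_score(Jm, criterion)
  }
  best <- if (criterion == "D") which(scores == max(scores)) else
    which(scores == min(scores))
  best <- best[1]  # grid enumeration order is lexicographic
  w <- grid[best, ]
  ranking <- data.frame(grid, score = scores)
  names(ranking)[seq_along(candidates)] <- names(candidates) %||%
    paste0("tracer", seq_along(candidates))
  structure(list(fractions = setNames(w, names(candidates)),
                 score = scores[best], criterion = criterion,
                 ranking = ranking[order(-scores), ]),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("design_result (%s-criterion): best mixture %s (score %.3f)\n",
              x$criterion,
              paste(sprintf("%s=%.0f%%", names(x$fractions),
                            100 * x$fractions), collapse = ", "),
              x$score))
  invisible(x)
}
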