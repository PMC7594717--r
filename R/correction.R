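# Natural isotope abundance correction of measured MIDs.
#
# Raw MS mass traces of a fragment mix the 13C enrichment of the inferred
# carbon backbone with natural heavy isotopes of every other atom in the
# detected ion. The correction matrix M maps the true backbone MID to the
# raw trace, raw = M %*% true; correction solves the triangular system.

#' IUPAC natural isotope abundances used for correction
#'
#' Mass-shift distributions per element (relative abundance of +0, +1, +2
#' isotopes). Values are IUPAC 2021 representative abundances.
#'
#' @return named list of numeric vectors.
#' @export
isotope_abundances <- function() {
  list(C = c(0.9893, 0.0107),
       H = c(0.999885, 0.000115),
       N = c(0.99636, 0.00364),
       O = c(0.99757, 0.00038, 0.00205),
       P = 1,
       S = c(0.9499, 0.0075, 0.0425))
}

#' Describe a measured fragment
#'
#' @param metabolite metabolite id.
#' @param backbone number of backbone carbons whose labeling is inferred.
#' @param formula elemental formula of the detected ion, e.g. `"C6H13O9P"`.
#' @param group measurement group id (defaults to the metabolite).
#' @return a `fragment`.
#' @export
fragment <- function(metabolite, backbone, formula, group = metabolite) {
  counts <- parse_formula(formula)
  if ((counts["C"] %||% 0) < backbone) {
    stop2("formula carbon count below backbone size for ", metabolite)
  }
  structure(list(metabolite = metabolite, backbone = as.integer(backbone),
                 formula = formula, counts = counts, group = group),
            class = "fragment")
}

parse_formula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  counts <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  for (p in parts) {
    el <- gsub("[0-9]", "", p)
    n <- gsub("[^0-9]", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(counts)) stop2("unsupported element in formula: ", el)
    counts[el] <- counts[el] + n
  }
  if (any(counts < 0)) stop2("negative element count")
  counts
}

#' Natural-abundance correction matrix of a fragment
#'
#' Builds the lower-triangular matrix `M` with `raw = M %*% true`, from the
#' isotope abundance distributions of every atom of the ion except the
#' backbone carbons being inferred. With `include_backbone = TRUE` the
#' binomial 13C contribution of the (mass-dependent) number of unlabeled
#' backbone carbons is folded in as well, which is the appropriate matrix
#' when the tracer substrate itself carries natural 13C on unlabeled
#' positions.
#'
#' @param frag a [fragment()].
#' @param abundances isotope table, see [isotope_abundances()].
#' @param include_backbone fold in backbone natural 13C (default FALSE).
#' @return (backbone+1) x (backbone+1) matrix, columns summing to <= 1.
#' @export
correction_matrix <- function(frag, abundances = isotope_abundances(),
                              include_backbone = FALSE) {
  nb <- frag$backbone
  counts <- frag$counts
  counts["C"] <- counts["C"] - nb
  base <- 1
  for (el in names(counts)) {
    d <- abundances[[el]] %||% 1
    for (i in seq_len(counts[el])) base <- mid_convolve(base, d)
  }
  aC <- abundances$C[2]
  M <- matrix(0, nb + 1, nb + 1)
  for (j in 0:nb) {
    col <- base
    if (include_backbone && nb - j > 0) {
      col <- mid_convolve(col, dbinom(0:(nb - j), nb - j, aC))
    }
    ix <- (j + 1):min(nb + 1, j + length(col))
    M[ix, j + 1] <- col[seq_along(ix)]
  }
  M
}

#' Correct a raw MID for natural isotope abundance
#'
#' Solves `M %*% corrected = raw`, clips small negative entries and
#' renormalizes to sum 1.
#'
#' @param raw raw MID vector of length backbone + 1.
#' @param frag a [fragment()].
#' @param neg_tol most negative corrected entry tolerated before erroring.
#' @param ... passed to [correction_matrix()].
#' @return corrected MID vector.
#' @export
correct_mid <- function(raw, frag, neg_tol = 1e-3, ...) {
  M <- correction_matrix(frag, ...)
  if (rcond(M) < 1e-12) stop2("ill-conditioned correction matrix for ",
                              frag$metabolite)
  x <- solve(M, raw)
  if (any(x < -neg_tol)) {
    stop2("correction produced a negative fraction below tolerance for ",
          frag$metabolite, " (min ", signif(min(x), 3), ")")
  }
  if (any(x < 0)) {
    warning("clipping small negative corrected fractions for ",
            frag$metabolite, call. = FALSE)
    x[x < 0] <- 0
  }
  x / sum(x)
}
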