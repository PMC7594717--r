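# Elementary metabolite unit (EMU) decomposition and steady-state MID
# simulation.
#
# The network is decomposed, starting from the target EMUs, into cascaded
# linear systems ordered by EMU size. Condensation reactions couple an EMU to
# convolutions of strictly smaller EMUs, so each size level solves a dense
# linear system A X = B Y whose coefficients are linear in the directed
# reaction fluxes.

#' Target EMUs for full carbon backbones
#'
#' @param model an `mfa_network`.
#' @param mets metabolite ids.
#' @return list of EMU specs (met, atoms).
#' @export
backbone_emus <- function(model, mets) {
  lapply(mets, function(m) {
    nc <- model$metabolites$carbons[model$metabolites$id == m]
    if (!length(nc)) stop2("unknown metabolite: ", m)
    list(met = m, atoms = seq_len(nc))
  })
}

# Directed reaction instances of the (expanded) model: forward instance per
# reaction and a backward instance (educts/products swapped) per
# bidirectional reaction. fluxes are weight * forward/backward of the parent.
directed_instances <- function(model) {
  inst <- list()
  for (r in model$reactions) {
    inst[[length(inst) + 1]] <- list(parent = r$variant_of, weight = r$weight,
                                     dir = 1, educts = r$educts,
                                     products = r$products)
    if (r$bidirectional) {
      inst[[length(inst) + 1]] <- list(parent = r$variant_of, weight = r$weight,
                                       dir = -1, educts = r$products,
                                       products = r$educts)
    }
  }
  inst
}

instance_fluxes <- function(instances, flux) {
  vapply(instances, function(ins) {
    base <- if (ins$dir > 0) flux$forward[ins$parent] else flux$backward[ins$parent]
    if (is.na(base)) stop2("missing flux for reaction ", ins$parent)
    ins$weight * base
  }, 0)
}

#' Decompose a network into an EMU system
#'
#' @param model an `mfa_network` (scrambling is expanded automatically).
#' @param targets list of EMU specs as returned by [backbone_emus()].
#' @return an `emu_system` with size-ordered levels.
#' @export
decompose <- function(model, targets) {
  model <- expand_scrambling(model)
  mets <- model$metabolites
  role <- setNames(mets$role, mets$id)
  instances <- directed_instances(model)

  # per-pool consumption terms: list of (instance index, multiplicity)
  cons <- list()
  for (i in seq_along(instances)) {
    tab <- table(vapply(instances[[i]]$educts, `[[`, "", "met"))
    for (m in names(tab)) {
      cons[[m]] <- rbind(cons[[m]] %||% NULL, c(i, tab[[m]]))
    }
  }
  # index product occurrences by metabolite
  prod_occ <- list()
  for (i in seq_along(instances)) {
    ps <- instances[[i]]$products
    for (j in seq_along(ps)) {
      m <- ps[[j]]$met
      if (is.null(ps[[j]]$atoms)) next
      prod_occ[[m]] <- rbind(prod_occ[[m]] %||% NULL, c(i, j))
    }
  }

  emus <- list()      # key -> list(met, atoms, size, contribs)
  queue <- list()
  push <- function(met, atoms) {
    key <- emu_key(met, atoms)
    if (is.null(emus[[key]]) && role[[met]] == "balanced") {
      emus[[key]] <<- list(met = met, atoms = atoms, size = length(atoms),
                           contribs = list())
      queue[[length(queue) + 1]] <<- key
    }
    key
  }
  for (tg in targets) {
    if (!tg$met %in% mets$id) stop2("unknown target metabolite: ", tg$met)
    if (role[[tg$met]] == "balanced") push(tg$met, sort(tg$atoms))
  }

  while (length(queue)) {
    key <- queue[[1]]; queue <- queue[-1]
    e <- emus[[key]]
    occ <- prod_occ[[e$met]]
    contribs <- list()
    if (!is.null(occ)) {
      for (k in seq_len(nrow(occ))) {
        i <- occ[k, 1]; j <- occ[k, 2]
        ins <- instances[[i]]
        term <- ins$products[[j]]
        Lp <- term$atoms[e$atoms]
        refs <- list()
        for (t in ins$educts) {
          if (is.null(t$atoms)) next
          pos <- sort(which(t$atoms %in% Lp))
          if (!length(pos)) next
          rmet <- t$met
          rtype <- if (role[[rmet]] == "balanced") "emu" else "input"
          if (rtype == "emu") push(rmet, pos)
          refs[[length(refs) + 1]] <- list(met = rmet, atoms = pos,
                                           type = rtype,
                                           key = emu_key(rmet, pos))
        }
        if (sum(lengths(lapply(refs, `[[`, "atoms"))) != length(Lp)) {
          stop2("atom bookkeeping failure at ", key)  # should not happen
        }
        contribs[[length(contribs) + 1]] <- list(inst = i, refs = refs)
      }
    }
    if (!length(contribs)) {
      stop2("metabolite ", e$met, " (EMU ", key,
            ") has no producing reaction; unreachable from inputs")
    }
    emus[[key]]$contribs <- contribs
  }

  # order levels by size; build integer-indexed assembly templates
  sizes <- sort(unique(vapply(emus, `[[`, 0L, "size")))
  levels <- list()
  solved_index <- character()
  for (s in sizes) {
    keys <- names(emus)[vapply(emus, `[[`, 0L, "size") == s]
    keys <- sort(keys)
    idx <- setNames(seq_along(keys), keys)
    ia <- integer(); ja <- integer(); insta <- integer(); coefa <- numeric()
    ir <- integer(); jr <- integer(); instr <- integer()
    ydefs <- list(); ymap <- character()
    pools <- vapply(keys, function(k) emus[[k]]$met, "")
    for (k in keys) {
      row <- idx[[k]]
      cm <- cons[[emus[[k]]$met]]
      if (is.null(cm)) {
        stop2("pool ", emus[[k]]$met, " has no consuming reaction")
      }
      for (q in seq_len(nrow(cm))) {
        ia <- c(ia, row); ja <- c(ja, row)
        insta <- c(insta, cm[q, 1]); coefa <- c(coefa, cm[q, 2])
      }
      for (cb in emus[[k]]$contribs) {
        refs <- cb$refs
        if (length(refs) == 1 && refs[[1]]$type == "emu" &&
            emus[[refs[[1]]$key]]$size == s) {
          ia <- c(ia, row); ja <- c(ja, idx[[refs[[1]]$key]])
          insta <- c(insta, cb$inst); coefa <- c(coefa, -1)
        } else {
          sig <- paste(vapply(refs, function(r) paste0(r$type, ":", r$key), ""),
                       collapse = "*")
          yi <- match(sig, ymap)
          if (is.na(yi)) {
            ydefs[[length(ydefs) + 1]] <- refs
            ymap <- c(ymap, sig)
            yi <- length(ydefs)
          }
          ir <- c(ir, row); jr <- c(jr, yi); instr <- c(instr, cb$inst)
        }
      }
    }
    levels[[as.character(s)]] <- list(
      size = s, keys = keys, pools = pools,
      ia = ia, ja = ja, insta = insta, coefa = coefa,
      ir = ir, jr = jr, instr = instr, ydefs = ydefs)
  }

  structure(list(model = model, instances = instances, levels = levels,
                 targets = targets, emus = emus),
            class = "emu_system")
}

#' @export
print.emu_system <- function(x, ...) {
  sz <- vapply(x$levels, function(l) length(l$keys), 0L)
  cat(sprintf("emu_system: %d EMUs in %d size levels (max size %s)\n",
              length(x$emus), length(x$levels),
              names(x$levels)[length(x$levels)]))
  cat("  per level:", paste(sprintf("%s:%d", names(x$levels), sz),
                            collapse = " "), "\n")
  invisible(x)
}

#' Simulate steady-state MIDs for every EMU of a system
#'
#' Solves the cascaded EMU linear systems by dense direct solves.
#'
#' @param system an `emu_system`.
#' @param flux a `flux_state` satisfying the pool balances.
#' @param tracer_input labeling of the input pools, see [input_labeling()].
#' @param strict error when MID normalization drifts (default TRUE); with
#'   `strict = FALSE` rows are renormalized instead, which tolerates slightly
#'   unbalanced flux vectors during penalized optimization steps.
#' @return named list of MID vectors (sum 1), keyed `"MET|i,j,..."`; target
#'   EMUs on input pools are included directly from the tracer input.
#' @export
simulate_mids <- function(system, flux, tracer_input, strict = TRUE) {
  fdir <- instance_fluxes(system$instances, flux)
  solved <- list()
  for (lv in system$levels) {
    n <- length(lv$keys)
    w <- lv$size + 1
    A <- matrix(0, n, n)
    av <- lv$coefa * fdir[lv$insta]
    for (q in seq_along(av)) A[lv$ia[q], lv$ja[q]] <- A[lv$ia[q], lv$ja[q]] + av[q]
    dg <- diag(A)
    scale <- max(abs(fdir), 1)
    if (any(dg <= 1e-12 * scale)) {
      stop2("pool with zero total influx/outflux: ",
            paste(unique(lv$pools[dg <= 1e-12 * scale]), collapse = ", "))
    }
    RHS <- matrix(0, n, w)
    if (length(lv$ir)) {
      Y <- matrix(0, length(lv$ydefs), w)
      for (yi in seq_along(lv$ydefs)) {
        refs <- lv$ydefs[[yi]]
        mid <- NULL
        for (r in refs) {
          cm <- if (r$type == "input") {
            input_emu_mid(tracer_input, r$met, r$atoms)
          } else {
            solved[[r$key]]
          }
          mid <- if (is.null(mid)) cm else mid_convolve(mid, cm)
        }
        Y[yi, ] <- mid
      }
      rv <- fdir[lv$instr]
      for (q in seq_along(rv)) {
        RHS[lv$ir[q], ] <- RHS[lv$ir[q], ] + rv[q] * Y[lv$jr[q], ]
      }
    }
    X <- solve(A, RHS)
    rs <- rowSums(X)
    if (strict && any(abs(rs - 1) > 1e-6)) {
      stop2("MID normalization lost at level ", lv$size,
            " (worst pool ", lv$pools[which.max(abs(rs - 1))], ")")
    }
    if (any(rs <= 0)) stop2("degenerate MID solution at level ", lv$size)
    X <- X / rs
    for (i in seq_len(n)) solved[[lv$keys[i]]] <- X[i, ]
  }
  # targets on input pools come straight from the tracer input
  for (tg in system$targets) {
    key <- emu_key(tg$met, sort(tg$atoms))
    if (is.null(solved[[key]])) {
      role <- system$model$metabolites$role[system$model$metabolites$id == tg$met]
      if (role == "input") {
        solved[[key]] <- input_emu_mid(tracer_input, tg$met, sort(tg$atoms))
      }
    }
  }
  solved
}

#' Convolution of two mass isotopomer distributions
#'
#' Cauchy product: the MID of a molecule assembled from two independent
#' fragments.
#'
#' @param a,b MID vectors.
#' @return MID of length `length(a) + length(b) - 1`.
#' @export
mid_convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    ix <- i:(i + length(b) - 1)
    out[ix] <- out[ix] + a[i] * b
  }
  out
}

#' Export simulated MIDs as a table
#'
#' @param mids named list from [simulate_mids()].
#' @param file optional CSV path.
#' @return data frame with metabolite, fragment atoms and m0..mn columns in
#'   long format (one row per mass shift).
#' @export
mid_table <- function(mids, file = NULL) {
  rows <- lapply(names(mids), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(metabolite = parts[1], fragment = parts[2],
               mass_shift = seq_along(mids[[k]]) - 1L,
               fraction = as.numeric(mids[[k]]), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(file)) {
    write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
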