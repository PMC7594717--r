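# Atom-mapped metabolic network model
#
# A network document declares metabolite pools (balanced intracellular pools,
# non-balanced input/output pools), reactions with per-carbon atom transitions
# in the letter-string convention ("G6P#abcdef <-> F6P#abcdef"), a biomass
# demand table (umol per gCDW of each precursor, realized as growth-scaled
# drain reactions), and optional cofactor annotations.

#' Parse a metabolic network specification
#'
#' Reads a structured (YAML) network document with sections `metabolites`,
#' `reactions`, and optionally `biomass`, `cofactors`, `nadph_coefficient`,
#' `preferred_free`, `fixed_exchange` and `tracer_inputs`, and returns a
#' validated network model.
#'
#' Each reaction is given as an equation in the atom-map letter convention,
#' e.g. `"FBP#abcdef <-> DHAP#cba + GAP#def"`. Letters label educt carbons;
#' every letter must appear exactly once on each side (carbon conservation).
#' Products that are non-balanced output pools may omit the atom map (drain /
#' sink reactions); such reactions must be unidirectional.
#'
#' @param document path to a YAML network file, or a YAML string, or an
#'   already-parsed list with the same structure.
#' @return an object of class `mfa_network`.
#' @export
load_network <- function(document) {
  doc <- if (is.list(document)) {
    document
  } else if (length(document) == 1 && file.exists(document)) {
    yaml::read_yaml(document)
  } else {
    yaml::yaml.load(paste(document, collapse = "\n"))
  }
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop2("network document needs 'metabolites' and 'reactions' sections")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id, carbons = as.integer(m$carbons %||% m$n_carbons),
               role = m$role %||% "balanced",
               symmetric = isTRUE(m$symmetric), stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(mets$id)) stop2("duplicate metabolite ids")
  if (!all(mets$role %in% c("balanced", "input", "output"))) {
    stop2("metabolite role must be balanced, input or output")
  }
  rxns <- lapply(doc$reactions, function(r) {
    parse_reaction(r$id, r$equation, mets)
  })
  names(rxns) <- vapply(rxns, `[[`, "", "id")
  if (anyDuplicated(names(rxns))) stop2("duplicate reaction ids")

  model <- structure(list(
    metabolites = mets,
    reactions = rxns,
    biomass = doc$biomass %||% list(demand = list()),
    nadph_coefficient = doc$nadph_coefficient %||% NA_real_,
    nadh_biomass = doc$nadh_biomass %||% 0,
    cofactors = doc$cofactors %||% list(),
    preferred_free = unlist(doc$preferred_free) %||% character(),
    fixed_exchange = unlist(doc$fixed_exchange) %||% character(),
    nadph_sources = doc$nadph_sources %||% list(),
    tracer_inputs = doc$tracer_inputs %||% list(),
    expanded = FALSE
  ), class = "mfa_network")
  # materialize biomass drains as reactions if requested by the document
  if (length(model$biomass$demand)) model <- add_biomass_drains(model)
  validate_network(model)
  model
}

# Parse one reaction equation into educt/product terms with atom letters.
parse_reaction <- function(id, equation, mets) {
  if (is.null(id) || is.null(equation)) stop2("reaction needs id and equation")
  bidir <- grepl("<->", equation, fixed = TRUE)
  sides <- strsplit(equation, if (bidir) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop2("reaction ", id, ": malformed equation")
  parse_side <- function(s) {
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    terms <- terms[nzchar(terms)]
    lapply(terms, function(tm) {
      parts <- strsplit(tm, "#", fixed = TRUE)[[1]]
      met <- trimws(parts[1])
      if (!met %in% mets$id) {
        stop2("reaction ", id, ": undeclared metabolite '", met, "'")
      }
      atoms <- if (length(parts) > 1) strsplit(parts[2], "")[[1]] else NULL
      nc <- mets$carbons[mets$id == met]
      if (!is.null(atoms) && length(atoms) != nc) {
        stop2("reaction ", id, ": atom map for ", met, " has ",
              length(atoms), " letters, metabolite has ", nc, " carbons")
      }
      list(met = met, atoms = atoms)
    })
  }
  educts <- parse_side(sides[1])
  products <- parse_side(sides[2])
  # carbon conservation: every educt letter appears once; product letters are
  # a permutation of educt letters, except letters lost into unmapped sinks.
  el <- unlist(lapply(educts, `[[`, "atoms"))
  pl <- unlist(lapply(products, `[[`, "atoms"))
  if (anyDuplicated(el)) stop2("reaction ", id, ": duplicated educt letters")
  if (anyDuplicated(pl)) stop2("reaction ", id, ": duplicated product letters")
  unmapped_sink <- any(vapply(products, function(p) is.null(p$atoms), TRUE))
  for (p in products) {
    if (is.null(p$atoms)) {
      role <- mets$role[mets$id == p$met]
      if (role != "output") {
        stop2("reaction ", id, ": product ", p$met,
              " lacks an atom map but is not an output pool")
      }
    }
  }
  if (!all(pl %in% el)) {
    stop2("reaction ", id, ": product letters not drawn from educt letters")
  }
  if (!unmapped_sink && length(pl) != length(el)) {
    stop2("reaction ", id, ": carbon not conserved (", length(el),
          " educt vs ", length(pl), " product carbons)")
  }
  for (e in educts) {
    if (is.null(e$atoms) && mets$carbons[mets$id == e$met] > 0) {
      stop2("reaction ", id, ": educt ", e$met, " lacks an atom map")
    }
  }
  if (bidir && unmapped_sink) {
    stop2("reaction ", id, ": bidirectional reactions need full atom maps")
  }
  list(id = id, bidirectional = bidir, educts = educts, products = products,
       variant_of = id, weight = 1)
}

# Biomass drains: one unidirectional sink reaction per precursor with demand
# coefficient (umol/gCDW); flux is coefficient * mu when fluxes are realized.
add_biomass_drains <- function(model) {
  dem <- model$biomass$demand
  sink <- model$biomass$sink %||% "BM"
  if (!sink %in% model$metabolites$id) {
    stop2("biomass sink pool '", sink, "' not declared")
  }
  for (met in names(dem)) {
    nc <- model$metabolites$carbons[model$metabolites$id == met]
    if (!length(nc)) stop2("biomass precursor '", met, "' not declared")
    letters_map <- paste(letters[seq_len(nc)], collapse = "")
    eq <- sprintf("%s#%s -> %s", met, letters_map, sink)
    rid <- paste0(met, "_bm")
    model$reactions[[rid]] <- parse_reaction(rid, eq, model$metabolites)
  }
  model
}

validate_network <- function(model) {
  mets <- model$metabolites
  for (r in model$reactions) {
    for (tm in c(r$educts, r$products)) {
      if (!tm$met %in% mets$id) stop2("reaction ", r$id, ": unknown pool")
    }
  }
  invisible(model)
}

#' @export
print.mfa_network <- function(x, ...) {
  s <- network_summary(x)
  cat(sprintf(paste0(
    "mfa_network: %d reactions (%d bidirectional, %d unidirectional)%s\n",
    "  %d balanced pools, %d non-balanced pools\n"),
    s$n_reactions, s$n_bidirectional, s$n_unidirectional,
    if (x$expanded) " [scrambling-expanded]" else "",
    s$n_balanced, s$n_nonbalanced))
  invisible(x)
}

#' Dimension summary of a network model
#'
#' @param model an `mfa_network`.
#' @return list with reaction and pool counts.
#' @export
network_summary <- function(model) {
  bidir <- vapply(model$reactions, `[[`, TRUE, "bidirectional")
  list(n_reactions = length(model$reactions),
       n_bidirectional = sum(bidir),
       n_unidirectional = sum(!bidir),
       n_balanced = sum(model$metabolites$role == "balanced"),
       n_nonbalanced = sum(model$metabolites$role != "balanced"))
}

#' Export the reaction table
#'
#' Writes (or returns) a TSV-style data frame with one row per reaction:
#' id, direction, educts, products, atom map and variant weight.
#'
#' @param model an `mfa_network`.
#' @param file optional path; when given the table is written as TSV.
#' @return the table, invisibly when written to file.
#' @export
reaction_table <- function(model, file = NULL) {
  fmt_side <- function(terms) {
    paste(vapply(terms, function(tm) {
      if (is.null(tm$atoms)) tm$met
      else paste0(tm$met, "#", paste(tm$atoms, collapse = ""))
    }, ""), collapse = " + ")
  }
  tab <- do.call(rbind, lapply(model$reactions, function(r) {
    data.frame(id = r$id,
               direction = if (r$bidirectional) "bidirectional" else "unidirectional",
               educts = fmt_side(r$educts), products = fmt_side(r$products),
               variant_of = r$variant_of, weight = r$weight,
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  if (!is.null(file)) {
    write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @importFrom utils write.table
NULL

# ---- scrambling ------------------------------------------------------------

#' Expand scrambling reactions for C-symmetric metabolites
#'
#' Every reaction touching a rotationally symmetric metabolite (e.g.
#' succinate, fumarate, meso-diaminopimelate) is replaced by orientation
#' variants with equal weights: for each symmetric molecule occurrence the
#' atom string may be read in either direction, and indistinguishable
#' orientations are merged. Variant fluxes are the parent flux times the
#' variant weight, so stoichiometry and all pool balances are unchanged.
#'
#' @param model an `mfa_network` with `symmetric` flags set.
#' @return an `mfa_network` with `expanded = TRUE`.
#' @export
expand_scrambling <- function(model) {
  if (model$expanded) return(model)
  sym <- model$metabolites$id[model$metabolites$symmetric]
  out <- list()
  for (r in model$reactions) {
    occ <- list()  # (side, index) of symmetric terms with atoms
    for (i in seq_along(r$educts)) {
      if (r$educts[[i]]$met %in% sym && !is.null(r$educts[[i]]$atoms))
        occ[[length(occ) + 1]] <- c("e", i)
    }
    for (i in seq_along(r$products)) {
      if (r$products[[i]]$met %in% sym && !is.null(r$products[[i]]$atoms))
        occ[[length(occ) + 1]] <- c("p", i)
    }
    if (!length(occ)) {
      out[[r$id]] <- r
      next
    }
    k <- length(occ)
    variants <- list()
    for (mask in 0:(2^k - 1)) {
      v <- r
      for (j in seq_len(k)) {
        if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) > 0L) {
          side <- occ[[j]][1]; idx <- as.integer(occ[[j]][2])
          if (side == "e") v$educts[[idx]]$atoms <- rev(v$educts[[idx]]$atoms)
          else v$products[[idx]]$atoms <- rev(v$products[[idx]]$atoms)
        }
      }
      sig <- canonical_map_signature(v)
      if (is.null(variants[[sig]])) {
        v$weight <- r$weight / 2^k
        variants[[sig]] <- v
      } else {
        variants[[sig]]$weight <- variants[[sig]]$weight + r$weight / 2^k
      }
    }
    if (length(variants) == 1) {
      out[[r$id]] <- r
    } else {
      suffix <- letters[seq_along(variants)]
      for (j in seq_along(variants)) {
        v <- variants[[j]]
        v$id <- paste0(r$id, "_", suffix[j])
        v$variant_of <- r$id
        out[[v$id]] <- v
      }
    }
  }
  model$reactions <- out
  model$expanded <- TRUE
  model
}

# Canonical signature of an atom map, invariant to letter naming: relabel
# educt letters in reading order, then print the product strings.
canonical_map_signature <- function(r) {
  el <- unlist(lapply(r$educts, `[[`, "atoms"))
  ren <- setNames(letters[seq_along(el)], el)
  paste(vapply(r$products, function(p) {
    if (is.null(p$atoms)) "." else paste(ren[p$atoms], collapse = "")
  }, ""), collapse = "|")
}

# ---- stoichiometry ---------------------------------------------------------

# Stoichiometric matrix over balanced pools x parent reactions.
# Scrambling variants collapse onto their parent (weights sum to 1 and all
# variants share the parent stoichiometry).
balanced_stoichiometry <- function(model) {
  parents <- unique(vapply(model$reactions, `[[`, "", "variant_of"))
  bal <- model$metabolites$id[model$metabolites$role == "balanced"]
  S <- matrix(0, length(bal), length(parents), dimnames = list(bal, parents))
  seen <- character()
  for (r in model$reactions) {
    if (r$variant_of %in% seen) next  # one variant carries the stoichiometry
    seen <- c(seen, r$variant_of)
    for (tm in r$educts) if (tm$met %in% bal) {
      S[tm$met, r$variant_of] <- S[tm$met, r$variant_of] - 1
    }
    for (tm in r$products) if (tm$met %in% bal) {
      S[tm$met, r$variant_of] <- S[tm$met, r$variant_of] + 1
    }
  }
  S
}

# Parent-level direction flags (TRUE if bidirectional)
parent_directions <- function(model) {
  parents <- unique(vapply(model$reactions, `[[`, "", "variant_of"))
  bid <- setNames(logical(length(parents)), parents)
  for (r in model$reactions) bid[r$variant_of] <- bid[r$variant_of] || r$bidirectional
  bid
}
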