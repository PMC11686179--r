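## Core domain types: metabolites, reactions, metabolic models.
##
## A model is a plain list with class "mbx_model":
##   id         - strain/species identifier
##   taxonomy   - list(species, genus, phylum)
##   mets       - data.frame(id, name, formula, charge, compartment)
##   rxns       - data.frame(id, name, lb, ub, subsystem, kind)
##   stoich     - named list (reaction id -> named numeric: metabolite id -> coeff)
##   biomass_id - id of the biomass reaction (may be NA for reaction catalogs)
##
## Metabolite ids carry an AGORA/VMH-style compartment suffix: "lcts[c]",
## "glc_D[e]", lumen "[u]", diet "[d]", fecal "[fe]".

REACTION_KINDS <- c("internal", "transport", "exchange", "biomass", "demand", "sink")
BALANCE_EXEMPT_KINDS <- c("exchange", "biomass", "demand", "sink")
COMPARTMENTS <- c("c", "e", "u", "d", "fe")

met_compartment <- function(id) {
  m <- regmatches(id, regexec("\\[([a-z]+)\\]$", id))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

met_base <- function(id) sub("\\[[a-z]+\\]$", "", id)

#' Build a metabolite table
#'
#' @param id Metabolite ids with compartment suffix, e.g. `"lcts[c]"`.
#' @param name Display names (defaults to the id).
#' @param formula Elemental formulas in Hill notation.
#' @param charge Integer charges.
#' @param compartment Compartment tags; inferred from the id suffix if omitted.
#' @return A data.frame with columns id, name, formula, charge, compartment.
#' @export
metabolites <- function(id, name = id, formula, charge = 0L, compartment = NULL) {
  if (is.null(compartment)) compartment <- met_compartment(id)
  data.frame(id = id, name = name, formula = formula,
             charge = as.numeric(charge), compartment = compartment,
             stringsAsFactors = FALSE)
}

#' Build a reaction table plus stoichiometry list from equation strings
#'
#' Equations use the form `"1 a[c] + 2 b[c] -> 1 c[c]"`; coefficients default
#' to 1 and either side may be empty (exchange reactions are written
#' `"1 glc_D[e] ->"`). Reversibility is carried by the bounds, not the arrow.
#'
#' @param id Reaction ids.
#' @param equation Equation strings (one per reaction).
#' @param lb,ub Flux bounds (mmol/gDW/h at strain scale).
#' @param name Display names.
#' @param subsystem Subsystem labels.
#' @param kind One of `r toString(REACTION_KINDS)`.
#' @return A list with elements `rxns` (data.frame) and `stoich` (named list),
#'   the "reaction set" currency accepted by [add_reactions()].
#' @export
reactions <- function(id, equation, lb = -1000, ub = 1000, name = id,
                      subsystem = "", kind = "internal") {
  n <- length(id)
  rxns <- data.frame(id = id, name = rep_len(name, n), lb = rep_len(lb, n),
                     ub = rep_len(ub, n), subsystem = rep_len(subsystem, n),
                     kind = rep_len(kind, n), stringsAsFactors = FALSE)
  stoich <- lapply(equation, parse_equation)
  names(stoich) <- id
  list(rxns = rxns, stoich = stoich)
}

#' Parse a reaction equation string into signed stoichiometry
#' @param equation A string like `"1 a[c] + 1 b[c] -> 2 c[c]"`.
#' @return Named numeric vector (metabolite id -> signed coefficient).
#' @export
parse_equation <- function(equation) {
  parts <- strsplit(equation, "->", fixed = TRUE)[[1]]
  if (length(parts) > 2L || !grepl("->", equation, fixed = TRUE)) {
    stop(sprintf("equation '%s' must contain exactly one '->'", equation),
         call. = FALSE)
  }
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric(0))
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("^([0-9.]+[eE]?[-+0-9]*\\s+)?(\\S+)$", tm))[[1]]
      if (length(m) == 0L) {
        stop(sprintf("cannot parse equation term '%s'", tm), call. = FALSE)
      }
      coeff <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      met <- m[3]
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coeff
    }
    out
  }
  lhs <- parse_side(parts[1], -1)
  rhs <- if (length(parts) == 2L) parse_side(parts[2], +1) else numeric(0)
  st <- lhs
  for (met in names(rhs)) {
    st[met] <- (if (met %in% names(st)) st[[met]] else 0) + rhs[[met]]
  }
  st <- st[st != 0]
  if (length(st) == 0L) {
    stop(sprintf("equation '%s' has empty net stoichiometry", equation),
         call. = FALSE)
  }
  st
}

#' Render signed stoichiometry as an equation string
#' @param stoich Named numeric vector of signed coefficients.
#' @return A string in the dialect accepted by [parse_equation()].
#' @export
format_equation <- function(stoich) {
  fmt <- function(ids, coeffs) {
    paste(sprintf("%s %s", format(coeffs, trim = TRUE, scientific = FALSE,
                                  digits = 15), ids), collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt(names(lhs), -unname(lhs)), "->", fmt(names(rhs), unname(rhs)))
}

#' Construct (and validate) a metabolic model
#'
#' @param id Model identifier.
#' @param mets Metabolite table, see [metabolites()].
#' @param rxns Reaction table (id, name, lb, ub, subsystem, kind).
#' @param stoich Named list of signed stoichiometries aligned with `rxns$id`.
#' @param biomass_id Id of the biomass reaction; `NA` is allowed only for
#'   reaction-catalog fragments.
#' @param taxonomy A list with species, genus, phylum (free text).
#' @return An object of class `mbx_model`.
#' @export
metabolic_model <- function(id, mets, rxns, stoich, biomass_id = NA_character_,
                            taxonomy = list(species = NA_character_,
                                            genus = NA_character_,
                                            phylum = NA_character_)) {
  model <- structure(list(id = id, taxonomy = taxonomy, mets = mets,
                          rxns = rxns, stoich = stoich[rxns$id],
                          biomass_id = biomass_id),
                     class = "mbx_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  mets <- model$mets; rxns <- model$rxns
  if (anyDuplicated(mets$id)) {
    stop(sprintf("duplicate metabolite ids: %s",
                 toString(unique(mets$id[duplicated(mets$id)]))), call. = FALSE)
  }
  if (anyDuplicated(rxns$id)) {
    stop(sprintf("duplicate reaction ids: %s",
                 toString(unique(rxns$id[duplicated(rxns$id)]))), call. = FALSE)
  }
  suff <- met_compartment(mets$id)
  bad <- is.na(suff) | suff != mets$compartment
  if (any(bad)) {
    stop(sprintf("metabolite id/compartment mismatch: %s",
                 toString(mets$id[bad])), call. = FALSE)
  }
  if (any(rxns$lb > rxns$ub)) {
    stop(sprintf("lower bound exceeds upper bound for: %s",
                 toString(rxns$id[rxns$lb > rxns$ub])), call. = FALSE)
  }
  if (!all(rxns$kind %in% REACTION_KINDS)) {
    stop(sprintf("unknown reaction kind(s): %s",
                 toString(setdiff(rxns$kind, REACTION_KINDS))), call. = FALSE)
  }
  if (!setequal(names(model$stoich), rxns$id) ||
      length(model$stoich) != nrow(rxns)) {
    stop("stoichiometry list does not match reaction table", call. = FALSE)
  }
  all_met_refs <- unique(unlist(lapply(model$stoich, names), use.names = FALSE))
  unresolved <- setdiff(all_met_refs, mets$id)
  if (length(unresolved) > 0L) {
    stop(sprintf("unresolved metabolite reference(s): %s", toString(unresolved)),
         call. = FALSE)
  }
  for (rid in rxns$id) {
    st <- model$stoich[[rid]]
    if (any(st == 0)) {
      stop(sprintf("reaction %s has zero stoichiometric coefficients", rid),
           call. = FALSE)
    }
  }
  exch <- rxns$id[rxns$kind == "exchange"]
  nmet <- vapply(model$stoich[exch], length, integer(1))
  if (any(nmet != 1L)) {
    stop(sprintf("exchange reaction(s) must touch exactly one metabolite: %s",
                 toString(exch[nmet != 1L])), call. = FALSE)
  }
  if (!is.na(model$biomass_id) && !model$biomass_id %in% rxns$id) {
    stop(sprintf("biomass reaction '%s' not in model", model$biomass_id),
         call. = FALSE)
  }
  invisible(model)
}

#' @export
print.mbx_model <- function(x, ...) {
  cat(sprintf("<mbx_model> %s: %d metabolites, %d reactions (biomass: %s)\n",
              x$id, nrow(x$mets), nrow(x$rxns), x$biomass_id))
  invisible(x)
}

#' Mass- and charge-balance check for a reaction
#'
#' Sums element counts and charges over products minus substrates. Exchange,
#' demand, sink and biomass reactions are exempt by convention (they exist to
#' move matter across the model boundary).
#'
#' @param reaction A list with `id`, `stoich` (named numeric) and `kind`, or a
#'   reaction id present in `model`.
#' @param metabolite_db Metabolite table providing formula and charge, or an
#'   `mbx_model` (its `mets` is used).
#' @param tol Imbalance tolerance (absorbs float noise on integral sums).
#' @return A `balance_report` list: reaction_id, element_imbalance (named
#'   numeric, nonzero entries only), charge_imbalance, verdict
#'   (`"balanced"`, `"unbalanced"` or `"exempt"`).
#' @examples
#' db <- metabolites(c("lcts[c]", "h2o[c]", "glc_D[c]", "gal[c]"),
#'                   formula = c("C12H22O11", "H2O", "C6H12O6", "C6H12O6"))
#' rx <- list(id = "LACZ", kind = "internal",
#'            stoich = parse_equation("1 lcts[c] + 1 h2o[c] -> 1 glc_D[c] + 1 gal[c]"))
#' check_balance(rx, db)$verdict
#' @export
check_balance <- function(reaction, metabolite_db, tol = 1e-9) {
  if (inherits(metabolite_db, "mbx_model")) {
    if (is.character(reaction) && length(reaction) == 1L) {
      rid <- reaction
      i <- match(rid, metabolite_db$rxns$id)
      if (is.na(i)) stop(sprintf("reaction '%s' not in model", rid), call. = FALSE)
      reaction <- list(id = rid, stoich = metabolite_db$stoich[[rid]],
                       kind = metabolite_db$rxns$kind[i])
    }
    metabolite_db <- metabolite_db$mets
  }
  if (reaction$kind %in% BALANCE_EXEMPT_KINDS) {
    return(structure(list(reaction_id = reaction$id,
                          element_imbalance = numeric(0),
                          charge_imbalance = 0, verdict = "exempt"),
                     class = "balance_report"))
  }
  st <- reaction$stoich
  idx <- match(names(st), metabolite_db$id)
  if (anyNA(idx)) {
    stop(sprintf("metabolite(s) missing from database: %s",
                 toString(names(st)[is.na(idx)])), call. = FALSE)
  }
  formulas <- metabolite_db$formula[idx]
  if (any(is.na(formulas) | !nzchar(formulas))) {
    stop(sprintf("metabolite(s) lack a formula: %s",
                 toString(names(st)[is.na(formulas) | !nzchar(formulas)])),
         call. = FALSE)
  }
  elems <- numeric(0)
  for (k in seq_along(st)) {
    elems <- add_element_counts(elems, parse_formula(formulas[k]), st[[k]])
  }
  charge <- sum(st * metabolite_db$charge[idx])
  elems <- elems[abs(elems) > tol]
  verdict <- if (length(elems) == 0L && abs(charge) <= tol) "balanced" else "unbalanced"
  structure(list(reaction_id = reaction$id, element_imbalance = elems,
                 charge_imbalance = if (abs(charge) > tol) charge else 0,
                 verdict = verdict),
            class = "balance_report")
}

#' Balance-check every reaction of a model
#' @param model An `mbx_model`.
#' @return data.frame(reaction_id, verdict, detail) with one row per reaction.
#' @export
check_model_balance <- function(model) {
  reports <- lapply(model$rxns$id, check_balance, metabolite_db = model)
  data.frame(
    reaction_id = vapply(reports, `[[`, character(1), "reaction_id"),
    verdict = vapply(reports, `[[`, character(1), "verdict"),
    detail = vapply(reports, function(r) {
      if (r$verdict != "unbalanced") return("")
      paste0(paste(names(r$element_imbalance), r$element_imbalance,
                   sep = ":", collapse = " "),
             if (r$charge_imbalance != 0) sprintf(" charge:%g", r$charge_imbalance))
    }, character(1)),
    stringsAsFactors = FALSE)
}

#' Add reactions (and their metabolites) to a model
#'
#' Reactions whose id already exists with identical stoichiometry are skipped,
#' making the operation idempotent; an id collision with *different*
#' stoichiometry is a conflict error. New metabolites are merged in; a
#' metabolite id collision with different formula or charge is also a conflict.
#'
#' @param model An `mbx_model`.
#' @param new A list with `rxns` (data.frame like `model$rxns`), `stoich`
#'   (named list), and optionally `mets` (metabolite table for new species).
#' @return A list with `model` (the grown model) and `n_added` (count of
#'   reactions actually inserted).
#' @export
add_reactions <- function(model, new) {
  mets <- model$mets
  if (!is.null(new$mets) && nrow(new$mets) > 0L) {
    common <- intersect(new$mets$id, mets$id)
    if (length(common) > 0L) {
      a <- mets[match(common, mets$id), c("formula", "charge")]
      b <- new$mets[match(common, new$mets$id), c("formula", "charge")]
      diff <- common[a$formula != b$formula | a$charge != b$charge]
      if (length(diff) > 0L) {
        stop(sprintf("metabolite conflict (formula/charge differ): %s",
                     toString(diff)), call. = FALSE)
      }
    }
    mets <- rbind(mets, new$mets[!new$mets$id %in% mets$id, , drop = FALSE])
  }
  rxns <- model$rxns
  stoich <- model$stoich
  n_added <- 0L
  added_ids <- character(0)
  for (k in seq_len(nrow(new$rxns))) {
    rid <- new$rxns$id[k]
    st <- new$stoich[[rid]]
    if (rid %in% rxns$id) {
      old <- stoich[[rid]]
      same <- setequal(names(old), names(st)) &&
        all(abs(old[names(st)] - st) < 1e-12)
      if (!same) {
        stop(sprintf("reaction id collision with different stoichiometry: %s",
                     rid), call. = FALSE)
      }
      next
    }
    missing <- setdiff(names(st), mets$id)
    if (length(missing) > 0L) {
      stop(sprintf("reaction %s references unknown metabolite(s): %s",
                   rid, toString(missing)), call. = FALSE)
    }
    rxns <- rbind(rxns, new$rxns[k, , drop = FALSE])
    stoich[[rid]] <- st
    n_added <- n_added + 1L
    added_ids <- c(added_ids, rid)
  }
  rownames(rxns) <- NULL
  out <- model
  out$mets <- mets
  out$rxns <- rxns
  out$stoich <- stoich
  validate_model(out)
  list(model = out, n_added = n_added, added = added_ids)
}

# Subset utility: drop reactions by id (used when rewiring exchanges during
# community assembly). Orphaned metabolites are kept; they are harmless.
drop_reactions <- function(model, ids) {
  keep <- !model$rxns$id %in% ids
  model$rxns <- model$rxns[keep, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$stoich <- model$stoich[model$rxns$id]
  model
}
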