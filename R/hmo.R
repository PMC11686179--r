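## HMO degradation module: literature-trait tables, the reaction catalog, and
## trait-driven expansion of strain reconstructions (uptake route injection +
## greedy gap-filling of degradation-product catabolism).

#' Load a strain x HMO trait table
#'
#' TSV schema: columns `strain_id`, `species`, `phylum`, one boolean column per
#' HMO, and one `ref_<hmo>` citation column per HMO. Booleans are parsed
#' strictly (`TRUE`/`FALSE`/`1`/`0`). Every `TRUE` cell must carry a non-empty
#' reference.
#'
#' @param path TSV file.
#' @return An `hmo_traits` object: `meta` (strain_id, species, phylum),
#'   `traits` (logical matrix strains x HMOs), `refs` (character matrix).
#' @export
load_trait_table <- function(path) {
  df <- read_tsv_strict(path)
  fixed <- c("strain_id", "species", "phylum")
  if (!all(fixed %in% names(df))) {
    stop("trait table must have columns strain_id, species, phylum", call. = FALSE)
  }
  ref_cols <- grep("^ref_", names(df), value = TRUE)
  hmo_cols <- setdiff(names(df), c(fixed, ref_cols))
  if (anyDuplicated(df$strain_id)) {
    stop(sprintf("duplicate strain rows: %s",
                 toString(df$strain_id[duplicated(df$strain_id)])), call. = FALSE)
  }
  parse_bool <- function(x) {
    x <- trimws(as.character(x))
    ok <- x %in% c("TRUE", "FALSE", "1", "0")
    if (!all(ok)) {
      stop(sprintf("non-boolean trait cell value(s): %s",
                   toString(unique(x[!ok]))), call. = FALSE)
    }
    x %in% c("TRUE", "1")
  }
  traits <- vapply(df[hmo_cols], parse_bool, logical(nrow(df)))
  traits <- matrix(traits, nrow = nrow(df),
                   dimnames = list(df$strain_id, hmo_cols))
  refs <- matrix("", nrow = nrow(df), ncol = length(hmo_cols),
                 dimnames = list(df$strain_id, hmo_cols))
  for (h in hmo_cols) {
    rc <- paste0("ref_", h)
    if (rc %in% names(df)) refs[, h] <- ifelse(is.na(df[[rc]]), "", df[[rc]])
  }
  bad <- which(traits & !nzchar(refs), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("TRUE trait cell(s) without a reference: %s",
                 toString(paste(rownames(traits)[bad[, 1]],
                                colnames(traits)[bad[, 2]], sep = "/"))),
         call. = FALSE)
  }
  structure(list(meta = df[fixed], traits = traits, refs = refs),
            class = "hmo_traits")
}

#' Write a trait table to TSV (inverse of [load_trait_table()])
#' @param traits An `hmo_traits` object.
#' @param path Output TSV file.
#' @export
write_trait_table <- function(traits, path) {
  df <- traits$meta
  for (h in colnames(traits$traits)) df[[h]] <- traits$traits[, h]
  for (h in colnames(traits$traits)) df[[paste0("ref_", h)]] <- traits$refs[, h]
  write_tsv_strict(df, path)
  invisible(path)
}

#' Load an HMO reaction catalog
#'
#' A catalog directory holds the tabular model dialect (metabolites.tsv,
#' reactions.tsv) plus `routes.tsv` (hmo, reaction_id: the ordered uptake route
#' per HMO — exchange, transport/extracellular hydrolase, degradation,
#' product export) and `catabolism.tsv` (product, reaction_id: gap-filling
#' templates grouped by the degradation product they consume). An optional
#' `mechanisms.tsv` (hmo, mechanism) records the transport mechanism
#' (`ABC`, `proton-symport`, `extracellular-hydrolysis`).
#'
#' Every non-exempt reaction is mass/charge balance-validated on load; an
#' unbalanced reaction aborts the load with its balance report.
#'
#' @param path Catalog directory.
#' @return An `hmo_catalog` object.
#' @export
load_catalog <- function(path) {
  mets <- read_tsv_strict(file.path(path, "metabolites.tsv"))
  rx <- read_tsv_strict(file.path(path, "reactions.tsv"))
  routes <- read_tsv_strict(file.path(path, "routes.tsv"))
  catab_path <- file.path(path, "catabolism.tsv")
  catabolism <- if (file.exists(catab_path)) {
    read_tsv_strict(catab_path)
  } else {
    data.frame(product = character(0), reaction_id = character(0))
  }
  mech_path <- file.path(path, "mechanisms.tsv")
  mechanisms <- if (file.exists(mech_path)) {
    read_tsv_strict(mech_path)
  } else {
    data.frame(hmo = character(0), mechanism = character(0))
  }
  stoich <- lapply(rx$equation, parse_equation)
  names(stoich) <- rx$id
  cat <- structure(list(
    mets = mets,
    rxns = rx[c("id", "name", "lb", "ub", "subsystem", "kind")],
    stoich = stoich, routes = routes, catabolism = catabolism,
    mechanisms = mechanisms), class = "hmo_catalog")
  validate_catalog(cat)
  cat
}

validate_catalog <- function(cat) {
  missing <- setdiff(c(cat$routes$reaction_id, cat$catabolism$reaction_id),
                     cat$rxns$id)
  if (length(missing) > 0L) {
    stop(sprintf("catalog routes reference unknown reaction(s): %s",
                 toString(missing)), call. = FALSE)
  }
  for (i in seq_len(nrow(cat$rxns))) {
    rep <- check_balance(list(id = cat$rxns$id[i],
                              stoich = cat$stoich[[cat$rxns$id[i]]],
                              kind = cat$rxns$kind[i]), cat$mets)
    if (rep$verdict == "unbalanced") {
      stop(sprintf(
        "catalog load error: reaction %s is unbalanced (elements: %s; charge: %g)",
        rep$reaction_id,
        paste(names(rep$element_imbalance), rep$element_imbalance,
              sep = ":", collapse = " "),
        rep$charge_imbalance), call. = FALSE)
    }
  }
  invisible(cat)
}

#' Write an HMO catalog directory (inverse of [load_catalog()])
#' @param catalog An `hmo_catalog`.
#' @param path Target directory.
#' @export
write_catalog <- function(catalog, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv_strict(catalog$mets, file.path(path, "metabolites.tsv"))
  rx <- catalog$rxns
  rx$equation <- vapply(catalog$stoich[rx$id], format_equation, character(1))
  write_tsv_strict(rx[c("id", "name", "equation", "lb", "ub", "subsystem", "kind")],
                   file.path(path, "reactions.tsv"))
  write_tsv_strict(catalog$routes, file.path(path, "routes.tsv"))
  write_tsv_strict(catalog$catabolism, file.path(path, "catabolism.tsv"))
  write_tsv_strict(catalog$mechanisms, file.path(path, "mechanisms.tsv"))
  invisible(path)
}

# Reaction-set view of a subset of catalog reactions, as accepted by
# add_reactions(): reactions plus every metabolite they touch.
catalog_subset <- function(catalog, rxn_ids) {
  rxn_ids <- unique(rxn_ids)
  idx <- match(rxn_ids, catalog$rxns$id)
  st <- catalog$stoich[rxn_ids]
  met_ids <- unique(unlist(lapply(st, names), use.names = FALSE))
  list(rxns = catalog$rxns[idx, , drop = FALSE], stoich = st,
       mets = catalog$mets[catalog$mets$id %in% met_ids, , drop = FALSE])
}

# Maximal uptake flux of an HMO through its exchange reaction, with every
# exchange bound opened to (-1000, 1000). Uptake is negative flux through the
# exchange, so the objective is -v_EX.
max_uptake_flux <- function(model, exchange_id) {
  m <- model
  open <- m$rxns$kind == "exchange"
  m$rxns$lb[open] <- -1000
  m$rxns$ub[open] <- 1000
  res <- fba(m, stats::setNames(-1, exchange_id))
  if (res$status != 0) return(0)
  res$objective
}

route_reactions <- function(catalog, hmo_id) {
  rids <- catalog$routes$reaction_id[catalog$routes$hmo == hmo_id]
  if (length(rids) == 0L) {
    stop(sprintf("HMO '%s' is not in the catalog", hmo_id), call. = FALSE)
  }
  rids
}

route_exchange <- function(catalog, hmo_id) {
  rids <- route_reactions(catalog, hmo_id)
  kinds <- catalog$rxns$kind[match(rids, catalog$rxns$id)]
  ex <- rids[kinds == "exchange"]
  # the route's own exchange is the one touching the HMO metabolite
  for (e in ex) {
    if (any(startsWith(names(catalog$stoich[[e]]), paste0(hmo_id, "[")))) {
      return(e)
    }
  }
  ex[1]
}

#' Gap-fill the degradation of one HMO
#'
#' Greedy dead-end repair: every metabolite produced by the HMO's degradation
#' reactions must be consumable by the model (by internal metabolism, export,
#' or a further degradation step). Products are visited in alphabetical order;
#' for each structurally dead-ended product the catalog's catabolism template
#' for that product is added. Afterwards an LP verifies that the HMO can carry
#' positive uptake flux; if not, the remaining dead ends are reported as an
#' error.
#'
#' @param model An `mbx_model` already containing the HMO uptake route.
#' @param hmo_id HMO identifier (catalog key).
#' @param catalog An `hmo_catalog`.
#' @return A list with `model` (possibly grown) and `added` (character vector
#'   of inserted reaction ids).
#' @export
gapfill_degradation <- function(model, hmo_id, catalog) {
  rids <- route_reactions(catalog, hmo_id)
  if (!all(rids %in% model$rxns$id)) {
    stop(sprintf("model %s lacks the uptake route for %s; expand first",
                 model$id, hmo_id), call. = FALSE)
  }
  kinds <- catalog$rxns$kind[match(rids, catalog$rxns$id)]
  degr <- rids[kinds == "internal"]
  products <- sort(unique(unlist(lapply(catalog$stoich[degr], function(st) {
    names(st)[st > 0]
  }), use.names = FALSE)))
  products <- setdiff(products, paste0(hmo_id, c("[c]", "[e]")))
  is_consumable <- function(mod, met) {
    for (rid in setdiff(mod$rxns$id, degr)) {
      st <- mod$stoich[[rid]]
      if (met %in% names(st) && st[[met]] < 0) return(TRUE)
    }
    FALSE
  }
  added <- character(0)
  dead <- character(0)
  for (p in products) {
    if (is_consumable(model, p)) next
    base <- met_base(p)
    tmpl <- catalog$catabolism$reaction_id[catalog$catabolism$product == base]
    if (length(tmpl) == 0L) {
      dead <- c(dead, p)
      next
    }
    res <- add_reactions(model, catalog_subset(catalog, tmpl))
    model <- res$model
    added <- c(added, res$added)
  }
  flux <- max_uptake_flux(model, route_exchange(catalog, hmo_id))
  if (flux <= 1e-6) {
    still <- products[!vapply(products, function(p) is_consumable(model, p),
                              logical(1))]
    blocked <- unique(c(still, dead))
    if (length(blocked) == 0L) blocked <- products # downstream blockage
    stop(sprintf("gap-filling failed for %s: dead-end product(s): %s",
                 hmo_id, toString(blocked)), call. = FALSE)
  }
  list(model = model, added = added)
}

#' Expand a strain reconstruction with its trait-enabled HMO routes
#'
#' For each HMO flagged `TRUE` in the strain's trait row, the catalog's
#' exchange/transport/degradation route is inserted (reactions already present
#' are skipped), the degradation products are gap-filled via
#' [gapfill_degradation()], and uptake feasibility is verified by LP
#' (maximal uptake flux > 1e-6 with open exchange bounds). Re-running the
#' expansion is a no-op.
#'
#' @param model An `mbx_model`.
#' @param traits_row Named logical vector (HMO id -> can-degrade flag), e.g. a
#'   row of `traits$traits`.
#' @param catalog An `hmo_catalog`.
#' @return A list with `model` and `report` (an `expansion_report`:
#'   model_id, reactions_added, n_added, gapfilled, feasible).
#' @export
expand_model <- function(model, traits_row, catalog) {
  hmos <- sort(names(traits_row)[as.logical(traits_row)])
  missing <- setdiff(hmos, unique(catalog$routes$hmo))
  if (length(missing) > 0L) {
    stop(sprintf("trait-enabled HMO(s) absent from catalog: %s",
                 toString(missing)), call. = FALSE)
  }
  reactions_added <- character(0)
  gapfilled <- character(0)
  feasible <- stats::setNames(logical(length(hmos)), hmos)
  for (h in hmos) {
    res <- add_reactions(model, catalog_subset(catalog, route_reactions(catalog, h)))
    model <- res$model
    reactions_added <- c(reactions_added, res$added)
    gf <- gapfill_degradation(model, h, catalog)
    model <- gf$model
    reactions_added <- c(reactions_added, gf$added)
    gapfilled <- c(gapfilled, gf$added)
    feasible[h] <- max_uptake_flux(model, route_exchange(catalog, h)) > 1e-6
  }
  report <- structure(list(model_id = model$id,
                           reactions_added = reactions_added,
                           n_added = length(reactions_added),
                           gapfilled = gapfilled, feasible = feasible),
                      class = "expansion_report")
  list(model = model, report = report)
}

#' Binary HMO utilization coverage matrix
#'
#' @param traits An `hmo_traits` object.
#' @return A list with `matrix` (strains x HMOs, 0/1, rows ordered by phylum
#'   then species then strain) and `counts` (per-strain capability counts).
#' @export
coverage_matrix <- function(traits) {
  ord <- order(traits$meta$phylum, traits$meta$species, traits$meta$strain_id)
  m <- traits$traits[ord, , drop = FALSE] * 1L
  list(matrix = m, counts = rowSums(m))
}
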