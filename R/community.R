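## Community model construction: taxa name matching, abundance normalization,
## pan-species models, and compartmentalized community assembly with the
## mgPipe reaction dialect (Diet_EX_*, DUt_*, UFEt_*, *_IEX_*,
## communityBiomass).

#' Normalize a taxon name for registry matching
#'
#' Case-fold, underscores to spaces, strip "subsp."/"subspecies" qualifiers and
#' square-bracket characters, collapse whitespace. Exact normalized equality is
#' required for a match — no fuzzy matching.
#' @param x Character vector of taxon names.
#' @return Normalized names.
#' @export
normalize_taxon <- function(x) {
  x <- tolower(x)
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("\\[|\\]", "", x)
  x <- gsub("\\bsubspecies\\b|\\bsubsp\\.?", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Match input taxa to a model registry
#'
#' @param names Input taxon names (e.g. abundance-table rows).
#' @param registry Character vector of registry model ids (species names), or a
#'   data.frame with an `id` column.
#' @return A `taxa_mapping`: `mapping` data.frame(input, model_id) and
#'   `unmatched` character vector. Two inputs resolving to the same registry id
#'   raise an ambiguity error.
#' @export
match_taxa <- function(names, registry) {
  if (is.data.frame(registry)) registry <- registry$id
  reg_norm <- normalize_taxon(registry)
  if (anyDuplicated(reg_norm)) {
    stop(sprintf("registry ids not unique after normalization: %s",
                 toString(registry[duplicated(reg_norm)])), call. = FALSE)
  }
  idx <- match(normalize_taxon(names), reg_norm)
  matched <- !is.na(idx)
  hits <- idx[matched]
  if (anyDuplicated(hits)) {
    dup <- registry[hits[duplicated(hits)]]
    stop(sprintf("ambiguous match: multiple inputs resolve to registry id(s): %s",
                 toString(unique(dup))), call. = FALSE)
  }
  structure(list(
    mapping = data.frame(input = names[matched], model_id = registry[hits],
                         stringsAsFactors = FALSE),
    unmatched = names[!matched]), class = "taxa_mapping")
}

#' Filter and renormalize a relative abundance table
#'
#' Entries below `cutoff` are zeroed, rows named "unclassified"/"unknown" are
#' dropped, and each sample column is renormalized to sum to 1.
#'
#' @param table Numeric matrix (taxa x samples, rownames = taxon names) or a
#'   data.frame whose first column holds taxon names.
#' @param cutoff Relative abundance cutoff (default 1e-4).
#' @return Numeric matrix with columns summing to 1.
#' @export
normalize_abundances <- function(table, cutoff = 1e-4) {
  stopifnot(cutoff >= 0)
  if (is.data.frame(table)) {
    m <- as.matrix(table[, -1, drop = FALSE])
    rownames(m) <- table[[1]]
    table <- m
  }
  drop <- grepl("^(unclassified|unknown)$", trimws(rownames(table)),
                ignore.case = TRUE)
  table <- table[!drop, , drop = FALSE]
  if (any(table < 0)) stop("negative abundances", call. = FALSE)
  table[table < cutoff] <- 0
  sums <- colSums(table)
  if (any(sums == 0)) {
    stop(sprintf("sample(s) with no taxa above the cutoff: %s",
                 toString(colnames(table)[sums == 0])), call. = FALSE)
  }
  sweep(table, 2, sums, "/")
}

#' Build a pan-species model from strain reconstructions
#'
#' The pan model's reaction set is the exact union of the strains' reaction id
#' sets; bounds of duplicated reactions are widened to the envelope
#' (min lower, max upper); stoichiometry conflicts for a shared id are an
#' error. The merged biomass (`biomassPan`) takes the union of all strains'
#' biomass components with each coefficient averaged over the strains that
#' contain it.
#'
#' @param strains A list of `mbx_model` (>= 1), same species.
#' @return An `mbx_model` with id `pan_<species>` and biomass `biomassPan`.
#' @export
build_pan_model <- function(strains) {
  stopifnot(length(strains) >= 1L)
  species <- strains[[1]]$taxonomy$species
  mets <- strains[[1]]$mets
  rxns <- NULL
  stoich <- list()
  for (s in strains) {
    new_m <- s$mets[!s$mets$id %in% mets$id, , drop = FALSE]
    mets <- rbind(mets, new_m)
    non_bio <- s$rxns[s$rxns$id != s$biomass_id, , drop = FALSE]
    for (k in seq_len(nrow(non_bio))) {
      rid <- non_bio$id[k]
      st <- s$stoich[[rid]]
      if (is.null(rxns) || !rid %in% rxns$id) {
        rxns <- rbind(rxns, non_bio[k, , drop = FALSE])
        stoich[[rid]] <- st
      } else {
        i <- match(rid, rxns$id)
        old <- stoich[[rid]]
        same <- setequal(names(old), names(st)) &&
          all(abs(old[names(st)] - st) < 1e-12)
        if (!same) {
          stop(sprintf("conflicting stoichiometry for shared reaction id %s", rid),
               call. = FALSE)
        }
        rxns$lb[i] <- min(rxns$lb[i], non_bio$lb[k])
        rxns$ub[i] <- max(rxns$ub[i], non_bio$ub[k])
      }
    }
  }
  # merged biomass: union of components, coefficients averaged over the
  # strains containing each component
  bio_sum <- numeric(0)
  bio_n <- numeric(0)
  bio_lb <- Inf
  bio_ub <- -Inf
  for (s in strains) {
    st <- s$stoich[[s$biomass_id]]
    i <- match(s$biomass_id, s$rxns$id)
    bio_lb <- min(bio_lb, s$rxns$lb[i])
    bio_ub <- max(bio_ub, s$rxns$ub[i])
    for (met in names(st)) {
      bio_sum[met] <- (if (met %in% names(bio_sum)) bio_sum[[met]] else 0) + st[[met]]
      bio_n[met] <- (if (met %in% names(bio_n)) bio_n[[met]] else 0) + 1
    }
  }
  pan_bio <- bio_sum / bio_n[names(bio_sum)]
  rxns <- rbind(rxns, data.frame(id = "biomassPan", name = "pan-species biomass",
                                 lb = bio_lb, ub = bio_ub, subsystem = "Biomass",
                                 kind = "biomass", stringsAsFactors = FALSE))
  stoich[["biomassPan"]] <- pan_bio
  rownames(rxns) <- NULL
  metabolic_model(id = paste0("pan_", gsub("[^A-Za-z0-9]+", "_", species)),
                  mets = mets, rxns = rxns, stoich = stoich,
                  biomass_id = "biomassPan",
                  taxonomy = strains[[1]]$taxonomy)
}

#' Community assembly configuration
#'
#' @param coupling_factor Factor c of the coupling constraints
#'   |v| <= c * v_biomass,species (mgPipe convention, default 400).
#' @param couple Whether to impose coupling constraints at all.
#' @param growth_lb,growth_ub Community biomass flux window (1/day), default
#'   \[0.4, 1\].
#' @param abundance_cutoff Relative abundance cutoff used upstream.
#' @return A list of class `community_config`.
#' @export
community_config <- function(coupling_factor = 400, couple = TRUE,
                             growth_lb = 0.4, growth_ub = 1,
                             abundance_cutoff = 1e-4) {
  stopifnot(coupling_factor > 0, growth_lb >= 0, growth_ub >= growth_lb,
            abundance_cutoff >= 0)
  structure(list(coupling_factor = coupling_factor, couple = isTRUE(couple),
                 growth_lb = growth_lb, growth_ub = growth_ub,
                 abundance_cutoff = abundance_cutoff),
            class = "community_config")
}

sanitize_tag <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

# retag a metabolite id with a species prefix, keeping the compartment suffix
tag_met <- function(tag, ids) paste0(tag, "_", ids)

#' Assemble a compartmentalized community model
#'
#' Joins pan-species models through a shared lumen: every species reaction and
#' metabolite is prefixed with its taxon tag; each species exchange reaction is
#' rewired into a lumen shuttle `<tag>_IEX_<met>[u]` (positive flux = secretion
#' into the lumen); every lumen metabolite receives the diet/fecal chain
#' `Diet_EX_m[d] -> DUt_m -> [u] -> UFEt_m -> EX_m[fe]`; a community biomass
#' reaction consumes `a_s` units of each species' biomass metabolite and
#' produces `microbeBiomass[u]` (with its own fecal chain); optional coupling
#' constraints tie every species reaction flux to that species' biomass flux.
#'
#' @param pan_models Named list of `mbx_model` (names = taxon as used in the
#'   abundance column).
#' @param abundances Named numeric vector, normalized (sums to 1); every taxon
#'   with abundance > 0 must have a pan model.
#' @param config A [community_config()].
#' @param id Sample identifier.
#' @return An `mbx_community`: list(id, model, species, lumen_mets, coupling,
#'   config).
#' @export
assemble_community <- function(pan_models, abundances,
                               config = community_config(), id = "community") {
  abundances <- abundances[abundances > 0]
  if (abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must be normalized to sum to 1", call. = FALSE)
  }
  missing <- setdiff(names(abundances), names(pan_models))
  if (length(missing) > 0L) {
    stop(sprintf("taxa with abundance > 0 but no pan model: %s",
                 toString(missing)), call. = FALSE)
  }
  taxa <- sort(names(abundances))
  mets <- NULL; rxns <- NULL; stoich <- list()
  species_rows <- list()
  coupling <- list()
  lumen <- character(0)       # base ids of lumen metabolites
  lumen_proto <- list()       # base id -> prototype metabolite row
  for (taxon in taxa) {
    tag <- sanitize_tag(taxon)
    pm <- pan_models[[taxon]]
    # tagged metabolites
    tm <- pm$mets
    tm$id <- tag_met(tag, tm$id)
    tm$name <- paste0(pm$mets$name, " (", taxon, ")")
    mets <- rbind(mets, tm)
    bio_rxn <- paste0(tag, "_", pm$biomass_id)
    exch <- pm$rxns$kind == "exchange"
    for (k in seq_len(nrow(pm$rxns))) {
      rid0 <- pm$rxns$id[k]
      st0 <- pm$stoich[[rid0]]
      if (exch[k]) {
        # rewire into a lumen shuttle: tag_met[e] <-> met[u]
        met_e <- names(st0)[1]
        base <- met_base(met_e)
        iex <- sprintf("%s_IEX_%s[u]", tag, base)
        st <- stats::setNames(c(-1, 1), c(tag_met(tag, met_e),
                                          sprintf("%s[u]", base)))
        row <- data.frame(id = iex, name = sprintf("%s lumen shuttle (%s)", base, taxon),
                          lb = -1000, ub = 1000, subsystem = "Lumen exchange",
                          kind = "transport", stringsAsFactors = FALSE)
        if (!base %in% lumen) {
          lumen <- c(lumen, base)
          proto <- pm$mets[match(met_e, pm$mets$id), , drop = FALSE]
          lumen_proto[[base]] <- proto
        }
        rxns <- rbind(rxns, row)
        stoich[[iex]] <- st
        coupling[[length(coupling) + 1L]] <- c(iex, bio_rxn)
      } else {
        rid <- paste0(tag, "_", rid0)
        st <- stats::setNames(as.numeric(st0), tag_met(tag, names(st0)))
        row <- pm$rxns[k, , drop = FALSE]
        row$id <- rid
        rxns <- rbind(rxns, row)
        stoich[[rid]] <- st
        coupling[[length(coupling) + 1L]] <- c(rid, bio_rxn)
      }
    }
    bio_prod <- pm$stoich[[pm$biomass_id]]
    bio_prod <- names(bio_prod)[bio_prod > 0]
    if (length(bio_prod) == 0L) {
      stop(sprintf("biomass reaction of %s produces no biomass metabolite", taxon),
           call. = FALSE)
    }
    species_rows[[taxon]] <- data.frame(
      taxon = taxon, tag = tag, abundance = unname(abundances[[taxon]]),
      biomass_rxn = bio_rxn,
      biomass_met = tag_met(tag, bio_prod[1]), stringsAsFactors = FALSE)
  }
  species <- do.call(rbind, species_rows)
  rownames(species) <- NULL
  # lumen/diet/fecal metabolites and the 4-reaction chain per lumen metabolite
  lumen <- sort(lumen)
  for (base in lumen) {
    proto <- lumen_proto[[base]]
    for (cmp in c("u", "d", "fe")) {
      mets <- rbind(mets, data.frame(
        id = sprintf("%s[%s]", base, cmp), name = proto$name,
        formula = proto$formula, charge = proto$charge, compartment = cmp,
        stringsAsFactors = FALSE))
    }
    ids <- c(sprintf("Diet_EX_%s[d]", base), sprintf("DUt_%s", base),
             sprintf("UFEt_%s", base), sprintf("EX_%s[fe]", base))
    chain <- data.frame(
      id = ids,
      name = c(sprintf("%s diet exchange", base),
               sprintf("%s diet-to-lumen transport", base),
               sprintf("%s lumen-to-feces transport", base),
               sprintf("%s fecal exchange", base)),
      lb = c(0, 0, 0, -1000), ub = c(0, 1000, 1000, 1000),
      subsystem = "Community exchange",
      kind = c("exchange", "transport", "transport", "exchange"),
      stringsAsFactors = FALSE)
    rxns <- rbind(rxns, chain)
    stoich[[ids[1]]] <- stats::setNames(-1, sprintf("%s[d]", base))
    stoich[[ids[2]]] <- stats::setNames(c(-1, 1), sprintf("%s[%s]", base, c("d", "u")))
    stoich[[ids[3]]] <- stats::setNames(c(-1, 1), sprintf("%s[%s]", base, c("u", "fe")))
    stoich[[ids[4]]] <- stats::setNames(-1, sprintf("%s[fe]", base))
  }
  # community biomass: a_s * species biomass metabolite -> microbeBiomass[u]
  mets <- rbind(mets, data.frame(
    id = c("microbeBiomass[u]", "microbeBiomass[fe]"),
    name = "community microbial biomass", formula = "X", charge = 0,
    compartment = c("u", "fe"), stringsAsFactors = FALSE))
  cb <- stats::setNames(c(-species$abundance, 1),
                        c(species$biomass_met, "microbeBiomass[u]"))
  rxns <- rbind(rxns, data.frame(
    id = c("communityBiomass", "UFEt_microbeBiomass", "EX_microbeBiomass[fe]"),
    name = c("community biomass", "biomass lumen-to-feces transport",
             "biomass fecal exchange"),
    lb = c(config$growth_lb, 0, -1000), ub = c(config$growth_ub, 1000, 1000),
    subsystem = c("Biomass", "Community exchange", "Community exchange"),
    kind = c("biomass", "transport", "exchange"), stringsAsFactors = FALSE))
  stoich[["communityBiomass"]] <- cb
  stoich[["UFEt_microbeBiomass"]] <- stats::setNames(
    c(-1, 1), c("microbeBiomass[u]", "microbeBiomass[fe]"))
  stoich[["EX_microbeBiomass[fe]"]] <- stats::setNames(-1, "microbeBiomass[fe]")
  rownames(rxns) <- NULL
  rownames(mets) <- NULL
  model <- metabolic_model(id = id, mets = mets, rxns = rxns, stoich = stoich,
                           biomass_id = "communityBiomass",
                           taxonomy = list(species = NA_character_,
                                           genus = NA_character_,
                                           phylum = NA_character_))
  coupling_df <- if (length(coupling) > 0L) {
    data.frame(rxn_id = vapply(coupling, `[[`, character(1), 1),
               biomass_rxn = vapply(coupling, `[[`, character(1), 2),
               stringsAsFactors = FALSE)
  } else {
    data.frame(rxn_id = character(0), biomass_rxn = character(0))
  }
  structure(list(id = id, model = model, species = species,
                 lumen_mets = lumen, coupling = coupling_df, config = config,
                 diet_skipped = NA_integer_),
            class = "mbx_community")
}

#' @export
print.mbx_community <- function(x, ...) {
  cat(sprintf("<mbx_community> %s: %d species, %d reactions, %d metabolites, %d lumen metabolites\n",
              x$id, nrow(x$species), nrow(x$model$rxns), nrow(x$model$mets),
              length(x$lumen_mets)))
  invisible(x)
}

# Inequality rows for the coupling constraints:
#   v_r - c v_bio <= 0  and  -v_r - c v_bio <= 0
coupling_rows <- function(community, rxn_index) {
  cfg <- community$config
  cp <- community$coupling
  if (!cfg$couple || nrow(cp) == 0L) return(NULL)
  n <- nrow(cp)
  r_idx <- unname(rxn_index[cp$rxn_id])
  b_idx <- unname(rxn_index[cp$biomass_rxn])
  list(A = list(i = c(seq_len(n), seq_len(n), n + seq_len(n), n + seq_len(n)),
                j = c(r_idx, b_idx, r_idx, b_idx),
                v = c(rep(1, n), rep(-cfg$coupling_factor, n),
                      rep(-1, n), rep(-cfg$coupling_factor, n))),
       n = 2L * n, b = rep(0, 2L * n))
}

# LPs for a community model, one per named objective (list of named numeric
# vectors over reaction ids). The constraint matrix is built once and shared.
community_lp_many <- function(community, objectives) {
  tri <- model_stoich_triplets(community$model)
  cp <- coupling_rows(community, tri$rxn_index)
  n <- nrow(community$model$rxns)
  lapply(objectives, function(objective) {
    obj <- numeric(n)
    idx <- tri$rxn_index[names(objective)]
    if (anyNA(idx)) {
      stop(sprintf("objective names not in model: %s",
                   toString(names(objective)[is.na(idx)])), call. = FALSE)
    }
    obj[idx] <- as.numeric(objective)
    args <- list(c = obj, lb = community$model$rxns$lb,
                 ub = community$model$rxns$ub,
                 Aeq = tri$Aeq, neq = tri$neq, maximize = TRUE)
    if (!is.null(cp)) {
      args$Aub <- cp$A; args$nub <- cp$n; args$bub <- cp$b
    }
    do.call(lp_problem, args)
  })
}

# single-objective convenience wrapper
community_lp <- function(community, objective) {
  community_lp_many(community, list(objective))[[1]]
}
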