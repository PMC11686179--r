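## LP-based interrogation of community models: net metabolite secretion
## (maximal fecal secretion minus dietary uptake), reaction/subsystem
## abundance and presence, and species-level metabolite contributions.
##
## Only LP objective values are reported; individual flux vectors are not,
## because the steady-state assumption admits multiple optimal solutions.

growth_probe_problem <- function(community) {
  comm <- community
  i <- match("communityBiomass", comm$model$rxns$id)
  comm$model$rxns$lb[i] <- 0 # probe the attainable maximum, not feasibility
  community_lp(comm, c(communityBiomass = 1))
}

#' Check that a community can reach its minimum growth on the applied diet
#' @param community An `mbx_community` with diet applied.
#' @return Maximal community biomass flux (1/day).
#' @export
community_growth_check <- function(community) {
  res <- solve_lp(growth_probe_problem(community))
  lb <- community$model$rxns$lb[match("communityBiomass",
                                      community$model$rxns$id)]
  if (res$status != 0) {
    stop(sprintf("community %s: growth LP not solvable (status %d)",
                 community$id, res$status), call. = FALSE)
  }
  if (res$objective < lb - 1e-9) {
    stop(sprintf("community %s cannot reach minimum growth %g on this diet (max %g)",
                 community$id, lb, res$objective), call. = FALSE)
  }
  res$objective
}

# Batched net secretion for several diet-applied communities: one LP backend
# call covers every community's growth probe and per-metabolite net LPs.
# Returns list(secretion = named list per community (NULL if growth fails),
# errors = named character).
net_secretion_batch <- function(communities, metabolites = NULL,
                                check_growth = TRUE) {
  probs <- list(); meta <- list()
  for (ci in seq_along(communities)) {
    comm <- communities[[ci]]
    if (check_growth) {
      probs[[length(probs) + 1L]] <- growth_probe_problem(comm)
      meta[[length(meta) + 1L]] <- list(type = "growth", ci = ci)
    }
    mets <- sort(metabolites %||% comm$lumen_mets)
    mets <- intersect(mets, comm$lumen_mets)
    objs <- lapply(mets, function(m) stats::setNames(
      c(1, 1), c(sprintf("EX_%s[fe]", m), sprintf("Diet_EX_%s[d]", m))))
    new <- community_lp_many(comm, objs)
    for (k in seq_along(new)) {
      probs[[length(probs) + 1L]] <- new[[k]]
      meta[[length(meta) + 1L]] <- list(type = "met", ci = ci, met = mets[k])
    }
  }
  res <- solve_lp_batch(probs)
  secretion <- vector("list", length(communities))
  names(secretion) <- names(communities)
  errors <- stats::setNames(character(0), character(0))
  failed <- logical(length(communities))
  for (k in seq_along(meta)) {
    m <- meta[[k]]; r <- res[[k]]
    comm <- communities[[m$ci]]
    if (m$type == "growth") {
      lb <- comm$model$rxns$lb[match("communityBiomass", comm$model$rxns$id)]
      if (r$status != 0 || r$objective < lb - 1e-9) {
        failed[m$ci] <- TRUE
        errors[comm$id] <- sprintf(
          "community %s cannot reach minimum growth %g on this diet", comm$id, lb)
      }
      next
    }
    if (failed[m$ci]) next
    if (is.null(secretion[[m$ci]])) {
      full <- sort(metabolites %||% comm$lumen_mets)
      secretion[[m$ci]] <- stats::setNames(rep(0, length(full)), full)
    }
    if (r$status == 0) secretion[[m$ci]][m$met] <- max(0, r$objective)
  }
  secretion[failed] <- list(NULL)
  list(secretion = secretion, errors = errors)
}

#' Net maximal metabolite secretion of a community
#'
#' For every lumen metabolite with a fecal exchange, one LP maximizes
#' `v_EX_m[fe] + v_Diet_EX_m[d]` (uptake-negative convention, i.e. secretion
#' minus dietary uptake) subject to steady state, the applied diet bounds,
#' coupling constraints, and the community growth window. Optima are clamped
#' at 0.
#'
#' @param community An `mbx_community`.
#' @param diet Optional DietFluxTable (or named vector) applied via
#'   [apply_diet()] before solving; pass `NULL` if the diet is already applied.
#' @param config Optional diet config forwarded to [apply_diet()].
#' @param metabolites Optional subset of lumen metabolite base ids.
#' @return Named numeric vector: base metabolite id -> net secretion flux
#'   (mmol/person/day).
#' @export
compute_net_secretion <- function(community, diet = NULL, config = NULL,
                                  metabolites = NULL) {
  if (!is.null(diet)) {
    community <- apply_diet(community, diet,
                            config = config %||% list(micronutrients = default_micronutrients(),
                                                      trickle = 0.1))
  }
  res <- net_secretion_batch(stats::setNames(list(community), community$id),
                             metabolites = metabolites)
  if (length(res$errors) > 0L) stop(res$errors[[1]], call. = FALSE)
  res$secretion[[1]]
}

#' Reaction abundance, presence, and subsystem abundance for one sample
#'
#' Reaction abundance RA(j) = sum over species of relative abundance times the
#' indicator that the species' pan model carries reaction j; presence is
#' RA(j) > 0; subsystem abundance sums RA over the reactions of each subsystem.
#'
#' @param abundances Named numeric vector (taxon -> normalized relative
#'   abundance).
#' @param pan_models Named list of `mbx_model` covering the taxa.
#' @return A list with `reaction_abundance`, `presence` (named numeric /
#'   integer over the union reaction id set) and `subsystem_abundance`.
#' @export
compute_reaction_metrics <- function(abundances, pan_models) {
  abundances <- abundances[abundances > 0]
  taxa <- names(abundances)
  missing <- setdiff(taxa, names(pan_models))
  if (length(missing) > 0L) {
    stop(sprintf("no pan model for: %s", toString(missing)), call. = FALSE)
  }
  all_rxns <- sort(unique(unlist(lapply(pan_models[taxa],
                                        function(m) m$rxns$id),
                                 use.names = FALSE)))
  ra <- stats::setNames(rep(0, length(all_rxns)), all_rxns)
  subsys <- stats::setNames(rep("", length(all_rxns)), all_rxns)
  for (taxon in taxa) {
    pm <- pan_models[[taxon]]
    ra[pm$rxns$id] <- ra[pm$rxns$id] + abundances[[taxon]]
    subsys[pm$rxns$id] <- pm$rxns$subsystem
  }
  sub_levels <- sort(unique(subsys[nzchar(subsys)]))
  sub_ab <- vapply(sub_levels, function(u) sum(ra[subsys == u]), numeric(1))
  list(reaction_abundance = ra,
       presence = as.integer(ra > 0) |> stats::setNames(all_rxns),
       subsystem_abundance = sub_ab)
}

#' Species-level contributions to metabolite secretion
#'
#' For each (species, metabolite) pair, one LP maximizes the species' lumen
#' shuttle flux `<tag>_IEX_<met>[u]` under the same community constraints.
#' Species without a shuttle for the metabolite contribute 0.
#'
#' @param community An `mbx_community` (diet applied).
#' @param metabolites Base metabolite ids of interest.
#' @param require_growth If `FALSE`, the community growth lower bound is
#'   relaxed to 0 for the contribution LPs.
#' @return data.frame(sample, species, metabolite, flux) with flux >= 0.
#' @export
compute_contributions <- function(community, metabolites, require_growth = TRUE) {
  comm <- community
  if (!require_growth) {
    i <- match("communityBiomass", comm$model$rxns$id)
    comm$model$rxns$lb[i] <- 0
  }
  grid <- expand.grid(species = comm$species$taxon, metabolite = metabolites,
                      stringsAsFactors = FALSE)
  rxn_ids <- sprintf("%s_IEX_%s[u]",
                     comm$species$tag[match(grid$species, comm$species$taxon)],
                     grid$metabolite)
  have <- rxn_ids %in% comm$model$rxns$id
  probs <- community_lp_many(comm, lapply(rxn_ids[have], function(rid) {
    stats::setNames(1, rid)
  }))
  res <- solve_lp_batch(probs)
  flux <- numeric(nrow(grid))
  flux[have] <- vapply(res, function(r) {
    if (r$status == 0) max(0, r$objective) else 0
  }, numeric(1))
  data.frame(sample = comm$id, species = grid$species,
             metabolite = grid$metabolite, flux = flux,
             stringsAsFactors = FALSE)
}

#' Summarize species contributions per group on the genus level
#'
#' Contributions are averaged over the samples of each stratification group per
#' (species, metabolite) and then summed over the species of each genus.
#'
#' @param table Long contribution table: data.frame(sample, species,
#'   metabolite, flux).
#' @param taxonomy data.frame(species, genus).
#' @param groups Named character vector: sample id -> group label.
#' @return data.frame(group, genus, metabolite, flux).
#' @export
summarize_contributions <- function(table, taxonomy, groups) {
  genus <- taxonomy$genus[match(table$species, taxonomy$species)]
  if (anyNA(genus)) {
    stop(sprintf("species without genus: %s",
                 toString(unique(table$species[is.na(genus)]))), call. = FALSE)
  }
  table$genus <- genus
  table$group <- groups[table$sample]
  if (anyNA(table$group)) {
    stop("samples missing from the group labels", call. = FALSE)
  }
  out <- list()
  for (g in sort(unique(unname(groups)))) {
    sub <- table[table$group == g, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("group '%s' has no samples", g), call. = FALSE)
      next
    }
    n_samples <- length(unique(sub$sample))
    # mean over the group's samples (absent pairs count as 0), then genus sums
    agg <- stats::aggregate(flux ~ genus + metabolite + species, data = sub, FUN = sum)
    agg$flux <- agg$flux / n_samples
    gen <- stats::aggregate(flux ~ genus + metabolite, data = agg, FUN = sum)
    gen$group <- g
    out[[g]] <- gen[c("group", "genus", "metabolite", "flux")]
  }
  if (length(out) == 0L) {
    return(data.frame(group = character(0), genus = character(0),
                      metabolite = character(0), flux = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group, res$genus, res$metabolite), , drop = FALSE]
}
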