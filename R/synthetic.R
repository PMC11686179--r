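## Synthetic data: a toy universe of strain reconstructions partitioned into
## metabolic guilds, cohort abundance tables with planted delivery-mode and
## time-point effects, and breast-milk / formula stage diets. Everything is
## deterministic given the config seed, balance-clean, and growth-feasible, so
## every pipeline stage can be exercised without external resources.

## ---- toy chemistry -------------------------------------------------------

# invented but self-consistent metabolite set: real-ish formulas chosen so
# that every generated reaction balances exactly
toy_chemistry <- function() {
  data.frame(
    id = c("glc_D", "gal", "lcts", "fuc_L", "acgam", "fuclac", "lnt",
           "lac_L", "but", "ac", "pyr", "ppd", "acd", "vitb",
           "h", "h2o", "co2", "h2"),
    name = c("D-glucose", "D-galactose", "lactose", "L-fucose",
             "N-acetyl-D-glucosamine", "2'-fucosyllactose (toy)",
             "lacto-N-tetraose (toy)", "L-lactate", "butyrate", "acetate",
             "pyruvate", "1,2-propanediol", "acetamide", "B-vitamin (toy)",
             "proton", "water", "carbon dioxide", "hydrogen"),
    formula = c("C6H12O6", "C6H12O6", "C12H22O11", "C6H12O5", "C8H15NO6",
                "C18H32O15", "C26H45NO21",
                "C3H5O3", "C4H7O2", "C2H3O2", "C3H3O3", "C3H8O2", "C2H5NO",
                "C6H12O6", "H", "H2O", "CO2", "H2"),
    charge = c(0, 0, 0, 0, 0, 0, 0, -1, -1, -1, -1, 0, 0, 0, 1, 0, 0, 0),
    stringsAsFactors = FALSE)
}

GUILDS <- c("hmo_degrader", "lactate_producer", "butyrate_producer",
            "vitamin_producer", "generalist")

#' Configuration of the synthetic strain universe
#'
#' @param n_per_guild Named integer vector: species per guild. The default
#'   (4/4/3/3/6) gives a 20-species universe dominated by the guilds the infant
#'   gut is built from.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `universe_config` list.
#' @export
universe_config <- function(n_per_guild = c(hmo_degrader = 4,
                                            lactate_producer = 4,
                                            butyrate_producer = 3,
                                            vitamin_producer = 3,
                                            generalist = 6),
                            seed = 1L) {
  stopifnot(all(names(n_per_guild) %in% GUILDS), all(n_per_guild >= 0))
  structure(list(n_per_guild = n_per_guild, seed = as.integer(seed)),
            class = "universe_config")
}

guild_genus <- c(hmo_degrader = "Bifidobacterium",
                 lactate_producer = "Streptococcus",
                 butyrate_producer = "Roseburia",
                 vitamin_producer = "Escherichia",
                 generalist = "Blautia")
guild_phylum <- c(hmo_degrader = "Actinobacteria",
                  lactate_producer = "Firmicutes",
                  butyrate_producer = "Firmicutes",
                  vitamin_producer = "Proteobacteria",
                  generalist = "Firmicutes")

toy_met_rows <- function(ids) {
  chem <- toy_chemistry()
  base <- met_base(ids)
  data.frame(id = ids, name = chem$name[match(base, chem$id)],
             formula = chem$formula[match(base, chem$id)],
             charge = chem$charge[match(base, chem$id)],
             compartment = met_compartment(ids), stringsAsFactors = FALSE)
}

# reaction set shared by every toy species: lactose/glucose uptake and
# hydrolysis, galactose export, water/proton handling, and the biomass
# reaction (0.1 glucose per unit biomass; biomass metabolite bio[c])
toy_core_reactions <- function() {
  reactions(
    id = c("EX_glc_D(e)", "GLCt", "EX_lcts(e)", "LCTSt", "LACZ",
           "GALt", "EX_gal(e)", "H2Ot", "EX_h2o(e)", "Ht", "EX_h(e)",
           "biomass"),
    equation = c(
      "1 glc_D[e] ->",
      "1 glc_D[e] -> 1 glc_D[c]",
      "1 lcts[e] ->",
      "1 lcts[e] -> 1 lcts[c]",
      "1 lcts[c] + 1 h2o[c] -> 1 glc_D[c] + 1 gal[c]",
      "1 gal[c] -> 1 gal[e]",
      "1 gal[e] ->",
      "1 h2o[e] -> 1 h2o[c]",
      "1 h2o[e] ->",
      "1 h[e] -> 1 h[c]",
      "1 h[e] ->",
      "0.1 glc_D[c] -> 1 bio[c]"),
    lb = c(-1000, -1000, -1000, 0, 0, -1000, -1000, -1000, -1000, -1000,
           -1000, 0),
    ub = 1000,
    subsystem = c("Exchange", "Transport", "Exchange", "Transport",
                  "Lactose metabolism", "Transport", "Exchange", "Transport",
                  "Exchange", "Transport", "Exchange", "Biomass"),
    kind = c("exchange", "transport", "exchange", "transport", "internal",
             "transport", "exchange", "transport", "exchange", "transport",
             "exchange", "biomass"))
}

guild_reactions <- function(guild) {
  switch(
    guild,
    lactate_producer = reactions(
      id = c("LDH_L", "L_LACt", "EX_lac_L(e)"),
      equation = c("1 glc_D[c] -> 2 lac_L[c] + 2 h[c]",
                   "1 lac_L[c] + 1 h[c] -> 1 lac_L[e] + 1 h[e]",
                   "1 lac_L[e] ->"),
      lb = c(0, -1000, -1000), ub = 1000,
      subsystem = c("Lactate fermentation", "Transport", "Exchange"),
      kind = c("internal", "transport", "exchange")),
    butyrate_producer = reactions(
      id = c("L_LACt", "EX_lac_L(e)", "BUTS", "BUTt", "EX_but(e)",
             "CO2t", "EX_co2(e)", "H2t", "EX_h2(e)"),
      equation = c("1 lac_L[c] + 1 h[c] -> 1 lac_L[e] + 1 h[e]",
                   "1 lac_L[e] ->",
                   "2 lac_L[c] + 1 h[c] -> 1 but[c] + 2 co2[c] + 2 h2[c]",
                   "1 but[c] + 1 h[c] -> 1 but[e] + 1 h[e]",
                   "1 but[e] ->",
                   "1 co2[c] -> 1 co2[e]", "1 co2[e] ->",
                   "1 h2[c] -> 1 h2[e]", "1 h2[e] ->"),
      lb = c(-1000, -1000, 0, -1000, -1000, -1000, -1000, -1000, -1000),
      ub = 1000,
      subsystem = c("Transport", "Exchange", "Butyrate synthesis", "Transport",
                    "Exchange", "Transport", "Exchange", "Transport", "Exchange"),
      kind = c("transport", "exchange", "internal", "transport", "exchange",
               "transport", "exchange", "transport", "exchange")),
    vitamin_producer = reactions(
      id = c("VITBS", "VITBt", "EX_vitb(e)"),
      equation = c("1 glc_D[c] -> 1 vitb[c]",
                   "1 vitb[c] -> 1 vitb[e]",
                   "1 vitb[e] ->"),
      lb = c(0, -1000, -1000), ub = 1000,
      subsystem = c("B-vitamin synthesis", "Transport", "Exchange"),
      kind = c("internal", "transport", "exchange")),
    generalist = reactions(
      id = c("ACFERM", "ACt", "EX_ac(e)", "CO2t", "EX_co2(e)", "H2t",
             "EX_h2(e)"),
      equation = c("1 glc_D[c] + 2 h2o[c] -> 2 ac[c] + 2 co2[c] + 4 h2[c] + 2 h[c]",
                   "1 ac[c] + 1 h[c] -> 1 ac[e] + 1 h[e]",
                   "1 ac[e] ->",
                   "1 co2[c] -> 1 co2[e]", "1 co2[e] ->",
                   "1 h2[c] -> 1 h2[e]", "1 h2[e] ->"),
      lb = c(0, -1000, -1000, -1000, -1000, -1000, -1000), ub = 1000,
      subsystem = c("Acetate fermentation", "Transport", "Exchange",
                    "Transport", "Exchange", "Transport", "Exchange"),
      kind = c("internal", "transport", "exchange", "transport", "exchange",
               "transport", "exchange")),
    hmo_degrader = reactions(
      # innate monosaccharide handling; the HMO uptake routes themselves are
      # injected from the trait table + catalog via expand_model()
      id = "GALISO",
      equation = "1 gal[c] -> 1 glc_D[c]",
      lb = 0, ub = 1000, subsystem = "Galactose metabolism",
      kind = "internal"))
}

merge_reaction_sets <- function(...) {
  sets <- list(...)
  rxns <- do.call(rbind, lapply(sets, `[[`, "rxns"))
  stoich <- do.call(c, lapply(sets, `[[`, "stoich"))
  keep <- !duplicated(rxns$id)
  list(rxns = rxns[keep, , drop = FALSE], stoich = stoich[rxns$id[keep]])
}

#' The HMO catalog of the synthetic universe
#'
#' Routes for the two toy HMOs: 2'-fucosyllactose (proton symport uptake,
#' fucosidase, fucose + GlcNAc export) and lacto-N-tetraose; plus gap-filling
#' catabolism templates for the degradation products (fucose to propanediol +
#' pyruvate, GlcNAc deacetylation, galactose isomerization, lactose
#' hydrolysis).
#'
#' @return An `hmo_catalog`.
#' @export
toy_hmo_catalog <- function() {
  rx <- reactions(
    id = c("EX_fuclac(e)", "FUCLACt", "FUCLAChyd", "FUCt", "EX_fuc_L(e)",
           "EX_lnt(e)", "LNTt", "LNThyd", "ACGAMt", "EX_acgam(e)",
           "FCLPA", "PPDt", "EX_ppd(e)", "PYRt", "EX_pyr(e)",
           "ACGAMdeg", "ACDt", "EX_acd(e)",
           "GALISO", "LACZ"),
    equation = c(
      "1 fuclac[e] ->",
      "1 fuclac[e] + 1 h[e] -> 1 fuclac[c] + 1 h[c]",
      "1 fuclac[c] + 1 h2o[c] -> 1 fuc_L[c] + 1 lcts[c]",
      "1 fuc_L[c] -> 1 fuc_L[e]",
      "1 fuc_L[e] ->",
      "1 lnt[e] ->",
      "1 lnt[e] + 1 h[e] -> 1 lnt[c] + 1 h[c]",
      "1 lnt[c] + 3 h2o[c] -> 2 gal[c] + 1 glc_D[c] + 1 acgam[c]",
      "1 acgam[c] -> 1 acgam[e]",
      "1 acgam[e] ->",
      "1 fuc_L[c] -> 1 ppd[c] + 1 pyr[c] + 1 h[c]",
      "1 ppd[c] -> 1 ppd[e]",
      "1 ppd[e] ->",
      "1 pyr[c] + 1 h[c] -> 1 pyr[e] + 1 h[e]",
      "1 pyr[e] ->",
      "1 acgam[c] + 1 h2o[c] -> 1 glc_D[c] + 1 acd[c]",
      "1 acd[c] -> 1 acd[e]",
      "1 acd[e] ->",
      "1 gal[c] -> 1 glc_D[c]",
      "1 lcts[c] + 1 h2o[c] -> 1 glc_D[c] + 1 gal[c]"),
    lb = c(-1000, 0, 0, -1000, -1000,
           -1000, 0, 0, -1000, -1000,
           0, -1000, -1000, -1000, -1000,
           0, -1000, -1000, 0, 0),
    ub = 1000,
    subsystem = c(rep("HMO degradation", 10),
                  "Fucose metabolism", "Transport", "Exchange", "Transport",
                  "Exchange", "Amino sugar metabolism", "Transport",
                  "Exchange", "Galactose metabolism", "Lactose metabolism"),
    kind = c("exchange", "transport", "internal", "transport", "exchange",
             "exchange", "transport", "internal", "transport", "exchange",
             "internal", "transport", "exchange", "transport", "exchange",
             "internal", "transport", "exchange", "internal", "internal"))
  met_ids <- sort(unique(unlist(lapply(rx$stoich, names), use.names = FALSE)))
  structure(list(
    mets = toy_met_rows(met_ids),
    rxns = rx$rxns, stoich = rx$stoich,
    routes = data.frame(
      hmo = c(rep("fuclac", 5), rep("lnt", 5)),
      reaction_id = c("EX_fuclac(e)", "FUCLACt", "FUCLAChyd", "FUCt",
                      "EX_fuc_L(e)",
                      "EX_lnt(e)", "LNTt", "LNThyd", "ACGAMt", "EX_acgam(e)"),
      stringsAsFactors = FALSE),
    catabolism = data.frame(
      product = c(rep("fuc_L", 5), rep("acgam", 3), "gal", "lcts"),
      reaction_id = c("FCLPA", "PPDt", "EX_ppd(e)", "PYRt", "EX_pyr(e)",
                      "ACGAMdeg", "ACDt", "EX_acd(e)", "GALISO", "LACZ"),
      stringsAsFactors = FALSE),
    mechanisms = data.frame(hmo = c("fuclac", "lnt"),
                            mechanism = c("proton-symport", "proton-symport"),
                            stringsAsFactors = FALSE)),
    class = "hmo_catalog") |> validate_catalog()
}

#' Generate the synthetic strain universe
#'
#' Produces one single-strain species reconstruction per guild slot, the
#' taxonomy table, the strain x HMO trait table (HMO degraders carry `fuclac`;
#' every second degrader additionally carries `lnt`), and the toy HMO catalog.
#' All models are balance-clean; growth feasibility of every species on the
#' breast-milk stage diet is LP-verified at generation time.
#'
#' @param config A [universe_config()].
#' @param check_growth LP-verify growth of every species (default TRUE).
#' @return list(models, taxonomy, traits, catalog); `models` is a named list
#'   keyed by species name.
#' @export
generate_universe <- function(config = universe_config(), check_growth = TRUE) {
  chem <- toy_chemistry()
  bad <- chem$id[is.na(chem$formula) | !nzchar(chem$formula)]
  if (length(bad) > 0L) {
    stop(sprintf("chemistry table inconsistency: %s", toString(bad)),
         call. = FALSE)
  }
  models <- list()
  tax_rows <- list()
  for (guild in GUILDS) {
    n <- config$n_per_guild[[guild]] %||% 0L
    if (n == 0L) next
    for (k in seq_len(n)) {
      species <- sprintf("%s synspecies %s%02d", guild_genus[[guild]],
                         substr(guild, 1, 1), k)
      set_core <- toy_core_reactions()
      set_guild <- guild_reactions(guild)
      rset <- merge_reaction_sets(set_core, set_guild)
      met_ids <- unique(c(
        unlist(lapply(rset$stoich, names), use.names = FALSE)))
      met_ids <- sort(setdiff(met_ids, "bio[c]"))
      mets <- rbind(toy_met_rows(met_ids),
                    data.frame(id = "bio[c]", name = "biomass", formula = "X",
                               charge = 0, compartment = "c",
                               stringsAsFactors = FALSE))
      model <- metabolic_model(
        id = sanitize_tag(species), mets = mets, rxns = rset$rxns,
        stoich = rset$stoich, biomass_id = "biomass",
        taxonomy = list(species = species, genus = guild_genus[[guild]],
                        phylum = guild_phylum[[guild]]))
      models[[species]] <- model
      tax_rows[[species]] <- data.frame(
        species = species, genus = guild_genus[[guild]],
        phylum = guild_phylum[[guild]], guild = guild,
        stringsAsFactors = FALSE)
    }
  }
  taxonomy <- do.call(rbind, tax_rows)
  rownames(taxonomy) <- NULL
  catalog <- toy_hmo_catalog()
  degraders <- taxonomy$species[taxonomy$guild == "hmo_degrader"]
  traits_m <- matrix(FALSE, nrow = nrow(taxonomy), ncol = 2,
                     dimnames = list(taxonomy$species, c("fuclac", "lnt")))
  traits_m[degraders, "fuclac"] <- TRUE
  traits_m[degraders[seq_along(degraders) %% 2L == 1L], "lnt"] <- TRUE
  refs <- matrix("", nrow = nrow(traits_m), ncol = ncol(traits_m),
                 dimnames = dimnames(traits_m))
  refs[traits_m] <- "synthetic guild assignment"
  traits <- structure(list(
    meta = data.frame(strain_id = taxonomy$species, species = taxonomy$species,
                      phylum = taxonomy$phylum, stringsAsFactors = FALSE),
    traits = traits_m, refs = refs), class = "hmo_traits")
  if (check_growth) {
    diets <- generate_diets()
    milk_diet <- build_stage_diet(
      feeding_regimen("5 days", "breastfed"), diets$milk)
    for (sp in names(models)) {
      if (strain_growth(models[[sp]], milk_diet) <= 1e-6) {
        stop(sprintf("generated species %s cannot grow on the milk diet", sp),
             call. = FALSE)
      }
    }
  }
  list(models = models, taxonomy = taxonomy, traits = traits,
       catalog = catalog)
}

#' Maximal growth of a single strain on a diet
#'
#' Exchange lower bounds are set to -flux for diet metabolites (0 otherwise,
#' micronutrient trickle for water/protons), a temporary biomass drain is
#' added, and biomass flux is maximized.
#'
#' @param model An `mbx_model`.
#' @param diet DietFluxTable or named vector (base metabolite -> flux).
#' @param micronutrients,trickle Trickle configuration, as in [apply_diet()].
#' @return Maximal biomass flux.
#' @export
strain_growth <- function(model, diet,
                          micronutrients = default_micronutrients(),
                          trickle = 0.1) {
  if (is.data.frame(diet)) diet <- stats::setNames(diet$flux, diet$metabolite)
  m <- model
  exch <- m$rxns$kind == "exchange"
  base <- vapply(m$rxns$id[exch], function(rid) {
    met_base(names(m$stoich[[rid]])[1])
  }, character(1))
  lb <- rep(0, sum(exch))
  lb[base %in% micronutrients] <- -trickle
  hit <- base %in% names(diet)
  lb[hit] <- -abs(unname(diet[base[hit]]))
  m$rxns$lb[exch] <- lb
  m$rxns$ub[exch] <- 1000
  bio_prod <- m$stoich[[m$biomass_id]]
  bio_prod <- names(bio_prod)[bio_prod > 0][1]
  m <- add_reactions(m, reactions("DM_bio_tmp", sprintf("1 %s ->", bio_prod),
                                  lb = 0, ub = 1000, kind = "demand"))$model
  res <- fba(m, stats::setNames(1, m$biomass_id))
  if (res$status != 0) return(0)
  res$objective
}

## ---- cohorts -------------------------------------------------------------

#' Planted CSD depletion effect map
#'
#' The canonical planted effect: the HMO-degrader guild is depleted in the
#' CSD-like group at the earliest time point by a multiplicative factor.
#'
#' @param multiplier Depletion multiplier (default 0.1).
#' @param time_point Affected time point (default "5 days").
#' @return data.frame(guild, group, time_point, multiplier).
#' @export
csd_depletion_effects <- function(multiplier = 0.1, time_point = "5 days") {
  data.frame(guild = "hmo_degrader", group = "CSD", time_point = time_point,
             multiplier = multiplier, stringsAsFactors = FALSE)
}

#' Configuration of a synthetic cohort
#'
#' The abundance model emulates the compositional structure of infant gut
#' metagenomes: per sample, each species is present with a probability set by
#' the time point's expected richness and its guild weight (occupancy), its
#' load is log-normal around its guild weight, effect-map multipliers rescale
#' the affected guild, shares are closed to sum 1, and shares below the
#' detection limit are zeroed (emulating the detection floor of taxonomic
#' profiling). By default the effect multiplier acts on both occupancy and
#' abundance (`effect_on`), reflecting that delivery-mode depletion of
#' bifidobacteria manifests mostly as absence at the earliest time points.
#'
#' @param n_vd,n_csd,n_maternal Samples per group (per time point for
#'   VD/CSD).
#' @param time_points Infant time points.
#' @param richness Named expected species count per time point (rising over
#'   the first year).
#' @param sigma Log-normal dispersion of species loads.
#' @param guild_weights Matrix guild x time point of occupancy/abundance
#'   weights; the default makes HMO degraders dominant early (breastfed,
#'   bifidobacteria-rich communities) and levels off by 1 year.
#' @param effects Effect map, e.g. [csd_depletion_effects()]; default none.
#' @param effect_on Which generative channels the multipliers act on:
#'   subset of `c("abundance", "occupancy")`.
#' @param detection_limit Relative abundance below which a species is
#'   reported absent.
#' @param seed Root seed; per-sample sub-seeds are derived from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_vd = 10, n_csd = 10, n_maternal = 0,
                          time_points = TIME_POINTS,
                          richness = c("5 days" = 5, "1 month" = 8,
                                       "6 months" = 12, "1 year" = 16),
                          sigma = 1.5,
                          guild_weights = NULL,
                          effects = NULL,
                          effect_on = c("abundance", "occupancy"),
                          detection_limit = 1e-3,
                          seed = 1L) {
  if (is.null(guild_weights)) {
    guild_weights <- rbind(
      hmo_degrader = c(4, 3, 1.5, 1, 0.3),
      lactate_producer = c(1.5, 1.5, 1, 1, 0.5),
      butyrate_producer = c(0.3, 0.5, 1, 1.5, 3),
      vitamin_producer = c(1, 1, 1, 1, 1),
      generalist = c(1, 1, 1, 1, 2))
    colnames(guild_weights) <- c(TIME_POINTS, "maternal")
  }
  if (is.unsorted(richness[time_points])) {
    stop("richness must be non-decreasing over time points", call. = FALSE)
  }
  if (!is.null(effects) && any(effects$multiplier <= 0)) {
    stop("effect multipliers must be > 0", call. = FALSE)
  }
  structure(list(n_vd = n_vd, n_csd = n_csd, n_maternal = n_maternal,
                 time_points = time_points, richness = richness,
                 sigma = sigma, guild_weights = guild_weights,
                 effects = effects %||% csd_depletion_effects()[0, ],
                 effect_on = match.arg(effect_on, several.ok = TRUE),
                 detection_limit = detection_limit, seed = as.integer(seed)),
            class = "cohort_config")
}

effect_multiplier <- function(config, guild, group, time_point) {
  e <- config$effects
  hit <- e$guild == guild & e$group == group & e$time_point == time_point
  if (any(hit)) prod(e$multiplier[hit]) else 1
}

#' Generate a synthetic cohort abundance table with metadata
#'
#' @param config A [cohort_config()].
#' @param taxonomy Taxonomy table from [generate_universe()] (species, genus,
#'   phylum, guild).
#' @return list(abundance = species x sample matrix with columns summing to 1,
#'   metadata = data.frame(sample, delivery_mode, time_point, feeding,
#'   antibiotics)).
#' @export
generate_cohort <- function(config, taxonomy) {
  species <- taxonomy$species
  n_sp <- length(species)
  samples <- list()
  meta <- list()
  idx <- 0L
  design <- rbind(
    if (config$n_vd > 0) expand.grid(rep = seq_len(config$n_vd), group = "VD",
                                     time_point = config$time_points,
                                     stringsAsFactors = FALSE),
    if (config$n_csd > 0) expand.grid(rep = seq_len(config$n_csd), group = "CSD",
                                      time_point = config$time_points,
                                      stringsAsFactors = FALSE),
    if (config$n_maternal > 0) expand.grid(rep = seq_len(config$n_maternal),
                                           group = "maternal",
                                           time_point = "maternal",
                                           stringsAsFactors = FALSE))
  for (i in seq_len(nrow(design))) {
    idx <- idx + 1L
    grp <- design$group[i]
    tp <- design$time_point[i]
    sid <- sprintf("%s_%s_%02d", grp, gsub(" ", "", tp), design$rep[i])
    richness <- if (tp == "maternal") max(config$richness) else config$richness[[tp]]
    w_col <- if (tp %in% colnames(config$guild_weights)) tp else "maternal"
    attempt <- 0L
    repeat {
      # per-sample sub-seed derived from the root seed (kept below 2^31)
      set.seed((config$seed * 10007L + idx * 131L + attempt) %% .Machine$integer.max)
      w <- config$guild_weights[taxonomy$guild, w_col]
      mult <- vapply(taxonomy$guild, effect_multiplier, numeric(1),
                     config = config, group = grp, time_point = tp)
      w_occ <- w * if ("occupancy" %in% config$effect_on) mult else 1
      pi_s <- pmin(0.95, richness * w_occ / sum(w_occ))
      present <- stats::runif(n_sp) < pi_s
      load <- exp(stats::rnorm(n_sp, mean = log(w), sd = config$sigma))
      if ("abundance" %in% config$effect_on) load <- load * mult
      load[!present] <- 0
      if (sum(load) > 0) {
        share <- load / sum(load)
        share[share < config$detection_limit] <- 0
        if (sum(share) > 0) {
          share <- share / sum(share)
          break
        }
      }
      attempt <- attempt + 1L
      message(sprintf("sample %s empty; regenerating with sub-seed offset %d",
                      sid, attempt))
    }
    samples[[sid]] <- share
    meta[[sid]] <- data.frame(
      sample = sid, delivery_mode = grp, time_point = tp,
      feeding = if (grp == "maternal") "adult" else "breastfed",
      antibiotics = FALSE, stringsAsFactors = FALSE)
  }
  abundance <- do.call(cbind, samples)
  rownames(abundance) <- species
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  list(abundance = abundance, metadata = metadata)
}

## ---- diets ---------------------------------------------------------------

#' Generate breast-milk and formula concentration tables plus stage regimens
#'
#' The breast-milk table carries the toy HMOs (2'-fucosyllactose at 2.4 g/L,
#' lacto-N-tetraose at 1.2 g/L, within reported ranges for mature milk),
#' lactose at 67 g/L, traces of free glucose and galactose, and water. The
#' formula variant lacks HMOs. Stage volumes follow the cohort defaults
#' (480/720/1260/1320 mL/day); the 6-month and 1-year regimens add solid food
#' items with per-gram flux tables.
#'
#' @param time_points Stages to build regimens for.
#' @param variants Feeding variants.
#' @return list(milk, formula, solids, regimens): concentration tables
#'   (metabolite, concentration, unit, mw), the solid-food per-gram flux
#'   table (food, metabolite, mmol_per_g), and a named list of
#'   [feeding_regimen()]s keyed `"<time point>|<variant>"`.
#' @export
generate_diets <- function(time_points = TIME_POINTS,
                           variants = c("breastfed", "formula")) {
  milk <- data.frame(
    metabolite = c("lcts", "fuclac", "lnt", "glc_D", "gal", "h2o"),
    concentration = c(67, 2.4, 1.2, 0.3, 0.2, 52800),
    unit = c("g/L", "g/L", "g/L", "g/L", "g/L", "mmol/L"),
    mw = c(342.30, 488.44, 707.63, 180.16, 180.16, NA),
    stringsAsFactors = FALSE)
  formula <- data.frame(
    metabolite = c("lcts", "glc_D", "gal", "h2o"),
    concentration = c(72, 0.5, 0.2, 52800),
    unit = c("g/L", "g/L", "g/L", "mmol/L"),
    mw = c(342.30, 180.16, 180.16, NA),
    stringsAsFactors = FALSE)
  solids <- data.frame(
    food = c("apple sauce strained", "apple sauce strained",
             "chicken soup",
             "bananas with apples and pears", "bananas with apples and pears",
             "baby food yogurt", "baby food yogurt"),
    metabolite = c("glc_D", "gal", "glc_D", "glc_D", "gal", "lcts", "glc_D"),
    mmol_per_g = c(0.30, 0.02, 0.05, 0.45, 0.03, 0.12, 0.02),
    stringsAsFactors = FALSE)
  stage_solids <- list(
    "5 days" = NULL, "1 month" = NULL,
    "6 months" = data.frame(food = c("apple sauce strained", "chicken soup"),
                            grams = c(50, 50), stringsAsFactors = FALSE),
    "1 year" = data.frame(food = c("bananas with apples and pears",
                                   "baby food yogurt", "chicken soup"),
                          grams = c(112, 122.5, 120), stringsAsFactors = FALSE))
  regimens <- list()
  for (tp in time_points) {
    for (v in variants) {
      si <- stage_solids[[tp]]
      regimens[[paste(tp, v, sep = "|")]] <- feeding_regimen(
        tp, v, solid_items = si %||% data.frame(food = character(0),
                                                grams = numeric(0)))
    }
  }
  list(milk = milk, formula = formula, solids = solids, regimens = regimens)
}

#' Generic adult diet flux table (toy counterpart of a standard adult diet)
#'
#' Used for maternal samples so that infant and maternal communities are
#' interrogated on a consistent reference diet.
#' @return A DietFluxTable.
#' @export
adult_diet <- function() {
  data.frame(metabolite = c("lcts", "glc_D", "gal", "h2o"),
             flux = c(15, 120, 5, 70000),
             provenance = "milk", stringsAsFactors = FALSE)
}

## ---- workspace writer ----------------------------------------------------

#' Write a complete synthetic workspace to disk
#'
#' Produces the on-disk layout the pipeline consumes: `models/` (tabular
#' dialect, one directory per species), `traits.tsv`, `catalog/`,
#' `abundance.tsv`, `metadata.tsv` and `diets/`.
#'
#' @param universe From [generate_universe()].
#' @param cohort From [generate_cohort()].
#' @param diets From [generate_diets()].
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_workspace <- function(universe, cohort, diets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (sp in names(universe$models)) {
    write_model(universe$models[[sp]],
                file.path(mdir, sanitize_tag(sp)), "tabular")
  }
  write_tsv_strict(universe$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_trait_table(universe$traits, file.path(dir, "traits.tsv"))
  write_catalog(universe$catalog, file.path(dir, "catalog"))
  ab <- data.frame(taxon = rownames(cohort$abundance), cohort$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(ab, file.path(dir, "abundance.tsv"))
  write_tsv_strict(cohort$metadata, file.path(dir, "metadata.tsv"))
  ddir <- file.path(dir, "diets")
  dir.create(ddir, showWarnings = FALSE)
  write_tsv_strict(diets$milk, file.path(ddir, "milk.tsv"))
  write_tsv_strict(diets$formula, file.path(ddir, "formula.tsv"))
  write_tsv_strict(diets$solids, file.path(ddir, "solids.tsv"))
  reg <- do.call(rbind, lapply(names(diets$regimens), function(k) {
    r <- diets$regimens[[k]]
    data.frame(key = k, time_point = r$time_point, feeding = r$feeding,
               milk_volume = r$milk_volume,
               solid_items = paste(sprintf("%s=%g", r$solid_items$food,
                                           r$solid_items$grams),
                                   collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  write_tsv_strict(reg, file.path(ddir, "regimens.tsv"))
  invisible(dir)
}

#' Read back a workspace written by [write_workspace()]
#' @param dir Workspace directory.
#' @return list(models, taxonomy, traits, catalog, abundance, metadata, diets).
#' @export
read_workspace <- function(dir) {
  mdir <- file.path(dir, "models")
  model_dirs <- list.dirs(mdir, recursive = FALSE)
  models <- lapply(model_dirs, read_model, format = "tabular")
  names(models) <- vapply(models, function(m) m$taxonomy$species, character(1))
  taxonomy <- read_tsv_strict(file.path(dir, "taxonomy.tsv"))
  ab <- read_tsv_strict(file.path(dir, "abundance.tsv"))
  abundance <- as.matrix(ab[, -1, drop = FALSE])
  rownames(abundance) <- ab[[1]]
  ddir <- file.path(dir, "diets")
  reg_df <- read_tsv_strict(file.path(ddir, "regimens.tsv"))
  regimens <- list()
  for (i in seq_len(nrow(reg_df))) {
    si <- reg_df$solid_items[i]
    solid_items <- if (is.na(si) || !nzchar(si)) {
      data.frame(food = character(0), grams = numeric(0))
    } else {
      parts <- strsplit(strsplit(si, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      data.frame(food = vapply(parts, `[[`, character(1), 1),
                 grams = as.numeric(vapply(parts, `[[`, character(1), 2)),
                 stringsAsFactors = FALSE)
    }
    regimens[[reg_df$key[i]]] <- feeding_regimen(
      reg_df$time_point[i], reg_df$feeding[i],
      milk_volume = reg_df$milk_volume[i], solid_items = solid_items)
  }
  list(models = models, taxonomy = taxonomy,
       traits = load_trait_table(file.path(dir, "traits.tsv")),
       catalog = load_catalog(file.path(dir, "catalog")),
       abundance = abundance,
       metadata = read_tsv_strict(file.path(dir, "metadata.tsv")),
       diets = list(milk = read_tsv_strict(file.path(ddir, "milk.tsv")),
                    formula = read_tsv_strict(file.path(ddir, "formula.tsv")),
                    solids = read_tsv_strict(file.path(ddir, "solids.tsv")),
                    regimens = regimens))
}
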