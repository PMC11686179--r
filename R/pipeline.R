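## End-to-end orchestration: workspace -> HMO expansion -> pan models ->
## community assembly -> diet -> simulation -> statistics, with a provenance
## manifest. Per-sample failures are logged and skipped; a run fails only if
## no sample succeeds.

#' Default run configuration
#'
#' @param workspace Workspace directory (layout of [write_workspace()]).
#' @param output Output directory for CSVs and the manifest.
#' @param abundance_cutoff Relative abundance cutoff (>= 0).
#' @param coupling_factor,couple,growth_lb,growth_ub Community constraints,
#'   see [community_config()].
#' @param micronutrients,trickle Diet defaults, see [apply_diet()].
#' @param solver LP backend name; only `"highs"` (scipy) is supported.
#' @param comparisons Character vector of comparison specs:
#'   `"vd_vs_csd@<time point>"`, `"timepoints"`, `"antibiotics"`,
#'   `"infant_vs_maternal"`.
#' @param contribution_metabolites Metabolites for species-contribution LPs
#'   (empty = skip).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed governs upstream synthetic generation).
#' @return A `run_config` list.
#' @export
run_config <- function(workspace, output,
                       abundance_cutoff = 1e-4, coupling_factor = 400,
                       couple = TRUE, growth_lb = 0.4, growth_ub = 1,
                       micronutrients = default_micronutrients(),
                       trickle = 0.1, solver = "highs",
                       comparisons = character(0),
                       contribution_metabolites = character(0),
                       seed = 1L) {
  structure(list(workspace = workspace, output = output,
                 abundance_cutoff = abundance_cutoff,
                 coupling_factor = coupling_factor, couple = couple,
                 growth_lb = growth_lb, growth_ub = growth_ub,
                 micronutrients = micronutrients, trickle = trickle,
                 solver = solver, comparisons = comparisons,
                 contribution_metabolites = contribution_metabolites,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read config: %s", path),
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config field(s): %s", toString(unknown)),
         call. = FALSE)
  }
  do.call(run_config, y)
}

SUPPORTED_SOLVERS <- "highs"

#' Validate a run configuration
#'
#' @param config A `run_config`, or a path to a YAML config.
#' @return data.frame(field, message) of violations (zero rows if clean).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  v <- list()
  flag <- function(field, msg) v[[length(v) + 1L]] <<- data.frame(
    field = field, message = msg, stringsAsFactors = FALSE)
  if (!dir.exists(config$workspace %||% "")) {
    flag("workspace", sprintf("workspace directory not found: %s",
                              config$workspace))
  } else {
    for (f in c("models", "traits.tsv", "catalog", "abundance.tsv",
                "metadata.tsv", "diets")) {
      if (!file.exists(file.path(config$workspace, f))) {
        flag("workspace", sprintf("missing workspace entry: %s", f))
      }
    }
  }
  if (config$abundance_cutoff < 0) {
    flag("abundance_cutoff", "abundance cutoff must be >= 0")
  }
  if (config$coupling_factor <= 0) {
    flag("coupling_factor", "coupling factor must be > 0")
  }
  if (config$growth_lb < 0 || config$growth_ub < config$growth_lb) {
    flag("growth", "growth window must satisfy 0 <= lb <= ub")
  }
  if (config$trickle < 0) flag("trickle", "trickle flux must be >= 0")
  if (!config$solver %in% SUPPORTED_SOLVERS) {
    flag("solver", sprintf("unknown solver '%s'; supported: %s",
                           config$solver, toString(SUPPORTED_SOLVERS)))
  }
  ok <- grepl("^vd_vs_csd@", config$comparisons) |
    config$comparisons %in% c("timepoints", "antibiotics", "infant_vs_maternal")
  if (any(!ok)) {
    flag("comparisons", sprintf("unknown comparison spec(s): %s",
                                toString(config$comparisons[!ok])))
  }
  if (length(v) == 0L) {
    return(data.frame(field = character(0), message = character(0)))
  }
  do.call(rbind, v)
}

# diet for one sample given its metadata row and the workspace diet tables
sample_diet <- function(meta_row, diets) {
  if (meta_row$delivery_mode == "maternal" || meta_row$feeding == "adult") {
    return(adult_diet())
  }
  feeding <- meta_row$feeding
  # combined breast/formula feeding receives the breast-milk diet in silico
  table_kind <- if (feeding %in% c("breastfed", "combined")) "milk" else "formula"
  key <- paste(meta_row$time_point, feeding, sep = "|")
  regimen <- diets$regimens[[key]] %||%
    diets$regimens[[paste(meta_row$time_point,
                          if (table_kind == "milk") "breastfed" else "formula",
                          sep = "|")]]
  if (is.null(regimen)) {
    stop(sprintf("no feeding regimen for time point '%s' / feeding '%s'",
                 meta_row$time_point, feeding), call. = FALSE)
  }
  build_stage_diet(regimen, diets[[table_kind]], diets$solids)
}

grouping_from_spec <- function(spec, metadata) {
  if (grepl("^vd_vs_csd@", spec)) {
    tp <- sub("^vd_vs_csd@", "", spec)
    list(type = "two_group", column = "delivery_mode", groups = c("VD", "CSD"),
         at = list(time_point = tp))
  } else if (spec == "timepoints") {
    list(type = "time_course", column = "time_point",
         at = list(delivery_mode = c("VD", "CSD")))
  } else if (spec == "antibiotics") {
    list(type = "two_group", column = "antibiotics",
         groups = c(TRUE, FALSE), at = list(delivery_mode = c("VD", "CSD")))
  } else if (spec == "infant_vs_maternal") {
    list(type = "two_group", column = "cohort_group",
         groups = c("infant", "maternal"))
  } else {
    stop(sprintf("unknown comparison spec '%s'", spec), call. = FALSE)
  }
}

#' Run the full pipeline on a workspace
#'
#' Loads the workspace, expands every strain with its trait-enabled HMO routes,
#' builds pan-species models, matches and normalizes the abundance table, then
#' per sample assembles the community model, applies the stage diet, and
#' computes net secretion profiles and reaction/subsystem metrics (plus
#' species contributions if configured). Results, group-comparison statistics,
#' and a provenance manifest are written to the output directory.
#'
#' @param config A `run_config`, or a path to a YAML config file.
#' @return Invisibly, a list with the result tables, per-sample status, and
#'   output paths. Fails with an error only if configuration is invalid or no
#'   sample succeeds.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  violations <- validate_config(config)
  if (nrow(violations) > 0L) {
    stop(sprintf("invalid configuration:\n%s",
                 paste(sprintf("- %s: %s", violations$field, violations$message),
                       collapse = "\n")), call. = FALSE)
  }
  ws <- read_workspace(config$workspace)
  dir.create(config$output, showWarnings = FALSE, recursive = TRUE)

  # 1. HMO expansion per strain (trait rows keyed by strain id)
  expansion <- list()
  for (sid in rownames(ws$traits$traits)) {
    sp <- ws$traits$meta$species[match(sid, ws$traits$meta$strain_id)]
    if (!sp %in% names(ws$models)) next
    ex <- expand_model(ws$models[[sp]], ws$traits$traits[sid, ], ws$catalog)
    ws$models[[sp]] <- ex$model
    expansion[[sid]] <- ex$report
  }

  # 2. pan-species models (group strains by species)
  strain_species <- vapply(ws$models, function(m) m$taxonomy$species,
                           character(1))
  pan_models <- lapply(split(ws$models, strain_species), build_pan_model)

  # 3. taxa matching + abundance normalization
  mapping <- match_taxa(rownames(ws$abundance), names(pan_models))
  ab <- ws$abundance[mapping$mapping$input, , drop = FALSE]
  rownames(ab) <- mapping$mapping$model_id
  ab <- normalize_abundances(ab, config$abundance_cutoff)

  ccfg <- community_config(coupling_factor = config$coupling_factor,
                           couple = config$couple,
                           growth_lb = config$growth_lb,
                           growth_ub = config$growth_ub,
                           abundance_cutoff = config$abundance_cutoff)
  dcfg <- list(micronutrients = config$micronutrients,
               trickle = config$trickle)

  metadata <- ws$metadata
  metadata$cohort_group <- ifelse(metadata$delivery_mode == "maternal",
                                  "maternal", "infant")
  samples <- intersect(colnames(ab), metadata$sample)
  # phase 1: assemble + diet per sample (failures isolated per sample)
  communities <- list(); abund_ok <- list()
  sizes <- list(); status <- list()
  for (s in samples) {
    res <- tryCatch({
      mrow <- metadata[metadata$sample == s, , drop = FALSE]
      abun <- ab[, s]
      abun <- abun[abun > 0]
      comm <- assemble_community(pan_models[names(abun)], abun,
                                 config = ccfg, id = s)
      diet <- sample_diet(mrow, ws$diets)
      comm <- suppressWarnings(apply_diet(comm, diet, dcfg))
      list(comm = comm, abun = abun)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("sample %s failed: %s", s, conditionMessage(res)))
      status[[s]] <- conditionMessage(res)
      next
    }
    communities[[s]] <- res$comm
    abund_ok[[s]] <- res$abun
    sizes[[s]] <- data.frame(sample = s, n_species = nrow(res$comm$species),
                             n_reactions = nrow(res$comm$model$rxns),
                             n_metabolites = nrow(res$comm$model$mets),
                             stringsAsFactors = FALSE)
  }
  # phase 2: one batched LP call covering all samples' growth + secretion LPs
  secretion <- list(); metrics <- list(); contrib <- list()
  if (length(communities) > 0L) {
    ns_res <- net_secretion_batch(communities)
    for (s in names(communities)) {
      if (is.null(ns_res$secretion[[s]])) {
        message(sprintf("sample %s failed: %s", s, ns_res$errors[[s]]))
        status[[s]] <- ns_res$errors[[s]]
        next
      }
      status[[s]] <- "ok"
      secretion[[s]] <- ns_res$secretion[[s]]
      metrics[[s]] <- compute_reaction_metrics(abund_ok[[s]], pan_models)
      if (length(config$contribution_metabolites) > 0L) {
        contrib[[s]] <- compute_contributions(communities[[s]],
                                              config$contribution_metabolites)
      }
    }
  }
  if (length(secretion) == 0L) {
    stop("no sample succeeded", call. = FALSE)
  }
  ok_samples <- names(secretion)
  sizes <- sizes[ok_samples]

  bind_named <- function(lst) {
    feats <- sort(unique(unlist(lapply(lst, names), use.names = FALSE)))
    m <- matrix(0, nrow = length(lst), ncol = length(feats),
                dimnames = list(names(lst), feats))
    for (s in names(lst)) m[s, names(lst[[s]])] <- lst[[s]]
    m
  }
  net_secretion <- bind_named(secretion)
  reaction_abundance <- bind_named(lapply(metrics, `[[`, "reaction_abundance"))
  reaction_presence <- bind_named(lapply(metrics, function(x) {
    as.numeric(x$presence) |> stats::setNames(names(x$presence))
  }))
  subsystem_abundance <- bind_named(lapply(metrics, `[[`, "subsystem_abundance"))
  contributions <- if (length(contrib) > 0L) do.call(rbind, contrib)

  write_matrix_csv <- function(m, name) {
    df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(config$output, name), row.names = FALSE)
  }
  write_matrix_csv(net_secretion, "net_secretion.csv")
  write_matrix_csv(reaction_abundance, "reaction_abundance.csv")
  write_matrix_csv(reaction_presence, "reaction_presence.csv")
  write_matrix_csv(subsystem_abundance, "subsystem_abundance.csv")
  if (!is.null(contributions)) {
    utils::write.csv(contributions, file.path(config$output, "contributions.csv"),
                     row.names = FALSE)
  }

  # 4. statistics; the secretion family is restricted to metabolites secreted
  # by at least one sample, matching how the feature universe is reported
  md_ok <- metadata[metadata$sample %in% ok_samples, , drop = FALSE]
  families <- list(
    secretion = net_secretion[, colSums(net_secretion) > 0, drop = FALSE],
    reaction_abundance = reaction_abundance,
    reaction_presence = reaction_presence,
    subsystem_abundance = subsystem_abundance)
  stats_tables <- list()
  for (spec in config$comparisons) {
    grouping <- grouping_from_spec(spec, md_ok)
    for (fam in names(families)) {
      tbl <- tryCatch(
        compare_features(families[[fam]], md_ok, grouping),
        error = function(e) {
          message(sprintf("comparison %s/%s skipped: %s", spec, fam,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(tbl)) next
      fname <- sprintf("stats_%s_%s.csv", fam, gsub("[^A-Za-z0-9_]+", "_", spec))
      utils::write.csv(tbl, file.path(config$output, fname), row.names = FALSE)
      stats_tables[[paste(fam, spec, sep = "|")]] <- tbl
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("babybiome")),
    config = unclass(config),
    n_samples = length(samples),
    n_samples_ok = length(ok_samples),
    unmatched_taxa = mapping$unmatched,
    sample_status = status,
    sample_sizes = do.call(rbind, sizes),
    expansion_n_added = vapply(expansion, `[[`, numeric(1), "n_added"))
  jsonlite::write_json(manifest, file.path(config$output, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       null = "null", pretty = TRUE)

  invisible(list(net_secretion = net_secretion,
                 reaction_abundance = reaction_abundance,
                 reaction_presence = reaction_presence,
                 subsystem_abundance = subsystem_abundance,
                 contributions = contributions, stats = stats_tables,
                 manifest = manifest, output = config$output))
}
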