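## Diet construction: milk composition tables and stage volumes -> uptake flux
## tables (mmol/person/day) -> diet exchange bounds on community models.

#' Default daily milk volumes by developmental stage (mL/day)
#' @return Named numeric vector for 5 days, 1 month, 6 months, 1 year.
#' @export
default_milk_volumes <- function() {
  c("5 days" = 480, "1 month" = 720, "6 months" = 1260, "1 year" = 1320)
}

TIME_POINTS <- c("5 days", "1 month", "6 months", "1 year")

#' Convert a milk concentration to a daily uptake flux
#'
#' `g/L`: flux = conc * (volume/1000) * 1000 / mw; `mmol/L`: flux =
#' conc * volume / 1000. Result in mmol/person/day.
#'
#' @param concentration Non-negative concentration value.
#' @param unit `"g/L"` or `"mmol/L"`.
#' @param volume_mL Daily consumption volume in mL.
#' @param mw_g_per_mol Molecular weight; required iff `unit == "g/L"`.
#' @return Flux in mmol/person/day.
#' @examples
#' concentration_to_flux(7, "g/L", 480, 342.30) # lactose example
#' @export
concentration_to_flux <- function(concentration, unit = c("g/L", "mmol/L"),
                                  volume_mL, mw_g_per_mol = NA) {
  unit <- match.arg(unit)
  if (concentration < 0 || volume_mL < 0) {
    stop("concentration and volume must be non-negative", call. = FALSE)
  }
  if (unit == "g/L") {
    if (is.na(mw_g_per_mol) || mw_g_per_mol <= 0) {
      stop("molecular weight (g/mol) required for a g/L concentration",
           call. = FALSE)
    }
    concentration * (volume_mL / 1000) * 1000 / mw_g_per_mol
  } else {
    concentration * volume_mL / 1000
  }
}

#' Build a feeding regimen
#'
#' @param time_point One of `"5 days"`, `"1 month"`, `"6 months"`, `"1 year"`.
#' @param feeding `"breastfed"`, `"formula"` or `"combined"` (combined feeding
#'   is modeled with the breast-milk table, following the cohort convention).
#' @param milk_volume mL/day; defaults to the stage value from
#'   [default_milk_volumes()].
#' @param solid_items data.frame(food, grams); must be empty before 6 months.
#' @return A `feeding_regimen` list.
#' @export
feeding_regimen <- function(time_point, feeding = c("breastfed", "formula", "combined"),
                            milk_volume = NULL,
                            solid_items = data.frame(food = character(0),
                                                     grams = numeric(0))) {
  feeding <- match.arg(feeding)
  if (!time_point %in% TIME_POINTS) {
    stop(sprintf("unknown time point '%s' (expected one of %s)", time_point,
                 toString(TIME_POINTS)), call. = FALSE)
  }
  if (is.null(milk_volume)) milk_volume <- default_milk_volumes()[[time_point]]
  if (time_point %in% c("5 days", "1 month") && nrow(solid_items) > 0L) {
    stop(sprintf("solid foods are not part of the %s regimen", time_point),
         call. = FALSE)
  }
  structure(list(time_point = time_point, feeding = feeding,
                 milk_volume = milk_volume, solid_items = solid_items),
            class = "feeding_regimen")
}

#' Build a stage diet flux table from a regimen
#'
#' Per metabolite, flux = milk contribution (concentration converted at the
#' regimen's volume) + sum of grams x per-gram flux over solid items.
#'
#' @param regimen A [feeding_regimen()]. For combined feeding pass the
#'   breast-milk concentration table as `milk`.
#' @param milk ConcentrationTable: data.frame(metabolite, concentration, unit,
#'   mw) — `mw` may be NA for `mmol/L` rows.
#' @param solids data.frame(food, metabolite, mmol_per_g); only needed when the
#'   regimen has solid items.
#' @return A `DietFluxTable`: data.frame(metabolite, flux, provenance) with
#'   flux in mmol/person/day.
#' @export
build_stage_diet <- function(regimen, milk,
                             solids = data.frame(food = character(0),
                                                 metabolite = character(0),
                                                 mmol_per_g = numeric(0))) {
  stopifnot(inherits(regimen, "feeding_regimen"))
  flux <- stats::setNames(numeric(0), character(0))
  prov <- character(0)
  for (i in seq_len(nrow(milk))) {
    f <- concentration_to_flux(milk$concentration[i], milk$unit[i],
                               regimen$milk_volume, milk$mw[i])
    if (f <= 0) next
    met <- milk$metabolite[i]
    flux[met] <- (if (met %in% names(flux)) flux[[met]] else 0) + f
    prov[met] <- "milk"
  }
  if (nrow(regimen$solid_items) > 0L) {
    unknown <- setdiff(regimen$solid_items$food, unique(solids$food))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown solid food item(s): %s", toString(unknown)),
           call. = FALSE)
    }
    for (i in seq_len(nrow(regimen$solid_items))) {
      item <- regimen$solid_items[i, ]
      rows <- solids[solids$food == item$food, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        met <- rows$metabolite[k]
        f <- item$grams * rows$mmol_per_g[k]
        if (f <= 0) next
        had_milk <- met %in% names(flux) && prov[met] == "milk"
        flux[met] <- (if (met %in% names(flux)) flux[[met]] else 0) + f
        prov[met] <- if (had_milk) "milk" else "solid"
      }
    }
  }
  out <- data.frame(metabolite = names(flux), flux = unname(flux),
                    provenance = unname(prov[names(flux)]),
                    stringsAsFactors = FALSE)
  out[order(out$metabolite), , drop = FALSE]
}

#' Default essential-micronutrient trickle list
#'
#' Metabolites opened at a small default uptake even when absent from the
#' diet table, so that community models are not rendered infeasible by missing
#' ubiquitous compounds. Configurable through the `config` of [apply_diet()].
#' @return Character vector of base metabolite ids.
#' @export
default_micronutrients <- function() c("h", "h2o")

#' Apply a diet flux table to a community model
#'
#' For each diet entry with a matching diet exchange `Diet_EX_<met>[d]` the
#' lower bound is set to `-flux` (negative flux = uptake into the lumen) and
#' the upper bound to 0. All other diet exchanges are closed (0, 0) except
#' metabolites on the configured micronutrient list, which are opened at the
#' trickle flux. Non-diet-exchange bounds are never touched. Diet entries
#' without a matching exchange are skipped with a warning.
#'
#' @param community An `mbx_community` (see [assemble_community()]).
#' @param diet A DietFluxTable from [build_stage_diet()], or a named numeric
#'   vector (metabolite -> mmol/person/day).
#' @param config List with `micronutrients` (base ids) and `trickle`
#'   (mmol/person/day, default 0.1).
#' @return The community with updated diet-exchange bounds; the number of
#'   skipped diet entries is recorded in `community$diet_skipped`.
#' @export
apply_diet <- function(community, diet,
                       config = list(micronutrients = default_micronutrients(),
                                     trickle = 0.1)) {
  stopifnot(inherits(community, "mbx_community"))
  if (is.data.frame(diet)) {
    diet <- stats::setNames(diet$flux, diet$metabolite)
  }
  micro <- config$micronutrients %||% default_micronutrients()
  trickle <- config$trickle %||% 0.1
  rxns <- community$model$rxns
  is_diet_ex <- startsWith(rxns$id, "Diet_EX_")
  diet_mets <- met_base(sub("^Diet_EX_", "", rxns$id[is_diet_ex]))
  lb <- stats::setNames(rep(0, sum(is_diet_ex)), diet_mets)
  lb[diet_mets %in% micro] <- -trickle
  matched <- names(diet)[names(diet) %in% diet_mets]
  lb[matched] <- -abs(diet[matched])
  skipped <- setdiff(names(diet), diet_mets)
  if (length(skipped) > 0L) {
    warning(sprintf("%d diet metabolite(s) without a diet exchange skipped: %s",
                    length(skipped), toString(skipped)), call. = FALSE)
  }
  rxns$lb[is_diet_ex] <- unname(lb[diet_mets])
  rxns$ub[is_diet_ex] <- 0
  community$model$rxns <- rxns
  community$diet_skipped <- length(skipped)
  community
}

`%||%` <- function(a, b) if (is.null(a)) b else a
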