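## Model readers/writers.
##
## Two dialects:
##  * "tabular": a directory holding metabolites.tsv (id, name, formula, charge,
##    compartment), reactions.tsv (id, name, equation, lb, ub, subsystem, kind)
##    and model.tsv (key/value metadata). Human-editable; used for fixtures.
##  * "sbml": SBML Level 3 Version 1 with the FBC v2 package (species charge +
##    chemical formula, flux bound parameters, active biomass objective).
##    Subsystem and kind travel in COBRA-style reaction notes.

#' Read a metabolic model from disk
#' @param path For `"tabular"`, a directory with metabolites.tsv/reactions.tsv;
#'   for `"sbml"`, an .xml file.
#' @param format `"sbml"` or `"tabular"`.
#' @return An `mbx_model`.
#' @export
read_model <- function(path, format = c("sbml", "tabular")) {
  format <- match.arg(format)
  switch(format, tabular = read_model_tabular(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model to disk
#' @param model An `mbx_model`.
#' @param path Target directory (tabular) or file (sbml).
#' @param format `"sbml"` or `"tabular"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("sbml", "tabular")) {
  format <- match.arg(format)
  switch(format, tabular = write_model_tabular(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_tsv_strict <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", quote = "")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

read_model_tabular <- function(path) {
  if (!dir.exists(path)) stop(sprintf("no such model directory: %s", path),
                              call. = FALSE)
  mets <- read_tsv_strict(file.path(path, "metabolites.tsv"))
  rxns <- read_tsv_strict(file.path(path, "reactions.tsv"))
  need_m <- c("id", "name", "formula", "charge", "compartment")
  need_r <- c("id", "name", "equation", "lb", "ub", "subsystem", "kind")
  if (!all(need_m %in% names(mets))) {
    stop("metabolites.tsv must have columns: ", toString(need_m), call. = FALSE)
  }
  if (!all(need_r %in% names(rxns))) {
    stop("reactions.tsv must have columns: ", toString(need_r), call. = FALSE)
  }
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  rxns$subsystem[is.na(rxns$subsystem)] <- ""
  meta <- c(id = basename(path), species = NA, genus = NA, phylum = NA,
            biomass_id = NA)
  meta_path <- file.path(path, "model.tsv")
  if (file.exists(meta_path)) {
    kv <- read_tsv_strict(meta_path)
    meta[kv$key] <- kv$value
  }
  stoich <- lapply(rxns$equation, parse_equation)
  names(stoich) <- rxns$id
  unresolved <- setdiff(unique(unlist(lapply(stoich, names))), mets$id)
  if (length(unresolved) > 0L) {
    stop(sprintf("load error: stoichiometry references metabolite(s) absent from metabolites.tsv: %s",
                 toString(unresolved)), call. = FALSE)
  }
  metabolic_model(
    id = unname(meta[["id"]]),
    mets = mets[need_m],
    rxns = rxns[c("id", "name", "lb", "ub", "subsystem", "kind")],
    stoich = stoich,
    biomass_id = unname(meta[["biomass_id"]]),
    taxonomy = list(species = unname(meta[["species"]]),
                    genus = unname(meta[["genus"]]),
                    phylum = unname(meta[["phylum"]])))
}

write_model_tabular <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv_strict(model$mets, file.path(path, "metabolites.tsv"))
  rx <- model$rxns
  rx$equation <- vapply(model$stoich[rx$id], format_equation, character(1))
  write_tsv_strict(rx[c("id", "name", "equation", "lb", "ub", "subsystem", "kind")],
                   file.path(path, "reactions.tsv"))
  meta <- data.frame(
    key = c("id", "species", "genus", "phylum", "biomass_id"),
    value = c(model$id, model$taxonomy$species, model$taxonomy$genus,
              model$taxonomy$phylum, model$biomass_id),
    stringsAsFactors = FALSE)
  write_tsv_strict(meta, file.path(path, "model.tsv"))
}

## ---- SBML ----------------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# SBML SIds allow only [A-Za-z0-9_] and must not start with a digit. Encode
# every other character (notably the compartment brackets) as __<ascii>__.
sbml_encode_id <- function(id) {
  vapply(id, function(x) {
    chars <- strsplit(x, "")[[1]]
    paste0(vapply(chars, function(ch) {
      if (grepl("^[A-Za-z0-9_]$", ch)) ch else sprintf("__%d__", utf8ToInt(ch))
    }, character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sbml_decode_id <- function(id) {
  vapply(id, function(x) {
    m <- gregexpr("__([0-9]+)__", x)[[1]]
    if (m[1] == -1) return(x)
    out <- x
    codes <- regmatches(x, gregexpr("__([0-9]+)__", x))[[1]]
    for (cd in unique(codes)) {
      ch <- intToUtf8(as.integer(gsub("_", "", cd)))
      out <- gsub(cd, ch, out, fixed = TRUE)
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = sbml_encode_id(model$id),
                               "fbc:strict" = "false")
  notes <- xml2::xml_add_child(mnode, "notes")
  body <- xml2::xml_add_child(notes, "body",
                              xmlns = "http://www.w3.org/1999/xhtml")
  for (k in c("species", "genus", "phylum")) {
    xml2::xml_add_child(body, "p",
                        sprintf("%s: %s", toupper(k),
                                as.character(model$taxonomy[[k]])))
  }
  comps <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cmp in unique(model$mets$compartment)) {
    xml2::xml_add_child(comps, "compartment", id = cmp, constant = "true")
  }
  spl <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    m <- model$mets[i, ]
    xml2::xml_add_child(
      spl, "species",
      id = paste0("M_", sbml_encode_id(m$id)), name = m$name,
      compartment = m$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false",
      "fbc:charge" = format(m$charge, scientific = FALSE),
      "fbc:chemicalFormula" = m$formula)
  }
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- stats::setNames(sprintf("bnd_%d", seq_along(bounds)),
                         sprintf("%.17g", bounds))
  pl <- xml2::xml_add_child(mnode, "listOfParameters")
  for (b in seq_along(bounds)) {
    xml2::xml_add_child(pl, "parameter", id = sprintf("bnd_%d", b),
                        value = format(bounds[b], digits = 17,
                                       scientific = FALSE),
                        constant = "true")
  }
  rl <- xml2::xml_add_child(mnode, "listOfReactions")
  for (i in seq_len(nrow(model$rxns))) {
    r <- model$rxns[i, ]
    st <- model$stoich[[r$id]]
    rn <- xml2::xml_add_child(
      rl, "reaction", id = paste0("R_", sbml_encode_id(r$id)), name = r$name,
      reversible = tolower(as.character(r$lb < 0)), fast = "false",
      "fbc:lowerFluxBound" = bid[[sprintf("%.17g", r$lb)]],
      "fbc:upperFluxBound" = bid[[sprintf("%.17g", r$ub)]])
    rnotes <- xml2::xml_add_child(rn, "notes")
    rbody <- xml2::xml_add_child(rnotes, "body",
                                 xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(rbody, "p", sprintf("SUBSYSTEM: %s", r$subsystem))
    xml2::xml_add_child(rbody, "p", sprintf("KIND: %s", r$kind))
    subs <- st[st < 0]; prods <- st[st > 0]
    if (length(subs) > 0L) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in seq_along(subs)) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", sbml_encode_id(names(subs)[k])),
                            stoichiometry = format(-unname(subs[k]), digits = 17,
                                                   scientific = FALSE),
                            constant = "true")
      }
    }
    if (length(prods) > 0L) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in seq_along(prods)) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", sbml_encode_id(names(prods)[k])),
                            stoichiometry = format(unname(prods[k]), digits = 17,
                                                   scientific = FALSE),
                            constant = "true")
      }
    }
  }
  if (!is.na(model$biomass_id)) {
    ol <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(ol, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    fl <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(fl, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sbml_encode_id(model$biomass_id)),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
}

sbml_note_field <- function(node, key, ns) {
  ps <- xml2::xml_find_all(node, ".//d1:notes//*[local-name()='p']", ns)
  txt <- xml2::xml_text(ps)
  hit <- grep(paste0("^", key, ": "), txt, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(paste0("^", key, ": "), "", hit[1])
}

read_model_sbml <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  mnode <- xml2::xml_find_first(doc, "./d1:model", ns)
  params <- xml2::xml_find_all(mnode, "./d1:listOfParameters/d1:parameter", ns)
  pmap <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  sp <- xml2::xml_find_all(mnode, "./d1:listOfSpecies/d1:species", ns)
  mets <- data.frame(
    id = sbml_decode_id(sub("^M_", "", xml2::xml_attr(sp, "id"))),
    name = xml2::xml_attr(sp, "name"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    charge = as.numeric(xml2::xml_attr(sp, "charge")),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]
  rnodes <- xml2::xml_find_all(mnode, "./d1:listOfReactions/d1:reaction", ns)
  rid <- sbml_decode_id(sub("^R_", "", xml2::xml_attr(rnodes, "id")))
  if (anyDuplicated(rid)) {
    stop(sprintf("load error: duplicate reaction id(s): %s",
                 toString(unique(rid[duplicated(rid)]))), call. = FALSE)
  }
  stoich <- vector("list", length(rnodes))
  rxns <- data.frame(id = rid, name = character(length(rid)),
                     lb = numeric(length(rid)), ub = numeric(length(rid)),
                     subsystem = character(length(rid)),
                     kind = character(length(rid)), stringsAsFactors = FALSE)
  for (i in seq_along(rnodes)) {
    rn <- rnodes[[i]]
    rxns$name[i] <- xml2::xml_attr(rn, "name")
    rxns$lb[i] <- pmap[[xml2::xml_attr(rn, "lowerFluxBound")]]
    rxns$ub[i] <- pmap[[xml2::xml_attr(rn, "upperFluxBound")]]
    subsys <- sbml_note_field(rn, "SUBSYSTEM", ns)
    kind <- sbml_note_field(rn, "KIND", ns)
    rxns$subsystem[i] <- if (is.na(subsys)) "" else subsys
    rxns$kind[i] <- if (is.na(kind)) "internal" else kind
    st <- numeric(0)
    for (side in c(-1, 1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rn, sprintf("./d1:%s/d1:speciesReference", tag), ns)
      ids <- sbml_decode_id(sub("^M_", "", xml2::xml_attr(refs, "species")))
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      for (k in seq_along(ids)) {
        st[ids[k]] <- (if (ids[k] %in% names(st)) st[[ids[k]]] else 0) +
          side * coef[k]
      }
    }
    stoich[[i]] <- st[st != 0]
  }
  names(stoich) <- rid
  rxns$name[is.na(rxns$name)] <- rxns$id[is.na(rxns$name)]
  unresolved <- setdiff(unique(unlist(lapply(stoich, names))), mets$id)
  if (length(unresolved) > 0L) {
    stop(sprintf("load error: unresolved metabolite reference(s): %s",
                 toString(unresolved)), call. = FALSE)
  }
  fo <- xml2::xml_find_first(
    mnode, "./fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  biomass_id <- NA_character_
  if (!inherits(fo, "xml_missing")) {
    biomass_id <- sbml_decode_id(sub("^R_", "", xml2::xml_attr(fo, "reaction")))
  }
  metabolic_model(
    id = sbml_decode_id(xml2::xml_attr(mnode, "id")),
    mets = mets, rxns = rxns, stoich = stoich, biomass_id = biomass_id,
    taxonomy = list(species = sbml_note_field(mnode, "SPECIES", ns),
                    genus = sbml_note_field(mnode, "GENUS", ns),
                    phylum = sbml_note_field(mnode, "PHYLUM", ns)))
}
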