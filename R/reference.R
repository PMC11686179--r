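## SYNTHETIC stand-in for the published HMO utilization trait table and HMO
## reaction catalog. The real curation tables are not redistributable here, so
## this module reconstructs objects with the same published *marginal*
## structure -- 243 HMO-utilizing strains across 31 species, a catalog of 78
## reactions over 34 HMO/degradation-product metabolites (28 HMOs plus simple
## sugars), with Bifidobacterium longum subsp. infantis carrying the largest
## capability set -- while the cell-level content is generated: each HMO is a
## lactose-core glycan defined by its monosaccharide composition, so every
## hydrolysis reaction is mass- and charge-balanced by construction.
## Everything produced here is deterministic and labelled synthetic.

HMO_UNIT_FORMULAS <- c(gal = "C6H12O6", glc_D = "C6H12O6", fuc_L = "C6H12O5",
                       acgam = "C8H15NO6", acnam = "C11H19NO9")

# cofactors excluded when counting "HMO metabolites and degradation products"
CATALOG_COFACTORS <- c("h2o", "h", "atp", "adp", "pi")

# 28 HMOs as monosaccharide compositions beyond the lactose core
# (fuc = L-fucose, acgam = GlcNAc, acnam = Neu5Ac, gal = D-galactose).
hmo_compositions <- function() {
  list(
    `2fl`    = c(fuc_L = 1),
    `3fl`    = c(fuc_L = 1),
    dfl      = c(fuc_L = 2),
    `3sl`    = c(acnam = 1),
    `6sl`    = c(acnam = 1),
    lnt      = c(gal = 1, acgam = 1),
    lnnt     = c(gal = 1, acgam = 1),
    lnfp1    = c(fuc_L = 1, gal = 1, acgam = 1),
    lnfp2    = c(fuc_L = 1, gal = 1, acgam = 1),
    lnfp3    = c(fuc_L = 1, gal = 1, acgam = 1),
    lnfp5    = c(fuc_L = 1, gal = 1, acgam = 1),
    lnfp6    = c(fuc_L = 1, gal = 1, acgam = 1),
    lndfh1   = c(fuc_L = 2, gal = 1, acgam = 1),
    lndfh2   = c(fuc_L = 2, gal = 1, acgam = 1),
    lsta     = c(acnam = 1, gal = 1, acgam = 1),
    lstb     = c(acnam = 1, gal = 1, acgam = 1),
    lstc     = c(acnam = 1, gal = 1, acgam = 1),
    dslnt    = c(acnam = 2, gal = 1, acgam = 1),
    lnh      = c(gal = 2, acgam = 2),
    lnnh     = c(gal = 2, acgam = 2),
    mflnh1   = c(fuc_L = 1, gal = 2, acgam = 2),
    mflnh3   = c(fuc_L = 1, gal = 2, acgam = 2),
    dflnha   = c(fuc_L = 2, gal = 2, acgam = 2),
    dflnhb   = c(fuc_L = 2, gal = 2, acgam = 2),
    tflnh    = c(fuc_L = 3, gal = 2, acgam = 2),
    dslnh    = c(acnam = 2, gal = 2, acgam = 2),
    fdslnh   = c(fuc_L = 1, acnam = 2, gal = 2, acgam = 2),
    fslnh    = c(fuc_L = 1, acnam = 1, gal = 2, acgam = 2))
}

# HMOs degraded by extracellular hydrolysis (hydrolase in [e], full breakdown
# to monosaccharides); all others are internalized first.
HMO_EXTRACELLULAR <- c("lnt", "lnnt", "lnh", "lnnh", "lsta", "lstb")

hmo_formula <- function(extras) {
  counts <- parse_formula("C12H22O11") # lactose core
  for (u in names(extras)) {
    counts <- add_element_counts(counts, parse_formula(HMO_UNIT_FORMULAS[[u]]),
                                 extras[[u]])
  }
  # each attached unit releases one water on bond formation
  counts <- add_element_counts(counts, parse_formula("H2O"), -sum(extras))
  format_formula(counts)
}

#' Synthetic stand-in HMO reaction catalog
#'
#' Deterministically generates a catalog with the published marginal counts:
#' 78 reactions over 28 HMOs, whose metabolite set (HMOs plus degradation
#' products, cofactors excluded) has 34 members. 22 HMOs are internalized
#' (11 proton symport, 11 ABC) and then hydrolyzed intracellularly to the
#' lactose core plus their decorating units; 6 are hydrolyzed extracellularly
#' to monosaccharides. This object is synthetic: it mirrors structure and
#' counts, not the real curated content.
#'
#' @return An `hmo_catalog`.
#' @export
synthetic_reference_catalog <- function() {
  comps <- hmo_compositions()
  hmos <- names(comps)
  base <- data.frame(
    id = c(hmos, "lcts", names(HMO_UNIT_FORMULAS), "h2o", "h", "atp", "adp", "pi"),
    formula = c(vapply(comps, hmo_formula, character(1)), "C12H22O11",
                unname(HMO_UNIT_FORMULAS), "H2O", "H", "C10H12N5O13P3",
                "C10H12N5O10P2", "HO4P"),
    charge = c(rep(0, length(hmos)), 0, rep(0, length(HMO_UNIT_FORMULAS)),
               0, 1, -4, -3, -2),
    stringsAsFactors = FALSE)
  mets <- list(); rxns <- list(); routes <- list(); mech <- list()
  used <- character(0)
  need_met <- function(base_id, comp) {
    id <- sprintf("%s[%s]", base_id, comp)
    used <<- union(used, id)
    id
  }
  transported <- setdiff(hmos, HMO_EXTRACELLULAR)
  symport <- transported[seq_len(11)]
  for (h in hmos) {
    extras <- comps[[h]]
    ex_id <- sprintf("EX_%s(e)", h)
    rxns[[ex_id]] <- list(id = ex_id, eq = sprintf("1 %s ->", need_met(h, "e")),
                          lb = -1000, ub = 1000, kind = "exchange")
    route <- ex_id
    if (h %in% HMO_EXTRACELLULAR) {
      mech[[h]] <- "extracellular-hydrolysis"
      units <- c(extras, c(gal = 1, glc_D = 1)) # lactose core fully split
      units <- tapply(units, names(units), sum)
      lhs <- sprintf("1 %s + %d %s", need_met(h, "e"), sum(units) - 1,
                     need_met("h2o", "e"))
      rhs <- paste(sprintf("%d %s", unname(units),
                           vapply(names(units), need_met, character(1), "e")),
                   collapse = " + ")
      hy_id <- sprintf("%sHYDe", toupper(h))
      rxns[[hy_id]] <- list(id = hy_id, eq = paste(lhs, "->", rhs),
                            lb = 0, ub = 1000, kind = "internal")
      route <- c(route, hy_id)
    } else {
      t_id <- sprintf("%st", toupper(h))
      if (h %in% symport) {
        mech[[h]] <- "proton-symport"
        eq <- sprintf("1 %s + 1 %s -> 1 %s + 1 %s",
                      need_met(h, "e"), need_met("h", "e"),
                      need_met(h, "c"), need_met("h", "c"))
      } else {
        mech[[h]] <- "ABC"
        eq <- sprintf(
          "1 %s + 1 %s + 1 %s -> 1 %s + 1 %s + 1 %s + 1 %s",
          need_met(h, "e"), need_met("atp", "c"), need_met("h2o", "c"),
          need_met(h, "c"), need_met("adp", "c"), need_met("pi", "c"),
          need_met("h", "c"))
      }
      rxns[[t_id]] <- list(id = t_id, eq = eq, lb = 0, ub = 1000,
                           kind = "transport")
      hy_id <- sprintf("%sHYD", toupper(h))
      lhs <- sprintf("1 %s + %d %s", need_met(h, "c"), sum(extras),
                     need_met("h2o", "c"))
      rhs <- paste(c(sprintf("1 %s", need_met("lcts", "c")),
                     sprintf("%d %s", unname(extras),
                             vapply(names(extras), need_met, character(1), "c"))),
                   collapse = " + ")
      rxns[[hy_id]] <- list(id = hy_id, eq = paste(lhs, "->", rhs),
                            lb = 0, ub = 1000, kind = "internal")
      route <- c(route, t_id, hy_id)
    }
    routes[[h]] <- data.frame(hmo = h, reaction_id = route,
                              stringsAsFactors = FALSE)
  }
  rx_df <- do.call(rbind, lapply(rxns, function(r) {
    data.frame(id = r$id, name = r$id, equation = r$eq, lb = r$lb, ub = r$ub,
               subsystem = "HMO degradation", kind = r$kind,
               stringsAsFactors = FALSE)
  }))
  rownames(rx_df) <- NULL
  met_df <- data.frame(
    id = sort(used),
    name = paste(met_base(sort(used)), "(synthetic stand-in)"),
    formula = base$formula[match(met_base(sort(used)), base$id)],
    charge = base$charge[match(met_base(sort(used)), base$id)],
    compartment = met_compartment(sort(used)), stringsAsFactors = FALSE)
  stoich <- lapply(rx_df$equation, parse_equation)
  names(stoich) <- rx_df$id
  cat <- structure(list(
    mets = met_df,
    rxns = rx_df[c("id", "name", "lb", "ub", "subsystem", "kind")],
    stoich = stoich,
    routes = do.call(rbind, routes),
    catabolism = data.frame(product = character(0),
                            reaction_id = character(0)),
    mechanisms = data.frame(hmo = names(mech),
                            mechanism = unlist(mech, use.names = FALSE),
                            stringsAsFactors = FALSE)),
    class = "hmo_catalog")
  rownames(cat$routes) <- NULL
  validate_catalog(cat)
  cat
}

#' Count the HMO/degradation-product metabolites of a catalog
#'
#' Unique base metabolites (compartment-stripped), excluding ubiquitous
#' cofactors (water, protons, ATP/ADP/phosphate).
#' @param catalog An `hmo_catalog`.
#' @return Integer count.
#' @export
catalog_metabolite_count <- function(catalog) {
  length(setdiff(unique(met_base(catalog$mets$id)), CATALOG_COFACTORS))
}

reference_species_table <- function() {
  spec <- function(species, phylum, strains, capabilities) {
    data.frame(species = species, phylum = phylum, strains = strains,
               capabilities = capabilities, stringsAsFactors = FALSE)
  }
  tbl <- rbind(
    spec("Bifidobacterium longum subsp. infantis", "Actinobacteria", 12, 28),
    spec("Bifidobacterium bifidum", "Actinobacteria", 18, 24),
    spec("Bifidobacterium breve", "Actinobacteria", 25, 20),
    spec("Bifidobacterium longum subsp. longum", "Actinobacteria", 20, 16),
    spec("Bifidobacterium pseudocatenulatum", "Actinobacteria", 10, 12),
    spec("Bifidobacterium dentium", "Actinobacteria", 4, 4),
    spec("Bifidobacterium adolescentis", "Actinobacteria", 8, 5),
    spec("Bifidobacterium catenulatum", "Actinobacteria", 6, 6),
    spec("Bifidobacterium animalis subsp. lactis", "Actinobacteria", 10, 3),
    spec("Bifidobacterium pseudolongum", "Actinobacteria", 3, 2),
    spec("Bacteroides fragilis", "Bacteroidetes", 12, 14),
    spec("Bacteroides thetaiotaomicron", "Bacteroidetes", 10, 12),
    spec("Phocaeicola vulgatus", "Bacteroidetes", 10, 10),
    spec("Bacteroides caccae", "Bacteroidetes", 4, 6),
    spec("Bacteroides ovatus", "Bacteroidetes", 6, 8),
    spec("Bacteroides dorei", "Bacteroidetes", 5, 5),
    spec("Bacteroides uniformis", "Bacteroidetes", 6, 4),
    spec("Lacticaseibacillus casei", "Firmicutes", 8, 3),
    spec("Lactobacillus acidophilus", "Firmicutes", 6, 2),
    spec("Limosilactobacillus fermentum", "Firmicutes", 5, 2),
    spec("Lacticaseibacillus rhamnosus", "Firmicutes", 7, 3),
    spec("Lactiplantibacillus plantarum", "Firmicutes", 6, 2),
    spec("Ligilactobacillus salivarius", "Firmicutes", 4, 1),
    spec("Roseburia intestinalis", "Firmicutes", 3, 2),
    spec("Roseburia inulinivorans", "Firmicutes", 2, 2),
    spec("Ruminococcus gnavus", "Firmicutes", 6, 4),
    spec("Clostridium perfringens", "Firmicutes", 8, 3),
    spec("Enterococcus faecalis", "Firmicutes", 7, 1),
    spec("Streptococcus thermophilus", "Firmicutes", 6, 1),
    spec("Veillonella parvula", "Firmicutes", 3, 1),
    spec("Akkermansia muciniphila", "Verrucomicrobia", 3, 9))
  stopifnot(sum(tbl$strains) == 243L, nrow(tbl) == 31L)
  tbl
}

#' Synthetic stand-in strain x HMO trait table
#'
#' 243 strains from 31 species; each species degrades the first k HMOs of the
#' catalog's fixed order, with *B. longum* subsp. *infantis* carrying all 28
#' (the published maximal capability). Cell content is synthetic.
#'
#' @return An `hmo_traits` object.
#' @export
synthetic_reference_traits <- function() {
  tbl <- reference_species_table()
  hmos <- names(hmo_compositions())
  rows <- list()
  for (i in seq_len(nrow(tbl))) {
    abbrev <- tolower(gsub("[^A-Za-z]+", "_", tbl$species[i]))
    for (s in seq_len(tbl$strains[i])) {
      rows[[length(rows) + 1L]] <- data.frame(
        strain_id = sprintf("%s_%02d", abbrev, s),
        species = tbl$species[i], phylum = tbl$phylum[i],
        capabilities = tbl$capabilities[i], stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  traits <- matrix(FALSE, nrow = nrow(meta), ncol = length(hmos),
                   dimnames = list(meta$strain_id, hmos))
  for (r in seq_len(nrow(meta))) {
    traits[r, seq_len(meta$capabilities[r])] <- TRUE
  }
  refs <- matrix("", nrow = nrow(meta), ncol = length(hmos),
                 dimnames = dimnames(traits))
  refs[traits] <- "synthetic stand-in (no literature citation)"
  structure(list(meta = meta[c("strain_id", "species", "phylum")],
                 traits = traits, refs = refs),
            class = "hmo_traits")
}
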