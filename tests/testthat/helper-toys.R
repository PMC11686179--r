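# Shared toy fixtures, built in code.

# lactose fermenter: biomass 0.1 lcts -> bio, fermentation 1 lcts -> 4 lac
make_lactate_toy <- function(id = "Toyus unus") {
  mets <- metabolites(c("lcts[e]", "lcts[c]", "lac_L[e]", "lac_L[c]", "bio[c]"),
                      formula = c("C12H22O11", "C12H22O11", "C3H5O3", "C3H5O3", "X"),
                      charge = c(0, 0, -1, -1, 0))
  rs <- reactions(
    id = c("EX_lcts(e)", "LCTSt", "BIO", "FERM", "LACt", "EX_lac_L(e)"),
    equation = c("1 lcts[e] ->", "1 lcts[e] -> 1 lcts[c]",
                 "0.1 lcts[c] -> 1 bio[c]", "1 lcts[c] -> 4 lac_L[c]",
                 "1 lac_L[c] -> 1 lac_L[e]", "1 lac_L[e] ->"),
    lb = c(-1000, 0, 0, 0, -1000, -1000), ub = 1000,
    subsystem = c("Exchange", "Transport", "Biomass", "Fermentation",
                  "Transport", "Exchange"),
    kind = c("exchange", "transport", "biomass", "internal", "transport",
             "exchange"))
  metabolic_model(id, mets, rs$rxns, rs$stoich, biomass_id = "BIO",
                  taxonomy = list(species = id, genus = "Toyus",
                                  phylum = "Firmicutes"))
}

# lactate-to-butyrate cross-feeder (1 lac -> 1 but, deliberately toy)
make_butyrate_toy <- function(id = "Toyus duo") {
  mets <- metabolites(c("lac_L[e]", "lac_L[c]", "but[e]", "but[c]", "bio[c]"),
                      formula = c("C3H5O3", "C3H5O3", "C4H7O2", "C4H7O2", "X"),
                      charge = c(-1, -1, -1, -1, 0))
  rs <- reactions(
    id = c("EX_lac_L(e)", "LACt", "BIO", "BUTS", "BUTt", "EX_but(e)"),
    equation = c("1 lac_L[e] ->", "1 lac_L[e] -> 1 lac_L[c]",
                 "0.1 lac_L[c] -> 1 bio[c]", "1 lac_L[c] -> 1 but[c]",
                 "1 but[c] -> 1 but[e]", "1 but[e] ->"),
    lb = c(-1000, 0, 0, 0, -1000, -1000), ub = 1000,
    subsystem = c("Exchange", "Transport", "Biomass", "Butyrate synthesis",
                  "Transport", "Exchange"),
    kind = c("exchange", "transport", "biomass", "internal", "transport",
             "exchange"))
  metabolic_model(id, mets, rs$rxns, rs$stoich, biomass_id = "BIO",
                  taxonomy = list(species = id, genus = "Toyus",
                                  phylum = "Firmicutes"))
}

# random toy model (for round-trip / pan-model property tests)
make_random_model <- function(seed, id = sprintf("rand_%d", seed)) {
  set.seed(seed)
  n_met <- sample(3:6, 1)
  base <- paste0("m", seq_len(n_met))
  formulas <- sprintf("C%dH%dO%d", sample(1:12, n_met, TRUE),
                      sample(1:20, n_met, TRUE), sample(1:10, n_met, TRUE))
  mets <- metabolites(c(paste0(base, "[c]"), paste0(base[1], "[e]"), "bio[c]"),
                      formula = c(formulas, formulas[1], "X"),
                      charge = c(sample(-2:2, n_met, TRUE), 0, 0))
  n_rxn <- sample(2:4, 1)
  ids <- paste0("R", seq_len(n_rxn))
  eqs <- vapply(seq_len(n_rxn), function(k) {
    pair <- sample(base, 2)
    sprintf("%d %s[c] -> %d %s[c]", sample(1:3, 1), pair[1],
            sample(1:3, 1), pair[2])
  }, character(1))
  rs <- reactions(
    id = c("EX_m1(e)", "M1t", ids, "BIO"),
    equation = c(sprintf("1 %s[e] ->", base[1]),
                 sprintf("1 %s[e] -> 1 %s[c]", base[1], base[1]),
                 eqs, sprintf("0.5 %s[c] -> 1 bio[c]", base[1])),
    lb = c(-1000, -1000, round(stats::runif(n_rxn, -100, 0), 3), 0),
    ub = c(1000, 1000, round(stats::runif(n_rxn, 1, 100), 3), 1000),
    subsystem = sample(c("S1", "S2"), n_rxn + 3, TRUE),
    kind = c("exchange", "transport", rep("internal", n_rxn), "biomass"))
  metabolic_model(id, mets, rs$rxns, rs$stoich, biomass_id = "BIO",
                  taxonomy = list(species = id, genus = "Randomus",
                                  phylum = "Testota"))
}

# shared reaction pool for pan-model property tests: strains draw random
# subsets with random bounds, so shared ids always agree on stoichiometry
reaction_pool <- function(n_pool = 10) {
  base <- paste0("p", 1:6)
  mets <- metabolites(c(paste0(base, "[c]"), paste0(base[1], "[e]"), "bio[c]"),
                      formula = c(rep("C2H4O2", 6), "C2H4O2", "X"))
  pool_eqs <- c("1 p1[e] ->", "1 p1[e] -> 1 p1[c]",
                vapply(seq_len(n_pool - 2), function(k) {
                  i <- (k %% 6) + 1; j <- ((k + 2) %% 6) + 1
                  sprintf("1 p%d[c] -> 1 p%d[c]", i, j)
                }, character(1)))
  ids <- c("EX_p1(e)", "P1t", paste0("PR", seq_len(n_pool - 2)))
  kinds <- c("exchange", "transport", rep("internal", n_pool - 2))
  list(ids = ids, eqs = pool_eqs, kinds = kinds, mets = mets)
}

make_pool_strain <- function(seed, pool, id = sprintf("pool_%d", seed)) {
  set.seed(seed)
  keep <- sort(unique(c(1:2, sample(3:length(pool$ids),
                                    sample(2:(length(pool$ids) - 2), 1)))))
  lb <- round(stats::runif(length(keep), -100, 0), 2)
  ub <- round(stats::runif(length(keep), 1, 100), 2)
  rs <- reactions(id = pool$ids[keep], equation = pool$eqs[keep],
                  lb = lb, ub = ub, kind = pool$kinds[keep])
  rs$rxns$lb[1:2] <- -1000; rs$rxns$ub[1:2] <- 1000
  bio <- reactions("BIO", "0.5 p1[c] -> 1 bio[c]", lb = 0, ub = 1000,
                   kind = "biomass")
  metabolic_model(id, pool$mets, rbind(rs$rxns, bio$rxns),
                  c(rs$stoich, bio$stoich), biomass_id = "BIO",
                  taxonomy = list(species = "Poolus sp", genus = "Poolus",
                                  phylum = "Testota"))
}

# minimal 3-reaction 2'-FL route catalog used by the expansion examples
make_mini_catalog <- function(include_fuc_template = TRUE) {
  ids <- c("EX_fuclac(e)", "FUCLACt", "FUCLAChyd")
  eqs <- c("1 fuclac[e] ->",
           "1 fuclac[e] -> 1 fuclac[c]",
           "1 fuclac[c] + 1 h2o[c] -> 1 fuc_L[c] + 1 lcts[c]")
  kinds <- c("exchange", "transport", "internal")
  catab <- data.frame(product = character(0), reaction_id = character(0),
                      stringsAsFactors = FALSE)
  if (include_fuc_template) {
    ids <- c(ids, "FUCt", "EX_fuc_L(e)")
    eqs <- c(eqs, "1 fuc_L[c] -> 1 fuc_L[e]", "1 fuc_L[e] ->")
    kinds <- c(kinds, "transport", "exchange")
    catab <- data.frame(product = "fuc_L",
                        reaction_id = c("FUCt", "EX_fuc_L(e)"),
                        stringsAsFactors = FALSE)
  }
  rs <- reactions(id = ids, equation = eqs,
                  lb = ifelse(kinds == "exchange", -1000, 0), ub = 1000,
                  subsystem = "HMO degradation", kind = kinds)
  mets <- data.frame(
    id = c("fuclac[e]", "fuclac[c]", "fuc_L[c]", "fuc_L[e]", "lcts[c]",
           "h2o[c]"),
    name = "toy", formula = c("C18H32O15", "C18H32O15", "C6H12O5", "C6H12O5",
                              "C12H22O11", "H2O"),
    charge = 0, compartment = c("e", "c", "c", "e", "c", "c"),
    stringsAsFactors = FALSE)
  mets <- mets[mets$id %in% unique(unlist(lapply(rs$stoich, names))), ]
  structure(list(
    mets = mets, rxns = rs$rxns, stoich = rs$stoich,
    routes = data.frame(hmo = "fuclac", reaction_id = c("EX_fuclac(e)",
                                                        "FUCLACt", "FUCLAChyd"),
                        stringsAsFactors = FALSE),
    catabolism = catab,
    mechanisms = data.frame(hmo = "fuclac", mechanism = "proton-symport",
                            stringsAsFactors = FALSE)),
    class = "hmo_catalog")
}

# host model for expansion tests: grows on lactose, no HMO machinery;
# glucose transport is reversible so surplus sugar can leave the cell
make_host_model <- function(id = "Host") {
  mets <- metabolites(
    c("lcts[e]", "lcts[c]", "glc_D[c]", "glc_D[e]", "gal[c]", "gal[e]",
      "h2o[e]", "h2o[c]", "bio[c]"),
    formula = c("C12H22O11", "C12H22O11", "C6H12O6", "C6H12O6", "C6H12O6",
                "C6H12O6", "H2O", "H2O", "X"))
  rs <- reactions(
    id = c("EX_lcts(e)", "LCTSt", "LACZ", "GLCt", "EX_glc_D(e)", "GALt",
           "EX_gal(e)", "H2Ot", "EX_h2o(e)", "BIO"),
    equation = c("1 lcts[e] ->", "1 lcts[e] -> 1 lcts[c]",
                 "1 lcts[c] + 1 h2o[c] -> 1 glc_D[c] + 1 gal[c]",
                 "1 glc_D[e] -> 1 glc_D[c]", "1 glc_D[e] ->",
                 "1 gal[c] -> 1 gal[e]", "1 gal[e] ->",
                 "1 h2o[e] -> 1 h2o[c]", "1 h2o[e] ->",
                 "0.1 glc_D[c] -> 1 bio[c]"),
    lb = c(-1000, 0, 0, -1000, -1000, -1000, -1000, -1000, -1000, 0),
    ub = 1000,
    kind = c("exchange", "transport", "internal", "transport", "exchange",
             "transport", "exchange", "transport", "exchange", "biomass"))
  metabolic_model(id, mets, rs$rxns, rs$stoich, biomass_id = "BIO",
                  taxonomy = list(species = id, genus = "Hostus",
                                  phylum = "Firmicutes"))
}

# metabolite db for the worked balance examples
balance_example_db <- function() {
  metabolites(
    c("lcts[c]", "h2o[c]", "glc_D[c]", "gal[c]", "lac_L[c]", "h[c]"),
    formula = c("C12H22O11", "H2O", "C6H12O6", "C6H12O6", "C3H5O3", "H"),
    charge = c(0, 0, 0, 0, -1, 1))
}
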