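test_that("match_taxa normalizes names and reports the unmatched", {
  registry <- c("Bifidobacterium longum", "Ruminococcus gnavus",
                "Bacteroides fragilis subsp. fragilis")
  tm <- match_taxa(c("Bifidobacterium_longum", "Escherichia coli",
                     "[Ruminococcus] gnavus",
                     "Bacteroides fragilis subspecies fragilis"), registry)
  expect_identical(tm$mapping$model_id[tm$mapping$input == "Bifidobacterium_longum"],
                   "Bifidobacterium longum")
  expect_identical(tm$mapping$model_id[tm$mapping$input == "[Ruminococcus] gnavus"],
                   "Ruminococcus gnavus")
  expect_identical(tm$mapping$model_id[tm$mapping$input == "Bacteroides fragilis subspecies fragilis"],
                   "Bacteroides fragilis subsp. fragilis")
  expect_identical(tm$unmatched, "Escherichia coli")
  # ambiguity: two inputs collapsing onto one registry id
  expect_error(match_taxa(c("Sp one", "sp_one"), "Sp one"), "ambiguous")
})

test_that("normalize_abundances filters, renormalizes, and flags empty samples", {
  m <- matrix(c(30, 10, 0.9999, 0.00005), nrow = 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  out <- normalize_abundances(m, cutoff = 1e-4)
  expect_equal(out[, "s1"], c(A = 0.75, B = 0.25))
  expect_equal(out[, "s2"], c(A = 1, B = 0))
  expect_equal(colSums(out), c(s1 = 1, s2 = 1))
  # all entries below cutoff
  m2 <- matrix(c(1e-6, 2e-6), nrow = 2, dimnames = list(c("A", "B"), "s1"))
  expect_error(normalize_abundances(m2, cutoff = 1e-4), "s1")
  # unclassified rows dropped
  m3 <- matrix(c(0.5, 0.5), nrow = 2,
               dimnames = list(c("unclassified", "A"), "s1"))
  out3 <- normalize_abundances(m3)
  expect_identical(rownames(out3), "A")
  expect_equal(out3["A", "s1"], 1)
})

test_that("build_pan_model takes exact unions, envelopes, and merged biomass", {
  s1 <- make_lactate_toy("Toyus unus")
  # single strain: structurally identical up to the biomass rename
  pan1 <- build_pan_model(list(s1))
  expect_setequal(pan1$rxns$id,
                  c(setdiff(s1$rxns$id, "BIO"), "biomassPan"))
  expect_equal(pan1$stoich$biomassPan, s1$stoich$BIO)
  for (rid in setdiff(s1$rxns$id, "BIO")) {
    expect_equal(pan1$stoich[[rid]], s1$stoich[[rid]])
  }
  # union + envelope
  s2 <- s1
  s2$id <- "strain2"
  s2 <- add_reactions(s2, reactions("EXTRA", "1 lac_L[c] -> 1 lac_L[e]",
                                    lb = 0, ub = 50, kind = "transport"))$model
  i <- match("FERM", s2$rxns$id)
  s2$rxns$lb[i] <- -5
  s2$rxns$ub[i] <- 5
  pan <- build_pan_model(list(s1, s2))
  expect_setequal(pan$rxns$id, c(setdiff(s1$rxns$id, "BIO"), "EXTRA",
                                 "biomassPan"))
  j <- match("FERM", pan$rxns$id)
  expect_equal(c(pan$rxns$lb[j], pan$rxns$ub[j]), c(-5, 1000))
  # merged biomass coefficients averaged over containing strains
  s3 <- s1
  s3$id <- "strain3"
  s3$stoich$BIO <- c(`lcts[c]` = -0.3, `bio[c]` = 1)
  pan2 <- build_pan_model(list(s1, s3))
  expect_equal(pan2$stoich$biomassPan[["lcts[c]"]], -0.2)
  # conflicting stoichiometry for a shared id
  s4 <- s1
  s4$id <- "strain4"
  s4$stoich$FERM <- c(`lcts[c]` = -1, `lac_L[c]` = 3)
  expect_error(build_pan_model(list(s1, s4)), "conflicting stoichiometry")
})

test_that("pan-model reaction sets equal the union on random strain pairs", {
  pool <- reaction_pool()
  for (k in 1:10) {
    a <- make_pool_strain(100 + k, pool, "strainA")
    b <- make_pool_strain(200 + k, pool, "strainB")
    pan <- build_pan_model(list(a, b))
    expect_setequal(pan$rxns$id,
                    union(setdiff(a$rxns$id, "BIO"),
                          c(setdiff(b$rxns$id, "BIO"), "biomassPan")))
    shared <- intersect(setdiff(a$rxns$id, "BIO"), setdiff(b$rxns$id, "BIO"))
    for (rid in shared) {
      ia <- match(rid, a$rxns$id); ib <- match(rid, b$rxns$id)
      ip <- match(rid, pan$rxns$id)
      expect_equal(pan$rxns$lb[ip], min(a$rxns$lb[ia], b$rxns$lb[ib]))
      expect_equal(pan$rxns$ub[ip], max(a$rxns$ub[ia], b$rxns$ub[ib]))
    }
  }
})

test_that("assemble_community builds the documented reaction complement", {
  # single species, 4 reactions, 2 extracellular metabolites -> 15 reactions
  mets <- metabolites(c("a[e]", "a[c]", "b[e]", "bio[c]"),
                      formula = c("C2H4", "C2H4", "C2H4", "X"))
  rs <- reactions(id = c("EX_a(e)", "EX_b(e)", "CONV", "BIO"),
                  equation = c("1 a[e] ->", "1 b[e] ->", "1 a[c] -> 1 b[e]",
                               "0.1 a[c] -> 1 bio[c]"),
                  lb = c(-1000, -1000, 0, 0), ub = 1000,
                  kind = c("exchange", "exchange", "internal", "biomass"))
  sp <- metabolic_model("S", mets, rs$rxns, rs$stoich, biomass_id = "BIO",
                        taxonomy = list(species = "S", genus = "G", phylum = "P"))
  comm <- assemble_community(list(S = build_pan_model(list(sp))), c(S = 1))
  expect_identical(nrow(comm$model$rxns), 15L)
  # closed form: tagged non-exchange + IEX + 4 per lumen met + 3 biomass path
  n_exch <- 2; n_rxn <- 4
  expect_identical(nrow(comm$model$rxns),
                   as.integer(n_rxn + 4 * n_exch + 3))
  # chain naming
  expect_true(all(c("Diet_EX_a[d]", "DUt_a", "UFEt_a", "EX_a[fe]",
                    "S_IEX_a[u]", "communityBiomass",
                    "EX_microbeBiomass[fe]") %in% comm$model$rxns$id))
})

test_that("community biomass uses abundances as stoichiometric coefficients", {
  p1 <- build_pan_model(list(make_lactate_toy("Sp A")))
  p2 <- build_pan_model(list(make_butyrate_toy("Sp B")))
  comm <- assemble_community(list(`Sp A` = p1, `Sp B` = p2),
                             c(`Sp A` = 0.6, `Sp B` = 0.4))
  cb <- comm$model$stoich$communityBiomass
  expect_equal(cb[["Sp_A_bio[c]"]], -0.6)
  expect_equal(cb[["Sp_B_bio[c]"]], -0.4)
  expect_equal(cb[["microbeBiomass[u]"]], 1)
  expect_error(assemble_community(list(`Sp A` = p1), c(`Sp A` = 0.6)),
               "normalized")
  expect_error(assemble_community(list(`Sp A` = p1),
                                  c(`Sp A` = 0.5, Ghost = 0.5)), "Ghost")
})

test_that("at abundance 1 the community growth equals the species biomass flux", {
  pan <- build_pan_model(list(make_lactate_toy()))
  comm <- assemble_community(stats::setNames(list(pan), "Toyus unus"),
                             c("Toyus unus" = 1),
                             config = community_config(growth_lb = 0.7,
                                                       growth_ub = 0.7))
  comm <- apply_diet(comm, c(lcts = 10))
  # maximal and minimal species biomass flux both equal the fixed growth
  hi <- solve_lp(babybiome:::community_lp(comm, c(Toyus_unus_biomassPan = 1)))
  expect_equal(hi$objective, 0.7, tolerance = 1e-6)
  lo <- babybiome:::community_lp(comm, c(Toyus_unus_biomassPan = 1))
  lo$maximize <- FALSE
  expect_equal(solve_lp(lo)$objective, 0.7, tolerance = 1e-6)
})

test_that("huge coupling factors relax to the uncoupled community", {
  p1 <- build_pan_model(list(make_lactate_toy("Sp A")))
  p2 <- build_pan_model(list(make_butyrate_toy("Sp B")))
  pans <- list(`Sp A` = p1, `Sp B` = p2)
  ab <- c(`Sp A` = 0.5, `Sp B` = 0.5)
  loose <- assemble_community(pans, ab, config = community_config(
    coupling_factor = 1e7, growth_lb = 0, growth_ub = 1))
  free <- assemble_community(pans, ab, config = community_config(
    couple = FALSE, growth_lb = 0, growth_ub = 1))
  for (comm in list(loose, free)) comm
  loose <- apply_diet(loose, c(lcts = 10))
  free <- apply_diet(free, c(lcts = 10))
  for (m in c("but", "lac_L")) {
    obj <- stats::setNames(c(1, 1), c(sprintf("EX_%s[fe]", m),
                                      sprintf("Diet_EX_%s[d]", m)))
    a <- solve_lp(babybiome:::community_lp(loose, obj))$objective
    b <- solve_lp(babybiome:::community_lp(free, obj))$objective
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("lumen steady state holds: random objectives keep diet+production = consumption+fecal", {
  # feasibility of the LP at optimum already implies S v = 0; verify that the
  # fecal outflow of lactate can never exceed 4x the lactose inflow
  pan <- build_pan_model(list(make_lactate_toy()))
  comm <- assemble_community(stats::setNames(list(pan), "Toyus unus"),
                             c("Toyus unus" = 1),
                             config = community_config(growth_lb = 0,
                                                       growth_ub = 1))
  set.seed(7)
  for (cap in c(1, 5, 20)) {
    comm2 <- apply_diet(comm, c(lcts = cap))
    res <- solve_lp(babybiome:::community_lp(comm2, c(`EX_lac_L[fe]` = 1)))
    expect_lte(res$objective, 4 * cap + 1e-9)
  }
})
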