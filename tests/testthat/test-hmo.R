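write_toy_traits <- function(path, empty = FALSE) {
  df <- data.frame(
    strain_id = c("A", "B", "C"), species = c("Sp a", "Sp b", "Sp c"),
    phylum = "Firmicutes",
    fuclac = c(TRUE, TRUE, FALSE), lnt = c(TRUE, FALSE, TRUE),
    ref_fuclac = c("doi:1", "doi:2", ""), ref_lnt = c("doi:3", "", "doi:4"),
    stringsAsFactors = FALSE)
  if (empty) {
    df$fuclac <- FALSE; df$lnt <- FALSE
    df$ref_fuclac <- ""; df$ref_lnt <- ""
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("load_trait_table parses strictly and enforces references", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_toy_traits(f)
  tr <- load_trait_table(f)
  expect_identical(sum(tr$traits), 4L)
  expect_identical(dim(tr$traits), c(3L, 2L))
  # empty table is valid with zero capabilities
  write_toy_traits(f, empty = TRUE)
  expect_identical(sum(load_trait_table(f)$traits), 0L)
  # non-boolean cell
  df <- read.delim(f)
  df$fuclac[1] <- "yes"
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_trait_table(f), "non-boolean")
  # TRUE cell without a reference
  write_toy_traits(f)
  df <- read.delim(f)
  df$ref_fuclac[1] <- ""
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_trait_table(f), "without a reference")
})

test_that("load_catalog balance-validates on load", {
  cat <- make_mini_catalog()
  d <- withr::local_tempdir()
  write_catalog(cat, d)
  expect_s3_class(load_catalog(d), "hmo_catalog")
  # inject the unbalanced glucose -> 2 lactate reaction
  rx <- read.delim(file.path(d, "reactions.tsv"))
  rx <- rbind(rx, data.frame(id = "BADLDH", name = "BADLDH",
                             equation = "1 glc_D[c] -> 2 lac_L[c]",
                             lb = 0, ub = 1000, subsystem = "x",
                             kind = "internal"))
  write.table(rx, file.path(d, "reactions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  mets <- read.delim(file.path(d, "metabolites.tsv"))
  mets <- rbind(mets, data.frame(id = c("glc_D[c]", "lac_L[c]"), name = "x",
                                 formula = c("C6H12O6", "C3H5O3"),
                                 charge = c(0, -1), compartment = "c"))
  write.table(mets, file.path(d, "metabolites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_catalog(d), "BADLDH.*unbalanced")
})

test_that("expand_model injects routes, skips present reactions, is idempotent", {
  host <- make_host_model()
  catalog <- make_mini_catalog()
  tr <- c(fuclac = TRUE)
  ex <- expand_model(host, tr, catalog)
  # 3 route reactions + 2 gap-filled export reactions for the fucose dead end
  expect_identical(sort(ex$report$reactions_added),
                   sort(c("EX_fuclac(e)", "FUCLACt", "FUCLAChyd", "FUCt",
                          "EX_fuc_L(e)")))
  expect_identical(ex$report$n_added, 5L)
  expect_true(ex$report$feasible[["fuclac"]])
  # idempotence
  ex2 <- expand_model(ex$model, tr, catalog)
  expect_identical(ex2$report$n_added, 0L)
  # transporter already present -> only the remainder is inserted
  host2 <- add_reactions(host, babybiome:::catalog_subset(catalog, c("EX_fuclac(e)", "FUCLACt")))$model
  ex3 <- expand_model(host2, tr, catalog)
  expect_false("FUCLACt" %in% ex3$report$reactions_added)
  expect_true("FUCLAChyd" %in% ex3$report$reactions_added)
  # HMO flagged but absent from catalog
  expect_error(expand_model(host, c(mystery_hmo = TRUE), catalog),
               "mystery_hmo")
})

test_that("expansion with a 3-reaction route and no dead end adds exactly 3", {
  host <- make_host_model()
  # give the host innate fucose catabolism so no gap-filling is needed
  host <- add_reactions(host, local({
    rs <- reactions(c("FCLiso", "EX_fucbig(e)"),
                    c("1 fuc_L[c] -> 1 fuc_iso[c]", "1 fuc_iso[e] ->"),
                    lb = c(0, -1000), ub = 1000,
                    kind = c("internal", "exchange"))
    rs2 <- reactions("FUCISOt", "1 fuc_iso[c] -> 1 fuc_iso[e]",
                     lb = 0, ub = 1000, kind = "transport")
    out <- list(rxns = rbind(rs$rxns, rs2$rxns),
                stoich = c(rs$stoich, rs2$stoich))
    out$mets <- metabolites(c("fuc_L[c]", "fuc_iso[c]", "fuc_iso[e]"),
                            formula = "C6H12O5")
    out
  }))$model
  catalog <- make_mini_catalog(include_fuc_template = FALSE)
  ex <- expand_model(host, c(fuclac = TRUE), catalog)
  expect_identical(ex$report$n_added, 3L)
  expect_length(ex$report$gapfilled, 0)
})

test_that("gapfill_degradation repairs dead ends and reports unfixable ones", {
  host <- make_host_model()
  catalog <- make_mini_catalog()
  host <- add_reactions(host, babybiome:::catalog_subset(
    catalog, c("EX_fuclac(e)", "FUCLACt", "FUCLAChyd")))$model
  gf <- gapfill_degradation(host, "fuclac", catalog)
  expect_identical(sort(gf$added), c("EX_fuc_L(e)", "FUCt"))
  # model already consuming all products: nothing added
  gf2 <- gapfill_degradation(gf$model, "fuclac", catalog)
  expect_length(gf2$added, 0)
  # catalog stripped of the fucose template: infeasibility names fuc_L
  stripped <- make_mini_catalog(include_fuc_template = FALSE)
  expect_error(gapfill_degradation(host, "fuclac", stripped), "fuc_L")
  # route must be present
  expect_error(gapfill_degradation(make_host_model(), "fuclac", catalog),
               "lacks the uptake route")
})

test_that("coverage_matrix orders rows and counts per-strain capabilities", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_toy_traits(f)
  tr <- load_trait_table(f)
  cm <- coverage_matrix(tr)
  expect_identical(cm$counts[c("A", "B", "C")], c(A = 2, B = 1, C = 1))
  expect_true(all(cm$matrix %in% 0:1))
  # empty table -> empty counts
  write_toy_traits(f, empty = TRUE)
  cm0 <- coverage_matrix(load_trait_table(f))
  expect_identical(unname(cm0$counts), rep(0, 3))
})

test_that("post-expansion every trait-enabled HMO carries uptake flux and the model grows monotonically", {
  u <- generate_universe(check_growth = FALSE)
  degraders <- u$taxonomy$species[u$taxonomy$guild == "hmo_degrader"]
  for (sp in degraders) {
    before <- u$models[[sp]]
    ex <- expand_model(before, u$traits$traits[sp, ], u$catalog)
    expect_true(all(ex$report$feasible))
    # monotone growth: no reaction removed
    expect_true(all(before$rxns$id %in% ex$model$rxns$id))
    # every inserted reaction is balance-clean or exempt
    rep <- check_model_balance(ex$model)
    expect_true(all(rep$verdict %in% c("balanced", "exempt")))
  }
})
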