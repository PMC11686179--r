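test_that("parse_formula reads Hill-notation formulas exactly", {
  cases <- list(
    list("C6H12O6", c(C = 6L, H = 12L, O = 6L)),
    list("C12H22O11", c(C = 12L, H = 22L, O = 11L)),
    list("C3H5O3", c(C = 3L, H = 5L, O = 3L)),
    list("H", c(H = 1L)),
    list("C10H12N5O13P3", c(C = 10L, H = 12L, N = 5L, O = 13L, P = 3L)),
    list("CR2X", c(C = 1L, R = 2L, X = 1L)), # pseudo-elements
    list("CHCH", c(C = 2L, H = 2L)))         # repeated symbols accumulate
  for (cs in cases) {
    expect_identical(parse_formula(cs[[1]])[names(cs[[2]])], cs[[2]])
  }
  expect_error(parse_formula("C6h"), "position 3")
  expect_error(parse_formula("6C"), "position 1")
  expect_error(parse_formula(""), "non-empty")
})

test_that("check_balance reproduces the hand-summed worked examples", {
  db <- balance_example_db()
  hydrolysis <- list(id = "LACZ", kind = "internal",
                     stoich = parse_equation(
                       "1 lcts[c] + 1 h2o[c] -> 1 glc_D[c] + 1 gal[c]"))
  expect_identical(check_balance(hydrolysis, db)$verdict, "balanced")

  homolactic <- list(id = "LDH", kind = "internal",
                     stoich = parse_equation(
                       "1 glc_D[c] -> 2 lac_L[c] + 2 h[c]"))
  rep <- check_balance(homolactic, db)
  expect_identical(rep$verdict, "balanced")
  expect_identical(rep$charge_imbalance, 0)

  unbalanced <- list(id = "BAD", kind = "internal",
                     stoich = parse_equation("1 glc_D[c] -> 2 lac_L[c]"))
  rep <- check_balance(unbalanced, db)
  expect_identical(rep$verdict, "unbalanced")
  expect_equal(rep$element_imbalance[["H"]], -2)
  expect_equal(rep$charge_imbalance, -2)
})

test_that("check_balance exempts boundary reactions and flags missing formulas", {
  db <- balance_example_db()
  ex <- list(id = "EX", kind = "exchange",
             stoich = parse_equation("1 glc_D[c] ->"))
  expect_identical(check_balance(ex, db)$verdict, "exempt")
  for (kind in c("demand", "sink", "biomass")) {
    expect_identical(check_balance(list(id = "x", kind = kind,
                                        stoich = c(`glc_D[c]` = -1)), db)$verdict,
                     "exempt")
  }
  db2 <- db
  db2$formula[db2$id == "gal[c]"] <- ""
  bad <- list(id = "LACZ", kind = "internal",
              stoich = parse_equation("1 lcts[c] + 1 h2o[c] -> 1 glc_D[c] + 1 gal[c]"))
  expect_error(check_balance(bad, db2), "gal\\[c\\]")
})

test_that("equation strings round-trip through parse/format", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    st <- stats::setNames(round(stats::runif(n, -4, 4), 3),
                          paste0("m", seq_len(n), "[c]"))
    st <- st[st != 0]
    if (length(st) == 0) next
    rt <- parse_equation(format_equation(st))
    expect_equal(rt[sort(names(rt))], st[sort(names(st))])
  }
  expect_error(parse_equation("1 a[c] + 1 b[c]"), "->")
  expect_error(parse_equation("1 a[c] -> 1 a[c]"), "empty net stoichiometry")
})

test_that("model construction enforces the documented invariants", {
  m <- make_lactate_toy()
  expect_s3_class(m, "mbx_model")
  # duplicate reaction id
  rxns <- rbind(m$rxns, m$rxns[2, ])
  expect_error(metabolic_model("x", m$mets, rxns, m$stoich, "BIO"),
               "duplicate reaction")
  # unresolved metabolite
  st <- m$stoich
  st$FERM <- c(st$FERM, `ghost[c]` = 1)
  expect_error(metabolic_model("x", m$mets, m$rxns, st, "BIO"), "ghost")
  # exchange touching two metabolites
  st <- m$stoich
  st$`EX_lcts(e)` <- c(`lcts[e]` = -1, `lac_L[e]` = 1)
  expect_error(metabolic_model("x", m$mets, m$rxns, st, "BIO"),
               "exactly one metabolite")
  # lb > ub
  rxns <- m$rxns
  rxns$lb[1] <- 5
  rxns$ub[1] <- -5
  expect_error(metabolic_model("x", m$mets, rxns, m$stoich, "BIO"),
               "lower bound")
  # compartment suffix mismatch
  mets <- m$mets
  mets$compartment[1] <- "c"
  expect_error(metabolic_model("x", mets, m$rxns, m$stoich, "BIO"), "mismatch")
})

test_that("add_reactions skips duplicates, is idempotent, and flags conflicts", {
  m <- make_lactate_toy()
  new <- reactions(id = c("FERM", "NEWR"),
                   equation = c("1 lcts[c] -> 4 lac_L[c]",
                                "1 lac_L[c] -> 1 lac_L[e]"),
                   lb = 0, ub = 1000, kind = "internal")
  res <- add_reactions(m, new)
  expect_identical(res$n_added, 1L)
  expect_identical(res$added, "NEWR")
  res2 <- add_reactions(res$model, new)
  expect_identical(res2$n_added, 0L)
  expect_gte(nrow(res2$model$rxns), nrow(m$rxns))
  # same id, different stoichiometry
  conflict <- reactions("FERM", "1 lcts[c] -> 3 lac_L[c]", kind = "internal")
  expect_error(add_reactions(m, conflict), "different stoichiometry")
  # unknown metabolite not provided
  orphan <- reactions("R3", "1 mystery[c] -> 1 lac_L[c]", kind = "internal")
  expect_error(add_reactions(m, orphan), "mystery")
  # metabolite merge conflict
  clash <- reactions("R4", "1 lcts[c] -> 4 lac_L[c]", kind = "internal")
  clash$mets <- metabolites("lcts[c]", formula = "C99", charge = 5)
  expect_error(add_reactions(m, clash), "conflict")
})

test_that("read/write round-trips are lossless for both dialects", {
  models <- c(list(make_lactate_toy(), make_host_model()),
              lapply(1:3, make_random_model))
  for (m in models) {
    # tabular
    d <- withr::local_tempdir()
    write_model(m, d, "tabular")
    m2 <- read_model(d, "tabular")
    expect_identical(m2$rxns$id, m$rxns$id)
    expect_equal(m2$stoich[names(m$stoich)], m$stoich)
    expect_equal(m2$rxns$lb, m$rxns$lb)
    expect_equal(m2$rxns$ub, m$rxns$ub)
    expect_identical(m2$rxns$subsystem, m$rxns$subsystem)
    expect_identical(m2$rxns$kind, m$rxns$kind)
    expect_identical(m2$biomass_id, m$biomass_id)
    expect_identical(m2$taxonomy$species, m$taxonomy$species)
    ordm <- function(x) x$mets[order(x$mets$id), c("formula", "charge")]
    expect_equal(ordm(m2), ordm(m), ignore_attr = TRUE)
    # sbml
    f <- withr::local_tempfile(fileext = ".xml")
    write_model(m, f, "sbml")
    m3 <- read_model(f, "sbml")
    expect_identical(m3$rxns$id, m$rxns$id)
    expect_equal(m3$stoich[names(m$stoich)], m$stoich)
    expect_equal(m3$rxns$lb, m$rxns$lb)
    expect_equal(m3$rxns$ub, m$rxns$ub)
    expect_identical(m3$rxns$kind, m$rxns$kind)
    expect_identical(m3$biomass_id, m$biomass_id)
    expect_equal(ordm(m3), ordm(m), ignore_attr = TRUE)
  }
})

test_that("SBML FBC flux bounds map onto reaction bounds", {
  m <- make_lactate_toy()
  f <- withr::local_tempfile(fileext = ".xml")
  write_model(m, f, "sbml")
  doc <- xml2::read_xml(f)
  txt <- as.character(doc)
  expect_match(txt, "fbc:lowerFluxBound")
  m2 <- read_model(f, "sbml")
  expect_equal(m2$rxns$lb[m2$rxns$id == "EX_lcts(e)"], -1000)
  expect_equal(m2$rxns$ub[m2$rxns$id == "EX_lcts(e)"], 1000)
})

test_that("tabular loader rejects stoichiometry keys absent from the metabolite sheet", {
  m <- make_lactate_toy()
  d <- withr::local_tempdir()
  write_model(m, d, "tabular")
  rx <- read.delim(file.path(d, "reactions.tsv"))
  rx$equation[4] <- "1 lcts[c] -> 4 phantom[c]"
  write.table(rx, file.path(d, "reactions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_model(d, "tabular"), "phantom")
})
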