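Package: babybiome
Title: Personalized Constraint-Based Modeling of the Infant Gut Microbiome
Version: 0.1.0
Authors@R:
    person("COSMIC", "Modeling", email = "babybiome@example.org", role = c("aut", "cre"))
Description: Builds and interrogates personalized, abundance-weighted community
    metabolic models of the developing infant gut microbiome. Strain- or
    species-level genome-scale reconstructions (SBML Level 3 + FBC or a simple
    tabular dialect) are expanded with a literature-trait-driven human milk
    oligosaccharide (HMO) degradation module, contextualized with stage-specific
    breast-milk or formula diets converted to uptake fluxes (mmol/person/day),
    and joined through a shared lumen compartment with diet and fecal exchange
    chains and an abundance-weighted community biomass reaction. Linear
    programming yields net metabolite secretion profiles, reaction and subsystem
    abundances, and species-level metabolite contributions; a statistics layer
    provides Wilcoxon rank-sum tests with Benjamini-Hochberg correction and
    Spearman correlations for group comparisons (delivery mode, time point,
    infant versus maternal). A synthetic-data module generates toy strain
    universes, cohorts with planted delivery-mode effects, and stage diets so
    the whole pipeline is testable without external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
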