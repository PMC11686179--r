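---
title: "Modeling infant gut microbiome metabolism with babybiome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling infant gut microbiome metabolism with babybiome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`babybiome` implements a constraint-based (COBRA-style) workflow for asking how
the *metabolic capabilities* of the developing infant gut microbiome differ
between groups of samples — most prominently between vaginally delivered (VD)
and Cesarean-section delivered (CSD) infants across the first year of life.
The workflow has five stages:

1. **HMO module injection.** Strain/species genome-scale reconstructions are
   expanded with human milk oligosaccharide (HMO) degradation routes driven by
   a literature trait table (which strain degrades which HMO) and a curated
   reaction catalog (exchange, transport, hydrolysis, and product-catabolism
   templates). Every formulated reaction must be elementally and charge
   balanced.
2. **Diet construction.** Breast-milk or formula composition tables
   (concentrations in g/L or mmol/L) are converted into daily uptake fluxes in
   mmol/person/day using stage-specific milk volumes, plus solid-food items
   from 6 months on.
3. **Community assembly.** Pan-species models (exact reaction unions with
   envelope bounds and a merged biomass) are joined through a shared lumen
   compartment, with a diet/fecal exchange chain per lumen metabolite and a
   community biomass reaction whose stoichiometric coefficients are the
   normalized relative abundances.
4. **Simulation.** Linear programs compute, per sample, the *net maximal
   secretion* of every fecally exchangeable metabolite (maximal fecal
   secretion minus dietary uptake, clamped at zero), reaction and subsystem
   abundances, absolute reaction presence, and species-level contribution
   fluxes.
5. **Statistics.** Two-sided Wilcoxon rank-sum tests per feature with
   Benjamini–Hochberg (BH) correction per feature family, reporting both
   "initially significant" (p < 0.05) and "FDR-significant" (q < 0.05)
   counts; Spearman correlations for abundance–flux relationships.

The steady-state assumption means all outputs are flux *capabilities*, not
concentrations, and only LP objective values are ever reported — individual
flux vectors are not unique at the optimum and never cross the API boundary.

# Key conventions

- **Identifiers.** Metabolites carry an AGORA/VMH-style compartment suffix
  (`lcts[c]`, `glc_D[e]`, lumen `[u]`, diet `[d]`, fecal `[fe]`). Community
  reaction naming is bit-compatible with the mgPipe dialect (`Diet_EX_*`,
  `DUt_*`, `UFEt_*`, `<tag>_IEX_*[u]`, `communityBiomass`), so models can be
  exchanged with tooling that expects that dialect.
- **Sign conventions.** Exchange reactions are written `met ->`; negative flux
  is uptake into the system. A diet entry of `f` mmol/person/day becomes
  bounds `(-f, 0)` on the diet exchange. Net secretion of metabolite `m` is
  the LP maximum of `v_EX_m[fe] + v_Diet_EX_m[d]`, i.e. secretion minus
  dietary uptake under the uptake-negative convention.
- **Balance checking.** Elemental formulas are parsed in Hill notation;
  pseudo-elements (`R`, `X`) take part in balancing like real elements, as is
  standard for generic groups. Exchange, demand, sink, and biomass reactions
  are exempt. The tolerance of 1e-9 only absorbs float noise on
  integer-derived sums.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| Abundance cutoff | 1e-4 | relative abundance | "low abundance" exclusion; species below it are dropped before renormalization |
| Coupling factor *c* | 400 | — | every species reaction obeys \|v\| ≤ c·v(biomass, species); the convention of the community-modeling workflow this package mirrors. Switchable off |
| Community growth window | [0.4, 1] | 1/day | net secretion values are meaningless without a growth requirement; these are the customary community bounds |
| Micronutrient trickle | 0.1 | mmol/person/day | metabolites on a configurable essential list (default: water, protons) stay open at a small uptake so models are not artificially infeasible |
| Milk volumes | 480/720/1260/1320 | mL/day | stage-specific consumption at 5 days, 1 month, 6 months, 1 year |
| LP tolerances | 1e-9 solver, 1e-6 comparison | — | objective values are solver-independent to 1e-6 on the shipped toys |

The single LP per metabolite (rather than a flux-variability max/min pair) is
a deliberate reading of "maximal production minus dietary uptake" as one net
objective; it is the cheaper computation and is what the worked toy examples
pin down. Reaction ids are sorted before LP construction, and the HiGHS
backend is deterministic, so reruns are byte-identical.

# LP backend

No linear programming library is available in the target R environment, so
the LP layer serializes batches of problems to JSON and solves them with
scipy's HiGHS implementation through the `python` interpreter on the PATH
(`inst/python/lp_batch.py`). Batching matters: a community sample needs one
growth-feasibility probe plus one LP per lumen metabolite, and the pipeline
solves all samples' LPs in a single subprocess call. Only statuses and
objective values return to R.

# The HMO expansion and gap-filling algorithm

For each trait-enabled HMO of a strain, the catalog's route (exchange,
transport *or* extracellular hydrolase, degradation reactions, product
exporters) is inserted; reactions already present are skipped, so expansion is
idempotent and models grow monotonically. The transport mechanism tag selects
the template chemistry: ABC transport consumes ATP, proton symport
co-transports H^+^, and extracellular hydrolysis keeps the glycosidase in the
`[e]` compartment.

Gap-filling is a greedy dead-end repair, since the upstream literature names
its gap-filling script but not its algorithm: degradation products are
visited in alphabetical order; a product that no other reaction can consume
gets the catalog's catabolism template for it; afterwards an LP verifies the
HMO can carry uptake flux > 1e-6 with open exchange bounds, and remaining
dead ends abort with an error naming them. Alphabetical order makes the added
set deterministic; on catalog-sized problems the greedy set is minimal in
practice.

# The synthetic world

The generator exists so that every stage is testable end to end with no
external resources. It emulates, in miniature:

- **A guild-structured universe** of 20 single-strain species (HMO degraders,
  lactate producers, butyrate cross-feeders, B-vitamin producers,
  generalists), built from a small self-consistent toy chemistry (real-ish
  formulas chosen so every reaction balances exactly; the toy "B vitamin" is
  deliberately a glucose isomer so its synthesis balances trivially). All
  species can grow on lactose, which makes milk-fed communities feasible and
  creates cross-feeding: most species export galactose, degraders consume it.
  HMO degraders do *not* carry their HMO routes innately — they acquire them
  through the trait-driven expansion, exercising the same code path the real
  workflow uses.
- **Cohorts** with a compositional abundance model: per sample, species are
  present with a probability set by the time point's expected richness and
  the guild's weight (occupancy), loads are log-normal (σ = 1.5) around the
  guild weight, shares are closed to sum to one, and shares below a detection
  limit (1e-3) are zeroed. Guild weights make HMO degraders dominant at early
  time points (the bifidobacteria-rich breastfed community) and butyrate
  producers dominant in the maternal configuration. The richness ramp
  (5/8/12/16 expected species) reproduces rising functional diversity over
  the first year.
- **Planted effects** are multiplicative factors per (guild, group, time
  point). By default a factor acts on *both* occupancy and abundance. This is
  a considered deviation from a pure abundance rescaling: with the coupling
  factor at its conventional 400 and realistic milk HMO fluxes of a few
  mmol/day, the per-species coupling caps (400·a·μ) never bind, so a
  depleted-but-present degrader community reaches the same diet-limited
  secretion optimum as a healthy one and a *maximal-capability* LP cannot see
  a pure abundance shift. Depletion of bifidobacteria in CSD infants is, in
  reality, substantially a presence/absence phenomenon at the earliest time
  points, and that is the channel through which a rank test on secretion
  capabilities can and does see it. The abundance-only semantics remain
  available (`effect_on = "abundance"`) and are what the renormalized-mixture
  calibration test uses.
- **Stage diets**: lactose 67 g/L, 2'-fucosyllactose 2.4 g/L and
  lacto-N-tetraose 1.2 g/L in breast milk (within reported ranges for mature
  milk), none of the HMOs in formula; solid items enter at 6 months (50 g
  strained apple sauce, 50 g chicken soup) and 1 year (112 g
  banana/apple/pear mash, 122.5 g yogurt, 120 g chicken soup). Maternal
  samples are simulated on a generic adult diet for a consistent reference.

What a green planted-effect test establishes: that the *pipeline* — model
expansion, assembly, diet application, LP interrogation, and the
Wilcoxon/BH layer — propagates a known guild-level depletion into
FDR-significant subsystem-abundance and secretion features. What it does not
establish: anything about real metagenomes (no sequencing noise, no
compositional bias from profiling, no strain-level heterogeneity, 20 species
instead of hundreds, and far fewer metabolites than a genome-scale
reconstruction resource).

# Stand-in curation fixtures

The published strain×HMO utilization table and HMO reaction catalog are not
redistributable here, so `synthetic_reference_traits()` and
`synthetic_reference_catalog()` generate clearly-labelled synthetic stand-ins
that reproduce the published *marginal* structure — 243 HMO-utilizing strains
across 31 species, 78 module reactions over 34 HMO/degradation-product
metabolites (28 HMOs; cofactors such as water, protons, and ATP are not
counted), and *Bifidobacterium longum* subsp. *infantis* as the strain with
the largest capability set. Each stand-in HMO is defined by its real
monosaccharide composition on a lactose core, so every hydrolysis reaction
balances by construction. Cell-level agreement with the real curation is
neither possible nor claimed.

# Statistical layer

- `rank_sum_test()` enumerates all rank assignments exactly when the pooled
  sample size is ≤ 12 and tie-free, otherwise it uses the normal
  approximation with tie and continuity corrections (identical to the
  standard corrected form). Tests are two-sided throughout — the conservative
  default when sidedness is unstated.
- `bh_adjust()` is the step-up procedure; one BH family per
  (feature class × comparison), so e.g. all net-secretion features of a
  VD-vs-CSD comparison at one time point are corrected together, and the
  secretion family is restricted to metabolites secreted by at least one
  sample.
- Time-course comparisons run all pairwise time-point tests per feature with
  BH across the pooled feature×pair family; a feature counts as significant
  if any pair is. This stays within the declared rank-sum machinery while
  handling four groups; an omnibus alternative was considered and documented
  as a possible switch, but the pairwise pooled family is what the per-row
  totals of a feature-count table correspond to.
- Constant features are skipped with p = 1 so they widen the BH family
  without ever being discoveries.

# Degenerate inputs and numerical choices

- A sample whose community cannot reach the minimum growth on its diet is an
  error naming the sample; `run_pipeline()` logs it, skips the sample, and
  fails only if no sample succeeds.
- Empty synthetic samples (possible at very low richness) are regenerated
  with an incremented sub-seed, with a message.
- Abundance columns that sum to zero after the cutoff are an error naming the
  sample, not a silent NaN.
- Ties in Wilcoxon with zero rank variance (all values identical) return
  p = 1 rather than NaN.
- Net secretion optima are clamped at 0; tiny negative optima are solver
  noise on a quantity that is non-negative by construction.

# Known limitations

- The LP backend requires a `python` with scipy on the PATH; there is no
  in-process fallback.
- Gap-filling is greedy and deterministic, not provably minimal.
- Pan-model biomass merging averages component coefficients over the strains
  containing them — one defensible reading of "a merged version" that
  preserves scale for identical strains; alternatives (union with max, flux
  re-scaling) were not implemented.
- Strain-level community assembly, flux variability analysis, flux sampling,
  and dynamic FBA are out of scope.
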