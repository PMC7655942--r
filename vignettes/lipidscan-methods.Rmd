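---
title: "Methods: two-cohort lipidomic association scanning and risk modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-cohort lipidomic association scanning and risk modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscan)
```

## Scope and model

`lipidscan` implements the statistical workflow used in large targeted
plasma lipidomics studies of Alzheimer's disease (AD) that scan several
hundred lipid species across two independent clinical cohorts:

1. **Preprocessing.** Concentrations are acquired in analytical batches
   containing pooled-plasma quality-control (QC) samples. Technical batch
   variation is removed multiplicatively: every lipid in every batch is
   rescaled so that its batch QC median equals the global QC median
   (`align_batches()`). Lipid concentrations are strongly right-skewed, so
   analysis operates on log10 concentrations, centred and scaled within
   each cohort and analysis set (`log10_standardize()`); all effects below
   are therefore *per SD of log10 concentration*. Class totals are sums of
   member species on the raw concentration scale, computed after alignment
   and before the log transform, because sums are only meaningful for
   concentrations.

2. **Prevalent disease.** One row per participant (the last acquired
   sample, with timepoint indicator covariates where several timepoints
   exist), MCI excluded so the contrast is AD versus cognitively normal.
   Per lipid: logistic regression of AD on the standardized lipid plus
   covariates (age, sex, BMI, total cholesterol, HDL-C, triglycerides,
   APOE &#949;4 count, statin, omega-3, plus site/timepoint or fasting
   where recorded), Wald two-sided p.

3. **Incident disease.** Baseline samples only, prevalent AD excluded, MCI
   retained. Cox proportional hazards with **age as the timescale**: entry
   at baseline age, exit at baseline age plus follow-up, Efron tie
   handling. Age acts only as the timescale and is not duplicated as a
   covariate. An MCI indicator is available as an optional sensitivity
   covariate (`scan_panel(..., adjust_mci = TRUE)`).

4. **Multiplicity.** Benjamini–Hochberg within two separate families —
   individual species and class totals — mirroring the 569-species /
   32-class families of a full panel. Fits flagged for separation or
   non-convergence are reported with `p = NA` and reduce the family rather
   than contributing spurious extremes.

5. **Meta-analysis.** Inverse-variance fixed-effects pooling across the
   two cohorts: \(w_i = 1/se_i^2\), \(\hat\beta = \sum w_i\beta_i/\sum
   w_i\), \(se = (\sum w_i)^{-1/2}\), \(p = 2\Phi(-|z|)\). No
   heterogeneity statistics are computed: the design is fixed-effects
   only.

6. **Clustering.** Lipid panels are heavily co-linear (shared chains,
   shared pathways). Spearman correlation, distance \(d = 1-\rho\)
   (signed, not \(1-|\rho|\): representatives must be positively
   interchangeable proxies in risk models), complete-linkage tree, and a
   dynamic hybrid cut (below). Clustering is computed per cohort on its
   own standardized matrix.

7. **Risk models.** Base model: age + sex + BMI + APOE &#949;4 count. On
   the discovery cohort, forward stepwise AIC selection adds lipids (cap
   10 for logistic diagnosis models, 5 for Cox incidence models) inside
   stratified 10-fold cross-validation; each lipid's *incorporation
   frequency* is the number of training fits that chose it. Because
   correlated lipids substitute for one another across folds and dilute
   their counts, frequencies are pooled within correlation clusters and
   each cluster contributes at most its most-incorporated member
   (`finalize_features()`). For incident discovery in an old, low-incidence
   cohort, a 2:1 age–sex-matched subset is drawn first (greedy
   nearest-age matching, cases processed in descending age). The selected
   features are then **retrained** on the replication cohort inside
   cross-validation (cohort case mixes differ too much to transfer
   coefficients); out-of-fold scores pooled per repeat give the
   C-statistic of base and base+lipids models and the category-free NRI,
   summarised over 200 repeats by the mean and 2.5/97.5 percentiles.

## Lipid nomenclature

`parse_lipid_name()` implements the shorthand grammar
`CLASS(prefix-chain[/chain][_chain]) [tags]`: `O-`/`P-` mark alkyl and
alkenyl (plasmalogen) ether linkages and move a species into the
`CLASS(O)`/`CLASS(P)` subclass; a leading `d` marks a sphingoid base; `/`
separates chains with known sn position and `_` chains with unknown
position; trailing `(a)`/`(b)` label chromatographically separated but
structurally unresolved isomers; `[sn1]` records a resolved sn position
and `[NL-x:y]` a chain identified from a neutral loss. `15-MHDA` is
parsed as a 16:0 chain carrying a methyl-branch annotation
(methylhexadecanoic acid). When chains are fully specified their carbons
and double bonds must sum to the printed totals; the vinyl-ether double
bond of plasmalogens is *not* added to the printed count. Parsing then
serialising reproduces the input name exactly. The species-to-class map
is configuration (a two-column registry file), not hard-coded, because
panel contents vary between laboratories.

## The dynamic hybrid tree cut

`dynamicTreeCut`-style branch detection is re-implemented here against an
explicit contract (byte-compatibility with any particular implementation
is not a goal):

* **Stage 1 (branch detection).** Under complete linkage a subtree's merge
  height equals its diameter, i.e. \(1-\min\rho\) over its members. The
  candidate branches are the maximal subtrees with diameter at most a
  tightness cutoff controlled by `deep_split` (0–4 map to 0.95, 0.80,
  0.65, 0.50, 0.35; default `deep_split = 1`). A candidate becomes a
  cluster only if it has at least `min_cluster_size` members (default 2 —
  a panel of ~570 species producing ~150 clusters implies average cluster
  size under 4, so the minimum must be permissive) and it is separated
  from the rest of the tree by a height gap of at least `min_gap`
  (default 0.1): branches that merge straight into the background
  correlation are rejected, which is what suppresses spurious pairs in
  unstructured data.
* **Stage 2 (singleton assignment).** Each unlabelled lipid joins the
  nearest accepted cluster if its average distance to the members is
  below that cluster's merging threshold (its diameter); otherwise it
  stays unassigned (id 0). Clusters are relabelled 1..K by decreasing
  size.

On planted block-correlated panels (within-block Spearman &#8805; 0.8,
none between) this recovers the blocks with adjusted Rand index 1.0
across seeds; on independent panels it returns no clusters.

## The synthetic two-cohort generator

`generate_cohort()` exists so that every downstream stage has testable
ground truth. It emulates:

* a species panel built from realistic, parseable names across up to 25
  classes and subclasses (default desk scale: 8 classes &#215; 25 species
  = 200 species; the full-size scale of a targeted assay is reachable by
  configuration);
* block-correlated log-normal concentrations: standard-normal latent
  abundances with correlation `rho_within` (default 0.5) inside a class
  and `rho_between` (default 0.05) across classes, mapped to
  concentrations \(10^{\mu_s + \sigma_s z}\) with per-species abundance
  scales \(\mu_s \sim U(1,3)\) (pmol/ml decades) and \(\sigma_s \sim
  U(0.15, 0.30)\), plus visit-to-visit measurement noise (SD 0.2 latent
  units);
* analytical batches (default 120 samples) with embedded QC samples
  (default 8/batch, drawn around the panel pool mean) and per-lipid,
  per-batch multiplicative factors with SD 0.1 on the log10 scale —
  exactly the structure QC-median alignment removes;
* covariates of an ageing memory-clinic cohort: age ~ N(75, 7&#178;)
  truncated at 60, 55% female, BMI 26 (4), cholesterol 5.2 (1.1), HDL-C
  1.5 (0.45), log-normal triglycerides (median 1.3), APOE &#949;4 counts
  0/1/2 at 0.60/0.32/0.08, statins 30%, omega-3 20%, a two-site flag or a
  fasting flag depending on the cohort;
* prevalent AD drawn from a logistic model on planted standardized
  species effects plus centred covariate effects (APOE 0.9 log-odds per
  allele, age 0.06/yr);
* incident conversion from a proportional-hazards model on the age scale
  with exponential baseline hazard (0.02/yr) and per-participant
  administrative censoring uniform on 2.4–9.9 years — giving ~6.15 (SD
  2.2) years of follow-up among non-converters, matching the follow-up
  structure of a long observational cohort;
* MCI as an intermediate band: among non-AD participants the MCI
  log-odds increase with the incident linear predictor and receive a
  prodromal boost (default +2.5) for participants who convert during
  follow-up, reproducing the strong baseline-MCI enrichment among
  converters seen in memory-clinic cohorts (where converters are
  predominantly MCI at baseline).

What the generator does **not** emulate: missing data mechanisms,
panel-specific abundance distributions, lipid-lipid correlation beyond
the two-level block structure, diagnosis drift other than conversion, and
assay drift within a batch. Passing tests therefore demonstrate that the
statistical machinery is correct under its stated assumptions, not that
any particular biological finding generalises.

```{r example}
panel <- default_panel(2, 5)
cfg <- sim_config(n_participants = 300, panel = panel, seed = 1,
                  beta_prevalent = planted_effects(panel, 2, 0.8))
cohort <- generate_cohort(cfg)
prev <- select_prevalent(cohort, panel)
head(scan_panel(prev, panel)[, c("lipid", "family", "beta", "se", "p", "q")])
```

## Numerical choices and degenerate inputs

* Logistic fits use iteratively reweighted least squares
  (`stats::glm.fit`); Cox fits use `survival::coxph` (Efron ties, delayed
  entry). Wald p-values are used throughout — the standard output of both
  model families and comparable across cohorts; likelihood-ratio tests
  are not mixed in.
* Complete or quasi-complete separation and monotone partial likelihoods
  are detected (divergent coefficient or SE) and *flagged*, not reported:
  panel scans continue past them and they shrink the FDR family.
* Rank-deficient designs fail fast with the collinear columns named.
* Batch alignment refuses QC-free batches and zero QC medians;
  standardisation refuses non-positive concentrations and zero-variance
  columns, naming sample and lipid.
* Latest-timepoint ties (duplicate aliquots) keep the first-read row with
  a warning. Missing covariates are handled by complete-case deletion per
  analysis set with a logged count; no imputation.
* Ranking ties in `representative_ranking()` break by the lowest mean
  selection step across CV fits, then lexicographic name, so results are
  reproducible.
* All stochastic steps (generation, fold assignment) run under explicit
  seeds via `withr::with_seed`; a fixed master seed makes selection and
  evaluation bit-reproducible.

## Design decisions that were genuinely open

* **Continuous NRI.** No risk categories are published for this setting,
  so the category-free NRI is the only parameter-free choice; it also
  accommodates total NRI values that exceed what categorical bounds would
  allow.
* **Discovery CV repeats.** Selection frequencies stabilise when the
  10-fold CV is re-randomised; the package defaults to 10 repeats
  (frequencies out of 100 training fits) with the repeat count exposed.
* **Replication CIs** are percentile intervals over the 200 evaluation
  repeats; a closed-form CI would understate fold-assignment variability.
* **Class totals after alignment.** Alignment is multiplicative per
  lipid, so summing before or after alignment differs; totals are
  computed from aligned concentrations so that class totals and species
  see the same technical correction.
* **AIBL-style site/timepoint and ADNI-style fasting covariates** enter
  as categorical indicators, not ordinal scores.

## Problem sizes used by the test-suite and acceptance script

Simulation-based checks run at desk scale, chosen to give stable
statistics while keeping a full run in the minutes range: parameter
recovery at n = 2000 participants (20 seeds); null FDR control over 50
seeds of 300 participants &#215; 40 species; meta power gain over 50
seed pairs at n = 800 per cohort; cluster recovery over 20 seeds of 400
participants &#215; 40 species; and the end-to-end discovery/replication
run at 800 participants per cohort over a 200-species panel with five
planted effects of 0.4 per SD, 2 discovery CV repeats and 200 replication
repeats.

## Known limitations

* The per-lipid scans model one row per participant; repeated-measures
  (mixed-model) extensions are out of scope.
* No imputation or outlier-sample heuristics; inputs are expected to be
  complete for the covariates used.
* Fixed-effects meta-analysis only; heterogeneity diagnostics are an
  explicit non-goal hook.
* Penalised alternatives (lasso/elastic net) to stepwise selection are
  not provided.
* The C-statistic for Cox replication uses the follow-up time axis within
  folds; other time axes (e.g. attained age) would change comparable
  pairs.
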