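# fctomics

Longitudinal fecal community typing and multi-omics analysis for two-arm
infant cohort studies.

## What this package is for

Intervention trials in formula-fed infants — for example, supplementing an
extensively hydrolysed formula with the human milk oligosaccharides
2′-fucosyllactose and lacto-*N*-neotetraose — ask whether a dietary change
redirects the maturation of the gut microbiome and its metabolic output.
`fctomics` implements the complete analysis chain for such studies, for
microbiome/metabolome analysts working from genus-level count tables,
targeted metabolite panels (including a 43-analyte bile-acid panel) and
KEGG-orthologue (KO) functional profiles:

1. **Community typing.** Genus counts are modelled as a mixture of
   Dirichlet-multinomials,
   `p(x) = Σ_k π_k DM(x; α_k)`, fitted by EM with responsibility-weighted
   digamma fixed-point updates. The number of components K is chosen by
   the minimal Laplace-approximated negative log model evidence across
   K = 2..10 with repeated restarts; components become fecal community
   types (FCT1..FCTK), numbered by temporal appearance (ascending mean
   member age).
2. **Maturation trajectories.** An age-binned transition network (mean
   Gregorian month bins, self-loops and bin-skipping edges allowed, edges
   ≤ 4% hidden from display) plus time-to-transition survival analysis:
   the event is the earliest visit at or beyond a target FCT,
   Kaplan–Meier curves, and a binary-covariate Cox model whose score test
   is the log-rank test.
3. **Group comparisons.** Two-sided Wilcoxon–Mann–Whitney tests (exact
   for small tie-free samples) with Cliff's delta effect sizes and
   consistent-variance confidence intervals; Fisher's exact tests for FCT
   prevalence; optional Benjamini–Hochberg control; competitive taxon-set
   enrichment.
4. **Metabolome discrimination.** NIPALS PLS/PLS-DA on age + treatment,
   VIP scores (`VIP_j = sqrt(p Σ_a SSY_a (w_ja/||w_a||)² / Σ_a SSY_a)`),
   score–variable correlations p(corr), venetian-blind Q2Y with
   permutation tests, and the selection rule VIP > 1 & |p(corr)| > 0.2 &
   WMW p < 0.05. Bile-acid deconjugation markers (BA/CBA, CA/CCA,
   CDCA/CCDCA, LCA/CLCA) with within-arm baseline-shift tests.
5. **Omics integration.** Pairwise KO × metabolite Kendall tau-b with BH
   control applied once over the whole matrix (FDR 10%), treatment and
   ordinal-FCT associations, and Ward.D2/Euclidean heatmap ordering.

A synthetic cohort generator (`generate_cohort()`) emulates the target
study design — ~130 infants, two arms, visits V0/V1/V3/V6, enrollment
stratification at 90 days, five latent community types whose progression
is slowed in the test arm (hazard ratio 0.56), Dirichlet-multinomial
counts, and linked metabolite/bile-acid/KO tables — so every stage is
testable without clinical data. Alpha and beta diversity (Faith's
phylogenetic diversity on rarefied counts, Bray–Curtis) are provided via
`picante` and `vegan`.

## Worked example

```r
library(fctomics)

cohort <- generate_cohort(cohort_config(), seed = 1)
cohort
#> <synthetic_cohort> 481 samples from 132 infants; 30 genera, 64 metabolites, 20 KOs (seed 1)

model <- fit_dmm(cohort$counts, K = 5, restarts = 3, seed = 7)
model
#> <dmm_model> K = 5, log-lik = -79238.11, -log evidence = 79948.63 (converged after 23 EM iterations)

assignment <- order_fcts(fct_assign(model), cohort$metadata)
table(assignment$fct)
#>   1   2   3   4   5
#>  66 129 139  85  62
```

The five fitted communities reproduce the generator's latent types
exactly here (adjusted Rand index 1 against `cohort$truth_fct`). Survival
analysis of the transition to FCT3 or later:

```r
surv <- fct_event_table(assignment, cohort$metadata, target_fct = 3)
cox_binary(surv)
#> <cox_result> HR = 0.679 [0.468, 0.985], score chi2 = 4.198, log-rank p = 0.04047 (114 events / 132)
```

The test arm transitions to late community types significantly later
(the coarse visit grid attenuates the latent 0.56 hazard ratio toward 1,
so the estimate is conservative). Bile-acid deconjugation: the control
arm's unconjugated/conjugated ratio falls from baseline at every visit,
while the test arm never declines (its only shift is a late *increase*,
driven by community maturity):

```r
panel <- cohort$metabolites[, intersect(bile_acid_panel(), colnames(cohort$metabolites))]
ratios <- bile_acid_ratios(panel)
v <- setNames(ratios$ba_cba, rownames(ratios))
round(baseline_shift_tests(v, cohort$metadata, "control"), 4)
#>     V1     V3     V6
#> 0.0000 0.0007 0.0036
round(baseline_shift_tests(v, cohort$metadata, "test"), 4)
#>     V1     V3     V6
#> 0.5690 0.1817 0.0007
```

`run_full_analysis(cohort, out_dir = "results")` chains every stage
(diversity, K selection, trajectory, differential abundance, PLS
selection, ratios, interdomain correlation) and writes a TSV/JSON results
bundle with a run manifest.

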