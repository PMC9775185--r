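# metsubtype

Metabolic abnormality is not one condition: central adiposity, raised blood
pressure, hyperglycaemia and dyslipidemia aggregate in different
combinations with different cardiovascular consequences. `metsubtype` is an
R package for epidemiologists who want to deconstruct that heterogeneity in
a population cohort: it clusters individuals carrying at least one
metabolic-syndrome component into latent subtypes, characterises the
subtypes, relates them to disease outcomes against a metabolically healthy
reference group, and probes their genetic basis with a case–control
exome-wide association stage and gene-set enrichment.

## The model

The clustering core is a covariate-adjusted finite mixture of regressions.
For individual *i* with standardized metabolic traits
*y<sub>i</sub>* ∈ ℝ<sup>P</sup> (BMI, waist, SBP, DBP, FBG, 2h-PBG, TC, TG,
HDL-C, LDL-C), control covariates *X<sub>i</sub>* and latent subtype
*z<sub>i</sub>* ∈ {1…K}:

> y<sub>ip</sub> = X<sub>i</sub> α<sub>·p</sub> + γ<sub>z<sub>i</sub>p</sub> + g<sub>i</sub> β<sub>z<sub>i</sub>·p</sub> + μ<sub>ip</sub>,  μ<sub>ip</sub> ~ N(0, σ²<sub>p</sub>)

Covariate effects α (age, sex, smoking, drinking, three genetic PCs, three
medication flags) are shared across subtypes so confounders cannot
masquerade as cluster structure; γ<sub>k</sub> are the subtype trait-mean
profiles by which subtypes are named; optional focal covariates *g* may
carry subtype-specific slopes β (unused by default). Fitting is by EM with
random restarts; the number of subtypes K maximizes 5-fold cross-validated
held-out likelihood. Around the core: NCEP-ATP III phenotyping (≥3 of five
components diagnose the syndrome; zero components define the reference
group), Table-1-style characterisation, logistic subtype–outcome odds
ratios with Wald 95% CIs, variant/sample QC (call rate ≥ 99.9% / ≥ 99%,
Hardy–Weinberg p ≥ 1e-4 in controls), additive-model per-variant logistic
EWAS (suggestive p < 5×10⁻⁵, genome-wide p < 7.5×10⁻⁸), ±50 kb SNP→gene
mapping and hypergeometric gene-set enrichment with per-category Bonferroni
correction. A synthetic-cohort generator with the same statistical
structure makes everything runnable without access to cohort data.

## Worked example

```r
library(metsubtype)

sc   <- generate_cohort(cohort_spec(n_individuals = 2000), seed = 42)
refs <- select_reference(sc$cohort)          # zero-component individuals
sub  <- sc$cohort[sc$cohort$id %in% refs$clustering_ids, ]

des <- mfmr_design(sub)                       # traits + covariate matrix
std <- standardize_traits(des$traits)
fit <- fit_mfmr(std$traits, des$X, K = 4, n_restarts = 5, seed = 1)
fit
#> MFMR model: K = 4 subtypes, P = 10 traits, Q = 10 covariates, F = 0 focal
#> mixing weights: 0.383 0.314 0.221 0.082
#> log-likelihood -25883.05 after 102 EM iterations (converged), 5 restarts kept
```

The mixing weights say the fitted subtypes hold 38/31/22/8% of the
clustered individuals; `autoplot(fit)` shows the γ heatmap each subtype is
named by, and `tidy(fit)` / `glance(fit)` expose parameters broom-style.
Associations with coronary heart disease against the reference group:

```r
labels  <- assign_subtypes(fit)$labels
lab_all <- ifelse(sc$cohort$id %in% refs$reference_ids, "reference",
                  labels[match(sc$cohort$id, sub$id)])
subtype_outcome_associations(sc$cohort, lab_all, outcome = "chd")
#> # A tibble: 4 × 11
#>   outcome subtype n_case n_total log_or    se    or ci_lo ci_hi      p significant
#> 1 chd     1           36     767  0.721 0.581 2.06  0.659  6.43 0.214  FALSE
#> 2 chd     2           43     574  1.25  0.595 3.49  1.09  11.2  0.0357 TRUE
#> 3 chd     3           21     383  0.935 0.627 2.55  0.745  8.71 0.136  FALSE
#> 4 chd     4            2     131 -0.496 0.887 0.609 0.107  3.46 0.576  FALSE
```

Each row is one subtype versus the reference group, adjusted for age, sex
and the number of metabolic-syndrome components: subtype 2 here carries
3.5-fold CHD odds (95% CI 1.09–11.2). The whole chain — simulate,
phenotype, cluster, associate, EWAS, enrich — also runs as one reproducible
pipeline:

```r
run_pipeline(list(seed = 1), out_dir = "run1")   # TSV outputs + manifest.json
```

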