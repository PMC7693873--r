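# gensubtype

Genetic-based disease subtype discovery: informative-variant selection
followed by consensus NMF clustering of affected patients, evaluated
against clinical outcomes.

## The problem

Hypertensive patients who share a diagnosis can differ in genetic etiology
and in cardiac outcome. Given a case/control cohort with SNP genotypes
(0/1/2 alternate-allele counts), covariates (age, sex, BMI) and clinical
outcome variables, `gensubtype` answers: *can the affected patients be
partitioned into genetically coherent subtypes that also differ in
clinical outcome?* It is aimed at statistical geneticists exploring
subtype structure in case/control GWAS-style cohorts.

The pipeline:

1. **Association filter.** Each variant *p* is screened with a
   covariate-adjusted logistic model
   `logit P(y_i = 1) = α₀ + α'X_i + β_p G_ip`; variants with Wald
   `p < cutoff` **and** `β_p > 0` (risk-increasing) are kept.
2. **Optional filters.** Rare variants (folded reference frequency
   `min(f, 1−f) < 0.01`, strict); deleterious variants (nonsynonymous,
   stopgain or stoploss in ≥1 of three annotation sources); F-statistic
   ranking `F = Var(p)/(p̄·q̄)` over the two status classes, cut at a top
   fraction and intersected with the association set.
3. **Feature matrix.** Selected variant counts (optionally summed into
   gene-region burdens) over the *affected* patients only.
4. **Consensus KL-NMF.** `A ≈ WH` by multiplicative updates minimizing the
   generalized Kullback–Leibler divergence (Poisson likelihood on counts),
   rerun from many random initializations; co-clustering frequencies form
   a consensus matrix, and the cophenetic correlation coefficient (CCC)
   selects the rank K. Patients are assigned by max-H with a normalized
   ambiguity margin.
5. **Evaluation.** Kruskal–Wallis rank tests of each outcome variable
   across subtypes, plus a label-matched allocation-stability audit
   between pipeline configurations.

Because suitable cohorts are access-restricted, the package ships a
first-class synthetic cohort generator (Hardy–Weinberg genotypes,
covariate-driven logistic disease risk, planted case-only subtypes with
allele-frequency shifts, subtype-shifted outcomes) that every claim in the
test suite is exercised against.

## Worked example

```r
library(gensubtype)

cfg        <- cohort_config(seed = 1)          # 200 cases / 200 controls, 300 variants
cohort     <- generate_cohort(cfg)
annotation <- generate_annotation(cfg, genes_per_cohort = 100,
                                  deleterious_fraction = 0.3)
subjects   <- data.frame(subject_id = cohort$covariates$subject_id,
                         status = unname(cohort$status),
                         cohort$covariates[, c("age", "sex", "bmi")])

fit <- gensubtype(cohort$genotypes, subjects, cohort$phenotypes, annotation,
                  pipeline_config(ranks = 2:4, nmf_runs = 10))
#> stage 1 (imputation): 0 missing genotype entries imputed by per-variant rounded mean
#> stage 2 (logistic positive-effect, p<0.05): 300 -> 75 variants
#> stage 6 (feature matrix): 75 features x 200 patients (0 zero rows, 0 zero columns dropped)
#> stage 7 (consensus NMF, 10 restarts): best rank K=2 (CCC 2:1.000 3:0.981 4:0.957)
#> stage 8 (Kruskal-Wallis, alpha=0.1): 6 significant outcome variable(s)

fit
#> Genetic subtype fit
#>   75 informative variants -> 75 features x 200 patients
#>   best rank K = 2 (CCC = 0.9999); cluster sizes: 101/99
#>   6 outcome variable(s) significant at alpha = 0.1
```

The log is the audit trail: 75 of 300 variants pass the positive-effect
logistic filter at 0.05; the consensus CCC is essentially 1 at rank 2 and
drops at ranks 3–4, so two subtypes are selected — recovering the two
planted subtypes (the cohort was simulated with a 0.25 allele-frequency
shift on 30 variants per subtype). The per-variable evaluation:

```r
head(fit$evaluation$report[, c("variable", "h_statistic", "p_value", "significant")])
#>   variable  h_statistic      p_value significant
#> 1 elateral 5.275606e+01 3.776565e-13        TRUE
#> 2  eseptal 3.721275e+01 1.059190e-09        TRUE
#> 3      gcs 7.028912e-02 7.909163e-01       FALSE
#> 4      gls 4.709529e+01 6.761798e-12        TRUE
#> 5      grs 1.806151e-04 9.892773e-01       FALSE
#> 6     sr_a 3.420546e+01 4.958953e-09        TRUE
```

Exactly the six outcome variables simulated with a 1-SD subtype shift
(`elateral`, `eseptal`, `gls`, `sr_a`, `sr_s`, `sseptal`) come out
significant; the three null variables (`gcs`, `grs`, `sr_e`) do not.
`summary(fit)` prints the full stage log and report; `plot(fit)` draws the
cluster-ordered consensus heatmap and the CCC-by-rank profile.

Real data enter through `read_genotypes()` (TSV or bi-allelic VCF),
`read_subjects()`, `read_phenotypes()` and `read_annotation()`;
`write_fixture()` emits a complete round-trippable input set from a
synthetic cohort. `pipeline_config(preset = ...)` provides the six studied
filter combinations (`rare_f_aggr`, `all_f_aggr`, `del_aggr_05`, `del_05`,
`del_aggr_10`, `del_10`), and `allocation_stability()` compares the
assignments of two fits after optimal label matching.

See `vignettes/genetic-subtyping-methods.Rmd` for the full model
description, parameter rationale, and what the synthetic generator does and
does not emulate.

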