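# Shared fixtures, memoised so expensive cohorts are simulated once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# The default study cohort: 200/200 subjects, 300 variants, two planted
# subtypes at frequency shift 0.25.
default_cohort <- function() {
  memo_fixture("default_cohort", generate_cohort(cohort_config()))
}

# Full null: no risk effects, no covariate effects, no subtype or phenotype
# shifts; association p-values must be uniform.
null_cohort <- function() {
  memo_fixture("null_cohort", generate_cohort(cohort_config(
    risk_beta = 0, covariate_effects = c(0, 0, 0),
    subtype_freq_shift = 0, phenotype_shift = 0, seed = 1L)))
}

null_assoc <- function() {
  memo_fixture("null_assoc", {
    ch <- null_cohort()
    fit_variant_logistic(ch$genotypes, ch$status,
                         ch$covariates[, c("age", "sex", "bmi")])
  })
}

cohort_subjects <- function(cohort) {
  data.frame(subject_id = cohort$covariates$subject_id,
             status = unname(cohort$status),
             cohort$covariates[, c("age", "sex", "bmi")],
             stringsAsFactors = FALSE)
}

# A small two-block feature matrix: two disjoint groups of samples supported
# by disjoint feature sets (exactly separable at rank 2).
block_matrix <- function() {
  A <- matrix(0, 6, 8)
  A[1:3, 1:4] <- matrix(c(4, 2, 3, 5, 1, 2, 3, 4, 2, 3, 4, 1), 3, 4)
  A[4:6, 5:8] <- matrix(c(5, 3, 2, 1, 4, 3, 2, 5, 4, 3, 1, 2), 3, 4)
  dimnames(A) <- list(paste0("f", 1:6), paste0("s", 1:8))
  A
}
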