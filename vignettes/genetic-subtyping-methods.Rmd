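---
title: "Methods: informative-variant selection and consensus NMF subtyping"
author: "gensubtype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: informative-variant selection and consensus NMF subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Hypertension (and complex disease generally) is heterogeneous: patients who
share a diagnosis may differ in underlying genetic etiology and in clinical
outcome. `gensubtype` implements a pipeline for discovering *genetic*
subtypes of affected patients from SNP array data: it first narrows millions
of variants down to an informative, disease-associated, positive-effect set,
then clusters the affected patients on those variants with consensus
non-negative matrix factorization (NMF), and finally asks whether the
resulting subtypes differ in independent clinical outcome variables (here,
nine echocardiographic indices of cardiac mechanics).

This vignette documents the model and every methodological choice a user or
reviewer might want to interrogate.

# Variant selection

## Per-variant logistic filter

For subject $i$ with disease status $y_i \in \{0,1\}$, covariates
$X_i = (\text{age}_i, \text{sex}_i, \text{BMI}_i)$ and alternate-allele
count $G_{ip} \in \{0,1,2\}$ at variant $p$, each variant is screened with

$$\mathrm{logit}\, P(y_i = 1) = \alpha_{0p} + \alpha_p' X_i + \beta_p G_{ip}.$$

Variants are kept when the two-sided Wald p-value of $\hat\beta_p$ falls
below a configurable cutoff (0.05 and 0.1 are the studied settings) **and**
$\hat\beta_p > 0$. The positive-effect restriction is deliberate: variants
with negative coefficients are protective, and the goal is a feature set
whose burden distinguishes *affected* patients, with all aggregated effects
pointing the same way. Choices here:

* Covariates enter on their raw scales (no standardization); the Wald test
  is invariant to affine covariate rescaling.
* Monomorphic variants, non-convergent fits and quasi-complete separation
  (detected via the fitted-probability warning of the IRLS fit, or an
  exploding standard error) are flagged `converged = FALSE` and excluded
  rather than refit with penalization — conservative and easy to audit.
* No multiple-testing correction is applied: the cutoff is a screening
  rule, not an inference.

## Rare and deleterious filters

The rare filter keeps variants whose *folded* reference-panel frequency
satisfies $\min(f, 1-f) < 0.01$ (strict inequality, "less than 1%"). The
reference column is allele-specific, but folding makes the rule invariant
to which allele was coded as reference.

The deleterious filter keeps a variant when **any one** of three gene-model
annotation sources labels it nonsynonymous, stopgain or stoploss — a union
rule, since the gene models differ in coverage and a single deleterious call
is evidence enough for a screening step. Any class outside the closed
vocabulary \{nonsynonymous, stopgain, stoploss, synonymous, unknown\} is a
validation error, not a silent pass.

## F-statistic ranking

Candidate variants can additionally be ranked by a two-class fixation-index
statistic. With $p_1, p_2$ the allele frequencies among affected and
unaffected subjects, $\bar p = (p_1+p_2)/2$, $\bar q = 1 - \bar p$:

$$F = \frac{\mathrm{Var}(p)}{\bar p \, \bar q}, \qquad
  \mathrm{Var}(p) = \frac{(p_1-\bar p)^2 + (p_2-\bar p)^2}{2}.$$

For two classes $\mathrm{Var}(p) = ((p_1-p_2)/2)^2 \le \bar p \bar q$, so
$F \in [0,1]$, with $F = 1$ only at complete divergence $(0,1)$. Conventions:

* $\bar p \in \{0, 1\}$ (monomorphic) gives 0/0; we define $F = 0$ so an
  uninformative variant can never be selected by rank.
* The cut keeps $\lceil \text{fraction} \times N \rceil$ variants —
  ceiling, so a small fraction still selects at least one variant — with
  ties broken lexicographically by variant id for determinism.
* The ranking is computed on the *pre-intersection pool* (the variants
  passing the non-association filters, e.g. all rare variants), the cut is
  applied, and only then is the result intersected with the
  positive-effect association set. The pipeline implements exactly this
  order for every configuration.

## Gene-burden aggregation

Low-frequency variants carry little per-variant signal, so the pipeline can
sum the allele counts of the selected variants within a gene region into a
single burden feature. Because only positive-effect variants survive
selection, the classic burden assumption (same direction of effect within a
region) holds by construction. The sum conserves total genotype mass, and a
plain count is used (no frequency weighting) so the result remains a valid
count input for the Poisson-likelihood NMF. Variants map to exactly one
region; if an annotation ever listed several, the first in annotation order
would be used.

# Consensus NMF subtyping

## The factorization

Given the nonnegative feature matrix $A$ ($N$ features $\times$ $M$
affected patients), NMF seeks $A \approx WH$ with $W \ge 0$
($N \times K$) and $H \ge 0$ ($K \times M$), minimizing the generalized
Kullback–Leibler divergence

$$D(A \| WH) = \sum_{ij} \Big( a_{ij} \log \frac{a_{ij}}{(WH)_{ij}}
  - a_{ij} + (WH)_{ij} \Big),$$

the objective matching a Poisson likelihood on count data — the natural
choice for allele/burden counts. The classic multiplicative updates are
used:

$$H_{kj} \leftarrow H_{kj}
  \frac{\sum_i W_{ik} a_{ij}/(WH)_{ij}}{\sum_i W_{ik}}, \qquad
  W_{ik} \leftarrow W_{ik}
  \frac{\sum_j H_{kj} a_{ij}/(WH)_{ij}}{\sum_j H_{kj}}.$$

Numerical choices:

* An epsilon guard of $10^{-12}$ is added inside every division and the
  divergence log; sparse count matrices hit exact zeros and the updates
  must not produce NaN.
* $W, H$ are initialized uniform random in $(0,1]$ from an explicit seed;
  every run in the package is reproducible.
* Stopping: every 10 iterations the sample connectivity matrix (who
  co-clusters with whom under max-H assignment) is recomputed; the run
  stops when it has been unchanged for 40 consecutive checks, or at 2000
  iterations. This targets *cluster* convergence rather than objective
  convergence, which is what the consensus step consumes.
* The divergence trace is recorded at every check and is asserted
  non-increasing (tolerance $10^{-8}$) in the tests — the known
  monotonicity guarantee of these updates.
* All-zero rows or columns are rejected with a pointer to the drop step in
  `build_feature_matrix()`; the objective is degenerate on them.

Patient $m$ is assigned to cluster $\arg\max_k H_{km}$ (ties to the
smallest index). The per-patient *margin* — largest minus second-largest
entry of the $H$ column, normalized by the column sum — is retained as an
ambiguity diagnostic: patients whose allocation changes between pipeline
configurations are expected to be the low-margin ones.

## Consensus and rank selection

NMF is stochastic in its initialization, and that stochasticity is turned
into a model-selection signal. For each candidate rank $K$ the
factorization is rerun from `nmf_runs` seeds (default 30); each run yields
a binary connectivity matrix, and their average — the consensus matrix —
holds co-clustering frequencies. If rank $K$ suits the data, runs agree
and the consensus is nearly binary.

Consistency is summarized by the cophenetic correlation coefficient (CCC):
average-linkage hierarchical clustering is applied to $1 - \text{consensus}$
and the CCC is the Pearson correlation between the dendrogram's cophenetic
distances and the original dissimilarities, over all pairs. $0 \le CCC \le 1$,
with 1 for a perfectly reproducible partition. Degenerate cases are pinned
down explicitly:

* A 0/1 consensus that encodes a valid (transitive) partition returns
  exactly 1 — including the zero-variance all-one-cluster case, which is
  detected before the correlation is attempted.
* A consensus with zero distance variance and no such structure (e.g. all
  off-diagonal entries 0.5) returns 0 by convention: it carries no cluster
  signal and must never win rank selection.
* Fewer than 3 samples is an error (the correlation needs variance over
  pairs).

The selected rank maximizes CCC over the candidate set (default 2–5); ties
break toward the smaller rank, on parsimony grounds. On the default
synthetic cohort this procedure selects $K = 2$, recovering the planted
two-subtype structure.

## Evaluation

Clinical meaningfulness is assessed by Kruskal–Wallis rank tests of each
outcome variable across the assigned subtypes — a non-parametric choice
because the echocardiographic indices are non-normal and the subtype sizes
unequal. The standard midrank statistic with tie correction and the
chi-square approximation on $K-1$ degrees of freedom are used throughout
(group sizes in scope are dozens or more; the test suite carries a
permutation oracle for small-sample honesty). If every value is identical
the statistic degenerates and $H = 0, p = 1$ is returned by convention.
The default significance level is $\alpha = 0.1$, configurable. No
multiplicity correction is applied across the nine variables, matching the
screening character of the evaluation.

Allocation stability between two pipeline configurations is audited by
matching cluster labels through the exhaustive maximum-overlap permutation
of the $K \times K$ contingency table (exact for $K \le 7$), counting
unchanged patients, and comparing mean assignment margins of changed versus
unchanged patients.

# The synthetic cohort generator

No suitable cohort with genotypes, covariates and echocardiographic
outcomes is publicly available, so the package ships a first-class
generator that emulates the statistical structure the pipeline assumes —
it is the test bed for every downstream claim.

* **Genotypes.** Each variant gets a baseline alternate-allele frequency:
  with probability `rare_fraction` (default 0.10) drawn from
  $U(0.001, 0.01)$, otherwise from `base_maf_range` (default
  $U(0.05, 0.5)$). Genotypes are $\mathrm{Binomial}(2, f)$ — Hardy–Weinberg
  equilibrium, no linkage disequilibrium.
* **Disease model.** Status follows a logistic model with covariate
  effects (defaults: 0.02 per year of age, 0.3 for sex, 0.03 per BMI
  unit — modest, realistic-scale log-odds) plus `risk_beta` (default 0.5)
  per allele over `n_risk_variants` (default 20) risk variants. The
  intercept is calibrated by bisection on the mean simulated case
  probability so the realized case fraction matches the design, then
  subjects are resampled to the exact requested counts (default 200/200).
* **Planted subtypes.** Sampled cases receive a balanced hidden subtype
  label; for each subtype, its `n_subtype_variants` (default 30)
  informative variants are redrawn at $f + $ `subtype_freq_shift` (default
  0.25). Controls keep baseline frequencies throughout — the subtype
  structure exists only among the affected, who are the clustering
  population. Risk and subtype-informative variant sets are disjoint, so
  the redraw does not perturb the disease model.
* **Outcomes.** The nine echocardiographic variables are unit-variance
  Gaussian; six of them (`elateral`, `eseptal`, `gls`, `sr_a`, `sr_s`,
  `sseptal`) carry a 1-SD mean shift between subtypes by default, leaving
  three null variables as internal negative controls.
* **Missingness** is masked completely at random at `missing_rate`
  (default 0 — the quality-control and imputation that precede such an
  analysis are out of scope, and the pipeline's own story for residual
  missingness is per-variant rounded-mean imputation, which preserves
  integer counts).
* **Covariates** are independent draws (age $\sim N(55, 10)$, sex
  $\sim \mathrm{Bern}(0.5)$, BMI $\sim N(30, 5)$); no claim of joint
  fidelity to any real cohort is made.

What the generator deliberately does **not** emulate: linkage
disequilibrium, family/pedigree relatedness, imputation dosages, and
population stratification. Passing tests therefore demonstrate correctness
of the statistical machinery under the planted model, not robustness to
those real-data complications.

# Problem sizes and reproducibility

All randomness flows through explicit seeds: the generator reproduces a
cohort bit-for-bit under a fixed config, and the pipeline is end-to-end
deterministic given its seeds, which the tests assert. The test suite and
examples run the consensus machinery with 10–15 restarts and candidate
ranks 2–4 on 200-patient cohorts — enough for stable consensus at these
problem sizes — while the package default remains 30 restarts over ranks
2–5, a common operating point for consensus NMF at desk scale. The planted
recovery checks use an adjusted-Rand-index bar of 0.8 (median over 10
generator seeds) at frequency shift 0.25.

# Known limitations

* The NMF input of 0/1/2 counts only approximately satisfies the Poisson
  assumption of the KL objective; burden aggregation brings it closer. A
  factorization tailored to trinary matrices is out of scope.
* Pedigree structure is not modeled in the association filter (no random
  effects); on family data the filter's p-values would be anticonservative.
* The exhaustive label matching in the stability audit is exponential in
  $K$ and capped at $K \le 7$ — not a practical limit for subtype counts.
* The rare-variant filter trusts the reference-panel frequency column; no
  in-sample frequency fallback is attempted.
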