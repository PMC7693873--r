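## Synthetic case/control cohort generator with planted genetic subtypes.
##
## The generator emulates the statistical structure the subtyping pipeline
## assumes: Hardy-Weinberg genotypes, covariate-driven logistic disease risk
## with positive-effect risk variants, allele-frequency shifts that exist only
## among cases and define the planted subtypes, and subtype-shifted
## echocardiographic outcomes.

#' Configuration for the synthetic cohort generator
#'
#' Collects and validates every knob of [generate_cohort()]. Defaults describe
#' a 200/200 case/control cohort of 300 variants with two planted hypertensive
#' subtypes.
#'
#' @param n_cases,n_controls Number of affected / unaffected subjects.
#' @param n_variants Total number of simulated bi-allelic variants.
#' @param n_subtypes Number of planted subtypes among cases.
#' @param n_risk_variants Variants with a positive log-odds effect
#'   (`risk_beta`) on disease status.
#' @param n_subtype_variants Subtype-informative variants *per subtype*; their
#'   alternate-allele frequency is raised by `subtype_freq_shift` within the
#'   matching planted subtype among cases.
#' @param base_maf_range Range the baseline alternate-allele frequency of
#'   common variants is drawn from, in (0, 0.5].
#' @param rare_fraction Proportion of variants drawn rare (frequency < 0.01).
#' @param subtype_freq_shift Frequency delta for subtype-informative variants.
#' @param risk_beta Log-odds per alternate allele for risk variants (positive).
#' @param covariate_effects Length-3 log-odds vector for (age in years,
#'   sex in {0,1}, BMI in kg/m^2).
#' @param phenotype_shift Named numeric vector of per-outcome mean differences
#'   between consecutive subtypes, in SD units of the unit-variance noise.
#'   Names must be among [phenotype_variables()]; unnamed scalar recycles over
#'   all nine outcomes.
#' @param missing_rate Proportion of genotype entries masked completely at
#'   random.
#' @param seed Integer RNG seed; fixing it reproduces the cohort bit-for-bit.
#'
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_cases = 200L, n_controls = 200L,
                          n_variants = 300L, n_subtypes = 2L,
                          n_risk_variants = 20L, n_subtype_variants = 30L,
                          base_maf_range = c(0.05, 0.5),
                          rare_fraction = 0.10,
                          subtype_freq_shift = 0.25,
                          risk_beta = 0.5,
                          covariate_effects = c(age = 0.02, sex = 0.3, bmi = 0.03),
                          phenotype_shift = c(elateral = 1, eseptal = 1, gls = 1,
                                              sr_a = 1, sr_s = 1, sseptal = 1),
                          missing_rate = 0,
                          seed = 1L) {
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  n_variants <- check_count(n_variants, "n_variants")
  n_subtypes <- check_count(n_subtypes, "n_subtypes")
  n_risk_variants <- check_count(n_risk_variants, "n_risk_variants", min = 0L)
  n_subtype_variants <- check_count(n_subtype_variants, "n_subtype_variants", min = 0L)
  if (length(base_maf_range) != 2L || any(!is.finite(base_maf_range)) ||
      base_maf_range[1] <= 0 || base_maf_range[2] > 0.5 ||
      base_maf_range[1] > base_maf_range[2])
    stop_field("base_maf_range", "must be an increasing pair within (0, 0.5]")
  check_probability(rare_fraction, "rare_fraction", open = FALSE)
  if (!is.numeric(subtype_freq_shift) || length(subtype_freq_shift) != 1L ||
      subtype_freq_shift < 0 || subtype_freq_shift >= 1)
    stop_field("subtype_freq_shift", "must be a single number in [0, 1)")
  if (base_maf_range[1] + subtype_freq_shift >= 1)
    stop_field("subtype_freq_shift", "shifted frequencies must stay in (0, 1)")
  if (!is.numeric(risk_beta) || length(risk_beta) != 1L || risk_beta < 0)
    stop_field("risk_beta", "must be a single non-negative number")
  if (!is.numeric(covariate_effects) || length(covariate_effects) != 3L)
    stop_field("covariate_effects", "must be a numeric triple (age, sex, bmi)")
  covariate_effects <- setNames(as.numeric(covariate_effects),
                                c("age", "sex", "bmi"))
  vars <- phenotype_variables()
  if (is.null(names(phenotype_shift)) && length(phenotype_shift) == 1L)
    phenotype_shift <- setNames(rep(phenotype_shift, length(vars)), vars)
  if (!is.numeric(phenotype_shift) || is.null(names(phenotype_shift)) ||
      !all(names(phenotype_shift) %in% vars))
    stop_field("phenotype_shift",
               "must be a named numeric vector over the nine outcome variables")
  shift <- setNames(numeric(length(vars)), vars)
  shift[names(phenotype_shift)] <- phenotype_shift
  check_probability(missing_rate, "missing_rate", open = FALSE)
  seed <- check_count(seed, "seed", min = 0L)
  if (n_subtype_variants * n_subtypes + n_risk_variants > n_variants)
    stop_field("n_subtype_variants",
               "n_risk_variants + n_subtypes * n_subtype_variants must not exceed n_variants")
  structure(list(
    n_cases = n_cases, n_controls = n_controls, n_variants = n_variants,
    n_subtypes = n_subtypes, n_risk_variants = n_risk_variants,
    n_subtype_variants = n_subtype_variants, base_maf_range = base_maf_range,
    rare_fraction = rare_fraction, subtype_freq_shift = subtype_freq_shift,
    risk_beta = risk_beta, covariate_effects = covariate_effects,
    phenotype_shift = shift, missing_rate = missing_rate, seed = seed
  ), class = "cohort_config")
}

# Calibrate the logistic intercept by bisection so that the mean simulated
# case probability equals `target` given the fixed linear predictor `eta`.
calibrate_intercept <- function(eta, target, tol = 1e-8) {
  lo <- -30; hi <- 30
  f <- function(a) mean(stats::plogis(a + eta)) - target
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic case/control cohort with planted subtypes
#'
#' Genotypes are drawn per variant as Binomial(2, f) under Hardy-Weinberg
#' equilibrium. Disease status follows a logistic model with covariate effects
#' and positive risk-variant effects, its intercept calibrated by bisection so
#' the realized case fraction matches the requested design; subjects are then
#' resampled to hit the exact case/control counts. Sampled cases receive a
#' balanced planted subtype label and the subtype-informative variants are
#' redrawn at frequency `f + subtype_freq_shift` within the matching subtype
#' (controls keep baseline frequencies). Outcome variables are unit-variance
#' Gaussian with subtype-shifted means.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"cohort"` with elements `genotypes`
#'   (subjects x variants matrix of 0/1/2 alternate-allele counts, `NA` where
#'   masked), `status` (named 0/1 vector), `covariates`, `phenotypes`
#'   (data frames keyed by `subject_id`), `truth_subtype` (named vector, `NA`
#'   for controls), `variant_info` (generating frequencies and roles) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, as.list(config))
  with_seed(config$seed, generate_cohort_impl(config))
}

# Variant roles and baseline frequencies; consumes a fixed RNG stream so that
# generate_cohort() and generate_annotation() agree on the generating
# frequencies under the same config seed.
variant_setup <- function(config) {
  P <- config$n_variants
  # variant roles: risk block first, then subtype-informative blocks
  role <- rep("background", P)
  subtype_of <- rep(NA_integer_, P)
  if (config$n_risk_variants > 0)
    role[seq_len(config$n_risk_variants)] <- "risk"
  idx <- config$n_risk_variants
  for (s in seq_len(config$n_subtypes)) {
    if (config$n_subtype_variants == 0) break
    v <- idx + seq_len(config$n_subtype_variants)
    role[v] <- "subtype"
    subtype_of[v] <- s
    idx <- idx + config$n_subtype_variants
  }
  # baseline alternate-allele frequencies
  rare <- runif(P) < config$rare_fraction
  freq <- ifelse(rare, runif(P, 0.001, 0.01),
                 runif(P, config$base_maf_range[1], config$base_maf_range[2]))
  # subtype-informative variants must keep f + shift inside (0, 1) and carry
  # enough baseline frequency to matter; draw them common
  sub_idx <- which(role == "subtype")
  if (length(sub_idx)) {
    hi <- min(config$base_maf_range[2], 0.99 - config$subtype_freq_shift)
    freq[sub_idx] <- runif(length(sub_idx), config$base_maf_range[1], hi)
  }
  list(role = role, subtype_of = subtype_of, freq = freq,
       variant_ids = sprintf("V%04d", seq_len(P)))
}

generate_cohort_impl <- function(config) {
  n_target <- config$n_cases + config$n_controls
  target_frac <- config$n_cases / n_target
  P <- config$n_variants

  setup <- variant_setup(config)
  role <- setup$role
  subtype_of <- setup$subtype_of
  freq <- setup$freq
  variant_ids <- setup$variant_ids

  # simulate a pool large enough to resample exact case/control counts
  draw_pool <- function(n_pool) {
    G <- matrix(rbinom(n_pool * P, 2L, rep(freq, each = n_pool)), n_pool, P)
    age <- rnorm(n_pool, 55, 10)
    sex <- rbinom(n_pool, 1L, 0.5)
    bmi <- rnorm(n_pool, 30, 5)
    eta <- config$covariate_effects["age"] * age +
      config$covariate_effects["sex"] * sex +
      config$covariate_effects["bmi"] * bmi
    if (config$n_risk_variants > 0)
      eta <- eta + config$risk_beta *
        rowSums(G[, role == "risk", drop = FALSE])
    a0 <- calibrate_intercept(eta, target_frac)
    p <- stats::plogis(a0 + eta)
    y <- rbinom(n_pool, 1L, p)
    list(G = G, age = age, sex = sex, bmi = bmi, y = y, a0 = a0)
  }

  pool <- NULL
  mult <- 4L
  for (attempt in 1:5) {
    cand <- draw_pool(mult * n_target)
    frac <- mean(cand$y)
    if (abs(frac - target_frac) <= 0.1 * target_frac &&
        sum(cand$y == 1L) >= config$n_cases &&
        sum(cand$y == 0L) >= config$n_controls) {
      pool <- cand
      break
    }
    mult <- mult * 2L
  }
  if (is.null(pool))
    stop("intercept calibration failed to realize the requested case fraction",
         call. = FALSE)

  keep <- c(sample(which(pool$y == 1L), config$n_cases),
            sample(which(pool$y == 0L), config$n_controls))
  G <- pool$G[keep, , drop = FALSE]
  status <- pool$y[keep]
  age <- pool$age[keep]; sex <- pool$sex[keep]; bmi <- pool$bmi[keep]
  n <- length(keep)
  subject_ids <- sprintf("S%04d", seq_len(n))
  dimnames(G) <- list(subject_ids, variant_ids)

  # planted subtypes among cases only: balanced labels, then redraw the
  # matching subtype-informative variants at the shifted frequency
  truth <- rep(NA_integer_, n)
  case_idx <- which(status == 1L)
  labels <- rep(seq_len(config$n_subtypes), length.out = length(case_idx))
  truth[case_idx] <- sample(labels)
  for (s in seq_len(config$n_subtypes)) {
    rows <- which(!is.na(truth) & truth == s)
    cols <- which(role == "subtype" & subtype_of == s)
    if (length(rows) && length(cols)) {
      f_shift <- freq[cols] + config$subtype_freq_shift
      G[rows, cols] <- matrix(
        rbinom(length(rows) * length(cols), 2L, rep(f_shift, each = length(rows))),
        length(rows), length(cols))
    }
  }

  # subtype-shifted outcomes: unit-variance noise, mean shift * (subtype - 1)
  vars <- phenotype_variables()
  pheno <- matrix(rnorm(n * length(vars)), n, length(vars),
                  dimnames = list(subject_ids, vars))
  for (j in seq_along(vars)) {
    sh <- config$phenotype_shift[vars[j]]
    if (sh != 0) {
      lev <- ifelse(is.na(truth), 0L, truth - 1L)
      pheno[, j] <- pheno[, j] + sh * lev
    }
  }

  if (config$missing_rate > 0) {
    mask <- runif(n * P) < config$missing_rate
    G[matrix(mask, n, P)] <- NA_integer_
  }

  structure(list(
    genotypes = G,
    status = setNames(status, subject_ids),
    covariates = data.frame(subject_id = subject_ids, age = age, sex = sex,
                            bmi = bmi, stringsAsFactors = FALSE),
    phenotypes = data.frame(subject_id = subject_ids, pheno,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            row.names = NULL),
    truth_subtype = setNames(truth, subject_ids),
    variant_info = data.frame(variant_id = variant_ids, role = role,
                              subtype = subtype_of, base_freq = freq,
                              stringsAsFactors = FALSE),
    config = config
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d cases / %d controls), %d variants\n",
              nrow(x$genotypes), sum(x$status == 1), sum(x$status == 0),
              ncol(x$genotypes)))
  cat(sprintf("Planted subtypes among cases: %d (freq shift %.3g)\n",
              x$config$n_subtypes, x$config$subtype_freq_shift))
  invisible(x)
}

#' Generate a synthetic variant annotation table
#'
#' Assigns every variant of a cohort to a gene region, labels it in three
#' annotation sources with a functional class from \{nonsynonymous, stopgain,
#' stoploss, synonymous, unknown\}, and reports a reference-panel
#' alternate-allele frequency equal to the generating frequency perturbed by
#' small Gaussian noise (truncated to (0, 1)).
#'
#' @param config The [cohort_config()] the cohort was generated from (supplies
#'   variant count, generating frequencies and the seed offset).
#' @param genes_per_cohort Number of distinct gene regions.
#' @param deleterious_fraction Target fraction of variants deleterious
#'   (nonsynonymous, stopgain or stoploss) in at least one source.
#' @return A data frame with columns `variant_id`, `gene_region`,
#'   `class_source1..3`, `reference_freq`.
#' @export
generate_annotation <- function(config, genes_per_cohort = 100L,
                                deleterious_fraction = 0.3) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, as.list(config))
  genes_per_cohort <- check_count(genes_per_cohort, "genes_per_cohort")
  check_probability(deleterious_fraction, "deleterious_fraction", open = FALSE)
  setup <- with_seed(config$seed, variant_setup(config))
  with_seed(config$seed + 10000L, {
    P <- config$n_variants
    variant_ids <- setup$variant_ids
    freq <- setup$freq
    gene <- sprintf("GENE%03d", sort(sample(seq_len(genes_per_cohort), P,
                                            replace = TRUE)))
    deleterious_classes <- c("nonsynonymous", "stopgain", "stoploss")
    benign_classes <- c("synonymous", "unknown")
    is_del <- runif(P) < deleterious_fraction
    classes <- matrix("synonymous", P, 3L)
    for (i in seq_len(P)) {
      if (is_del[i]) {
        n_src <- sample(1:3, 1L, prob = c(0.2, 0.3, 0.5))
        src <- sample(1:3, n_src)
        classes[i, src] <- sample(deleterious_classes, n_src, replace = TRUE,
                                  prob = c(0.95, 0.03, 0.02))
        classes[i, -src] <- sample(benign_classes, 3L - n_src, replace = TRUE,
                                   prob = c(0.9, 0.1))
      } else {
        classes[i, ] <- sample(benign_classes, 3L, replace = TRUE,
                               prob = c(0.9, 0.1))
      }
    }
    ref <- pmin(pmax(freq + rnorm(P, 0, 0.001), 1e-4), 1 - 1e-4)
    data.frame(variant_id = variant_ids, gene_region = gene,
               class_source1 = classes[, 1], class_source2 = classes[, 2],
               class_source3 = classes[, 3], reference_freq = ref,
               stringsAsFactors = FALSE)
  })
}

#' Write a cohort and its annotation as plain-text pipeline inputs
#'
#' Emits `genotypes.tsv`, `subjects.tsv`, `phenotypes.tsv`, `annotation.tsv`
#' and `genotypes.vcf` into `directory`, in the formats the pipeline readers
#' consume; the TSV genotype matrix round-trips bit-identically through
#' [read_genotypes()], and the VCF reproduces the 0/1/2 alternate-allele
#' counts (missing entries become `./.`).
#'
#' @param cohort A `"cohort"` object.
#' @param annotation The matching annotation data frame.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture <- function(cohort, annotation, directory) {
  stopifnot(inherits(cohort, "cohort"))
  if (!identical(annotation$variant_id, colnames(cohort$genotypes)))
    stop("annotation rows must match cohort variants one-to-one", call. = FALSE)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(directory, "genotypes.tsv"),
    subjects = file.path(directory, "subjects.tsv"),
    phenotypes = file.path(directory, "phenotypes.tsv"),
    annotation = file.path(directory, "annotation.tsv"),
    vcf = file.path(directory, "genotypes.vcf")
  )
  gdf <- data.frame(subject_id = rownames(cohort$genotypes),
                    cohort$genotypes, stringsAsFactors = FALSE,
                    check.names = FALSE)
  write.table(gdf, paths["genotypes"], sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  subj <- cbind(cohort$covariates[, "subject_id", drop = FALSE],
                status = unname(cohort$status),
                cohort$covariates[, c("age", "sex", "bmi")])
  write.table(subj, paths["subjects"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(annotation, paths["annotation"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_vcf(cohort$genotypes, paths["vcf"])
  invisible(paths)
}

# Minimal VCFv4.2 writer for a subjects x variants 0/1/2 matrix; one
# bi-allelic SNP per variant with unphased diploid GT fields.
write_vcf <- function(genotypes, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gensubtype",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t"))
  rows <- vapply(seq_len(ncol(genotypes)), function(p) {
    g <- genotypes[, p]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c("1", p, colnames(genotypes)[p], "A", "G", ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
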