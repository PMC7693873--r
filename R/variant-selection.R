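## Per-variant logistic association filtering with positive-effect selection,
## rare-variant (folded frequency < 1%) and deleterious-variant filters.

FUNCTIONAL_CLASSES <- c("nonsynonymous", "stopgain", "stoploss",
                        "synonymous", "unknown")
DELETERIOUS_CLASSES <- c("nonsynonymous", "stopgain", "stoploss")

#' Per-variant covariate-adjusted logistic association
#'
#' Fits, for every variant p, the model
#' `logit P(y = 1) = a0 + a' x + b * g_p` where `y` is disease status, `x`
#' the (age, sex, BMI) covariates and `g_p` the 0/1/2 alternate-allele count,
#' and returns the genotype coefficient with its Wald test. Monomorphic
#' variants and fits showing non-convergence or quasi-complete separation are
#' flagged `converged = FALSE` with the p-value left undefined.
#'
#' @param genotypes Subjects x variants numeric matrix of 0/1/2 counts;
#'   missing genotypes must already be imputed (see [gensubtype()]).
#' @param status Binary 0/1 vector, both classes present.
#' @param covariates Subjects x 3 numeric matrix or data frame (age, sex,
#'   BMI); constant columns are tolerated (they drop out as aliased).
#' @return A data frame of class `"variant_assoc"` with columns `variant_id`,
#'   `beta`, `se`, `p_value`, `converged`, `reason`.
#' @export
fit_variant_logistic <- function(genotypes, status, covariates) {
  genotypes <- as.matrix(genotypes)
  status <- as.integer(status)
  if (length(status) != nrow(genotypes))
    stop("status length must match the number of subjects", call. = FALSE)
  if (length(unique(status)) < 2L)
    stop("status must contain both cases and controls", call. = FALSE)
  X <- as.matrix(covariates)
  if (nrow(X) != nrow(genotypes) || ncol(X) != 3L)
    stop("covariates must be a subjects x 3 matrix (age, sex, bmi)",
         call. = FALSE)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("V%04d", seq_len(ncol(genotypes)))

  res <- lapply(seq_len(ncol(genotypes)), function(p) {
    g <- genotypes[, p]
    if (anyNA(g))
      stop(sprintf("variant %s has missing genotypes; impute first", ids[p]),
           call. = FALSE)
    if (var(g) == 0)
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  converged = FALSE, reason = "degenerate"))
    dat <- data.frame(y = status, X, g = g)
    names(dat) <- c("y", "age", "sex", "bmi", "g")
    separated <- FALSE
    fit <- withCallingHandlers(
      tryCatch(glm(y ~ age + sex + bmi + g, family = binomial(), data = dat),
               error = function(e) NULL),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (is.null(fit) || is.na(coef(fit)["g"]))
      return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                  converged = FALSE, reason = "degenerate"))
    cf <- summary(fit)$coefficients
    beta <- cf["g", "Estimate"]
    se <- cf["g", "Std. Error"]
    ok <- fit$converged && !separated && is.finite(se) && se > 0 && se < 50
    list(beta = beta, se = se,
         p = if (ok) 2 * pnorm(-abs(beta / se)) else NA_real_,
         converged = ok,
         reason = if (ok) "" else if (separated) "separation" else "nonconvergence")
  })
  out <- data.frame(
    variant_id = ids,
    beta = vapply(res, `[[`, numeric(1), "beta"),
    se = vapply(res, `[[`, numeric(1), "se"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    converged = vapply(res, `[[`, logical(1), "converged"),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("variant_assoc", "data.frame")
  out
}

#' Select variants by association p-value and effect direction
#'
#' Keeps converged variants with Wald `p_value < p_cutoff`, and (by default)
#' only those whose genotype effect on disease risk is positive — variants
#' with negative effects, however significant, are protective and do not
#' inform case subtyping.
#'
#' @param results A `"variant_assoc"` data frame from [fit_variant_logistic()].
#' @param p_cutoff Significance cutoff in (0, 1).
#' @param positive_only Keep only `beta > 0` variants.
#' @return Character vector of selected variant ids.
#' @export
select_by_association <- function(results, p_cutoff, positive_only = TRUE) {
  check_probability(p_cutoff, "p_cutoff")
  keep <- results$converged & !is.na(results$p_value) &
    results$p_value < p_cutoff
  if (positive_only) keep <- keep & results$beta > 0
  results$variant_id[keep]
}

#' Select rare variants by reference-panel frequency
#'
#' A variant is rare when its folded (minor-allele) reference frequency is
#' strictly below `threshold`: `min(f, 1 - f) < threshold`. Folding makes the
#' rule invariant to ref/alt allele coding.
#'
#' @param annotation Annotation data frame with `variant_id` and
#'   `reference_freq` in `[0, 1]`.
#' @param threshold Frequency threshold, default 0.01 (the "< 1%" rule).
#' @return Character vector of rare variant ids.
#' @export
select_rare <- function(annotation, threshold = 0.01) {
  check_probability(threshold, "threshold")
  f <- annotation$reference_freq
  if (any(!is.finite(f) | f < 0 | f > 1))
    stop_field("reference_freq", "must lie in [0, 1] for all variants")
  annotation$variant_id[pmin(f, 1 - f) < threshold]
}

#' Select deleterious variants across three annotation sources
#'
#' Union rule: a variant is kept iff at least one of the three annotation
#' source columns labels it nonsynonymous, stopgain or stoploss.
#'
#' @param annotation Annotation data frame with columns `class_source1`,
#'   `class_source2`, `class_source3` drawn from the closed vocabulary
#'   \{nonsynonymous, stopgain, stoploss, synonymous, unknown\}.
#' @return Character vector of deleterious variant ids.
#' @export
select_deleterious <- function(annotation) {
  cls <- as.matrix(annotation[, c("class_source1", "class_source2",
                                  "class_source3")])
  bad <- setdiff(unique(as.vector(cls)), FUNCTIONAL_CLASSES)
  if (length(bad))
    stop(sprintf("unknown functional class value(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  keep <- apply(cls, 1L, function(r) any(r %in% DELETERIOUS_CLASSES))
  annotation$variant_id[keep]
}
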