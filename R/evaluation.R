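## Kruskal-Wallis evaluation of outcome variables across subtypes, and
## label-matched allocation-stability comparison between pipeline
## configurations.

#' Kruskal-Wallis rank test
#'
#' Compares the distribution of `values` across the groups of `groups` with
#' the standard midrank H statistic (tie-corrected) and the chi-square
#' approximation on `groups - 1` degrees of freedom. Missing values are
#' dropped pairwise. When every non-missing value is identical the statistic
#' degenerates (0/0 under the tie correction); the conventional `H = 0`,
#' `p = 1` is returned.
#'
#' @param values Numeric vector.
#' @param groups Group labels (any atomic type).
#' @return List with `h_statistic`, `p_value`, `n_per_group` (named counts).
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    stop("Kruskal-Wallis needs at least two non-empty groups", call. = FALSE)
  n_per_group <- table(groups)
  if (length(unique(values)) == 1L)
    return(list(h_statistic = 0, p_value = 1,
                n_per_group = c(unclass(n_per_group))))
  kt <- kruskal.test(values, groups)
  list(h_statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       n_per_group = c(unclass(n_per_group)))
}

#' Evaluate subtype assignments against outcome variables
#'
#' Runs [kruskal_wallis()] for every outcome variable across the assigned
#' clusters and flags variables significant at `alpha`. The default
#' `alpha = 0.1` matches the working significance rule for these
#' echocardiographic comparisons. Variables with no testable data (entirely
#' missing, or a degenerate single-cluster assignment) are reported as
#' untestable rather than erroring.
#'
#' @param phenotypes Data frame with `subject_id` and one column per outcome
#'   variable.
#' @param assignment A `"subtype_assignment"` (patient ids in
#'   `names(assignment$cluster)` must appear in `phenotypes$subject_id`).
#' @param alpha Significance level.
#' @return List of class `"kw_report"`: `report` (data frame with `variable`,
#'   `h_statistic`, `p_value`, `n_per_group`, `testable`, `significant`) and
#'   `n_significant`.
#' @export
evaluate_subtypes <- function(phenotypes, assignment, alpha = 0.1) {
  check_probability(alpha, "alpha")
  ids <- names(assignment$cluster)
  if (is.null(ids)) stop("assignment clusters must be named by patient id",
                         call. = FALSE)
  missing <- setdiff(ids, phenotypes$subject_id)
  if (length(missing))
    stop(sprintf("patient(s) absent from phenotype table: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  ph <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  vars <- setdiff(names(phenotypes), "subject_id")
  rows <- lapply(vars, function(v) {
    vals <- ph[[v]]
    groups <- assignment$cluster
    ok_groups <- length(unique(groups[!is.na(vals)])) >= 2L
    if (!any(!is.na(vals)) || !ok_groups)
      return(data.frame(variable = v, h_statistic = NA_real_,
                        p_value = NA_real_, n_per_group = NA_character_,
                        testable = FALSE, significant = FALSE,
                        stringsAsFactors = FALSE))
    kw <- kruskal_wallis(vals, groups)
    data.frame(variable = v, h_statistic = kw$h_statistic,
               p_value = kw$p_value,
               n_per_group = paste(kw$n_per_group, collapse = "/"),
               testable = TRUE,
               significant = kw$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  structure(list(report = report, n_significant = sum(report$significant),
                 alpha = alpha),
            class = "kw_report")
}

#' @export
print.kw_report <- function(x, digits = 4, ...) {
  cat(sprintf("Kruskal-Wallis evaluation (alpha = %g): %d significant variable(s)\n\n",
              x$alpha, x$n_significant))
  print(x$report, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Allocation stability between two subtype assignments
#'
#' Matches the labels of `assign_b` to those of `assign_a` by exhaustive
#' maximum-overlap permutation matching on the K x K contingency table
#' (exact for K <= 7), then counts the patients whose matched labels agree.
#' When `margins_a` is supplied, the mean assignment margin is summarized
#' separately for patients that changed and those that did not — changed
#' patients are expected to be the ambiguous, low-margin ones.
#'
#' @param assign_a,assign_b `"subtype_assignment"` objects (or named integer
#'   vectors) over the same patient set.
#' @param margins_a Optional named margin vector from the first assignment;
#'   defaults to `assign_a$margin` if present.
#' @return List of class `"stability_report"`: `n_unchanged`, `n_total`,
#'   `changed` (named logical), `mean_margin_changed`,
#'   `mean_margin_unchanged`.
#' @export
allocation_stability <- function(assign_a, assign_b, margins_a = NULL) {
  lab_a <- if (inherits(assign_a, "subtype_assignment")) assign_a$cluster else assign_a
  lab_b <- if (inherits(assign_b, "subtype_assignment")) assign_b$cluster else assign_b
  if (is.null(margins_a) && inherits(assign_a, "subtype_assignment"))
    margins_a <- assign_a$margin
  if (is.null(names(lab_a)) || is.null(names(lab_b)))
    stop("assignments must be named by patient id", call. = FALSE)
  only_a <- setdiff(names(lab_a), names(lab_b))
  only_b <- setdiff(names(lab_b), names(lab_a))
  if (length(only_a) || length(only_b))
    stop(sprintf("patient sets differ (only in a: %s; only in b: %s)",
                 paste(utils::head(only_a, 5L), collapse = ","),
                 paste(utils::head(only_b, 5L), collapse = ",")),
         call. = FALSE)
  lab_b <- lab_b[names(lab_a)]
  K <- max(max(lab_a), max(lab_b))
  if (K > 7L) stop("exhaustive label matching supports at most 7 clusters",
                   call. = FALSE)
  tab <- matrix(0L, K, K)
  for (i in seq_along(lab_a)) tab[lab_a[i], lab_b[i]] <- tab[lab_a[i], lab_b[i]] + 1L
  best <- NULL; best_overlap <- -1L
  for (perm in permutations(K)) {
    # perm maps label of b -> label of a
    overlap <- sum(tab[cbind(perm, seq_len(K))])
    if (overlap > best_overlap) { best_overlap <- overlap; best <- perm }
  }
  matched_b <- best[lab_b]
  changed <- matched_b != lab_a
  mm_changed <- if (!is.null(margins_a) && any(changed))
    mean(margins_a[names(lab_a)][changed]) else NA_real_
  mm_unchanged <- if (!is.null(margins_a) && any(!changed))
    mean(margins_a[names(lab_a)][!changed]) else NA_real_
  structure(list(n_unchanged = sum(!changed), n_total = length(lab_a),
                 changed = setNames(changed, names(lab_a)),
                 mean_margin_changed = mm_changed,
                 mean_margin_unchanged = mm_unchanged),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Allocation stability: %d of %d patients unchanged\n",
              x$n_unchanged, x$n_total))
  if (!is.na(x$mean_margin_changed) || !is.na(x$mean_margin_unchanged))
    cat(sprintf("Mean assignment margin: changed %.4f, unchanged %.4f\n",
                x$mean_margin_changed, x$mean_margin_unchanged))
  invisible(x)
}
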