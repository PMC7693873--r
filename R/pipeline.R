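## End-to-end orchestration: configuration presets, the gensubtype() fitting
## function, and its print/summary/plot methods.

#' Pipeline configuration
#'
#' Collects the filter and clustering settings of one subtyping run. The six
#' named presets reproduce the studied filter combinations:
#' \describe{
#'   \item{`rare_f_aggr`}{logistic(0.05, positive) + rare + F-ranking (2%) +
#'     gene aggregation}
#'   \item{`all_f_aggr`}{logistic(0.05, positive) + F-ranking over all
#'     variants (15%) + gene aggregation}
#'   \item{`del_aggr_05` / `del_05`}{logistic(0.05, positive) + deleterious,
#'     with / without gene aggregation}
#'   \item{`del_aggr_10` / `del_10`}{the same at cutoff 0.1}
#' }
#'
#' @param preset Optional preset name; explicit arguments override it.
#' @param logistic_p_cutoff Association p-value cutoff (0.05 or 0.1 in the
#'   presets).
#' @param positive_only Keep only positive-effect variants.
#' @param use_rare_filter,rare_threshold Rare-variant filter on the folded
#'   reference frequency (strict `<`, default 1%).
#' @param use_deleterious_filter Deleterious-variant union filter.
#' @param use_f_ranking,f_top_fraction F-statistic ranking over the
#'   configured pool, cut at the top fraction, then intersected with the
#'   association-selected set.
#' @param aggregate_genes Aggregate selected variants into gene burdens.
#' @param ranks Candidate NMF ranks for cophenetic rank selection.
#' @param nmf_runs Consensus restarts per rank.
#' @param nmf_seed Base seed for the restarts.
#' @param nmf_max_iter Maximum multiplicative-update iterations per restart.
#' @param kw_alpha Significance level for the Kruskal-Wallis evaluation.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(preset = NULL,
                            logistic_p_cutoff = 0.05,
                            positive_only = TRUE,
                            use_rare_filter = FALSE,
                            rare_threshold = 0.01,
                            use_deleterious_filter = FALSE,
                            use_f_ranking = FALSE,
                            f_top_fraction = 0.02,
                            aggregate_genes = FALSE,
                            ranks = 2:5,
                            nmf_runs = 30L,
                            nmf_seed = 1L,
                            nmf_max_iter = 2000L,
                            kw_alpha = 0.1) {
  presets <- list(
    rare_f_aggr = list(logistic_p_cutoff = 0.05, use_rare_filter = TRUE,
                       use_f_ranking = TRUE, f_top_fraction = 0.02,
                       aggregate_genes = TRUE),
    all_f_aggr = list(logistic_p_cutoff = 0.05, use_f_ranking = TRUE,
                      f_top_fraction = 0.15, aggregate_genes = TRUE),
    del_aggr_05 = list(logistic_p_cutoff = 0.05,
                       use_deleterious_filter = TRUE, aggregate_genes = TRUE),
    del_05 = list(logistic_p_cutoff = 0.05, use_deleterious_filter = TRUE),
    del_aggr_10 = list(logistic_p_cutoff = 0.1,
                       use_deleterious_filter = TRUE, aggregate_genes = TRUE),
    del_10 = list(logistic_p_cutoff = 0.1, use_deleterious_filter = TRUE)
  )
  args <- list(logistic_p_cutoff = logistic_p_cutoff,
               positive_only = positive_only,
               use_rare_filter = use_rare_filter,
               rare_threshold = rare_threshold,
               use_deleterious_filter = use_deleterious_filter,
               use_f_ranking = use_f_ranking,
               f_top_fraction = f_top_fraction,
               aggregate_genes = aggregate_genes,
               ranks = ranks, nmf_runs = nmf_runs, nmf_seed = nmf_seed,
               nmf_max_iter = nmf_max_iter, kw_alpha = kw_alpha)
  if (!is.null(preset)) {
    if (!preset %in% names(presets))
      stop_field("preset", sprintf("must be one of: %s",
                                   paste(names(presets), collapse = ", ")))
    supplied <- names(match.call())[-1]
    for (nm in names(presets[[preset]]))
      if (!nm %in% supplied) args[[nm]] <- presets[[preset]][[nm]]
    args$preset <- preset
  }
  check_probability(args$logistic_p_cutoff, "logistic_p_cutoff")
  check_probability(args$rare_threshold, "rare_threshold")
  check_probability(args$kw_alpha, "kw_alpha")
  if (args$f_top_fraction <= 0 || args$f_top_fraction > 1)
    stop_field("f_top_fraction", "must lie in (0, 1]")
  args$nmf_runs <- check_count(args$nmf_runs, "nmf_runs", min = 2L)
  args$nmf_seed <- check_count(args$nmf_seed, "nmf_seed", min = 0L)
  structure(args, class = "pipeline_config")
}

# Per-variant rounded-mean imputation; keeps integer 0/1/2 counts for the
# Poisson-likelihood NMF downstream.
impute_genotypes <- function(genotypes) {
  na_cols <- which(colSums(is.na(genotypes)) > 0)
  for (p in na_cols) {
    g <- genotypes[, p]
    fill <- if (all(is.na(g))) 0L else as.integer(round(mean(g, na.rm = TRUE)))
    genotypes[is.na(g), p] <- fill
  }
  genotypes
}

#' Fit genetic subtypes of affected patients
#'
#' The main fitting function. Runs, in order: (1) per-variant rounded-mean
#' imputation of missing genotypes; (2) the covariate-adjusted logistic
#' association filter with positive-effect selection; (3) the optional
#' rare-variant filter; (4) the optional deleterious-variant filter; (5) the
#' optional F-statistic ranking — computed on the pre-intersection pool (the
#' variants passing the non-association filters), cut at the top fraction,
#' then intersected with the association-selected set; (6) feature-matrix
#' construction over affected patients, with optional gene-burden
#' aggregation; (7) consensus KL-NMF rank selection and max-H subtype
#' assignment; (8) Kruskal-Wallis evaluation of the outcome variables. Every
#' stage logs its input/output feature counts.
#'
#' @param genotypes Subjects x variants 0/1/2 matrix (NA allowed).
#' @param subjects Data frame with `subject_id`, `status`, `age`, `sex`,
#'   `bmi` (see [read_subjects()]).
#' @param phenotypes Data frame with `subject_id` plus outcome variables.
#' @param annotation Variant annotation data frame (see [read_annotation()]).
#' @param config A [pipeline_config()].
#' @return Object of class `"gensubtype"` with elements `config`,
#'   `association`, `selection` (per-stage variant-id sets), `stage_counts`,
#'   `feature_matrix`, `rank_selection`, `best_K`, `consensus`, `assignment`,
#'   `evaluation`, `log`.
#' @export
gensubtype <- function(genotypes, subjects, phenotypes, annotation,
                       config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  genotypes <- as.matrix(genotypes)
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes)))
    stop("genotypes must have subject row names and variant column names",
         call. = FALSE)
  if (!all(rownames(genotypes) %in% subjects$subject_id))
    stop("every genotyped subject must appear in the subject table",
         call. = FALSE)
  subjects <- subjects[match(rownames(genotypes), subjects$subject_id), ]
  if (!all(colnames(genotypes) %in% annotation$variant_id))
    stop("every variant must appear in the annotation table", call. = FALSE)
  annotation <- annotation[match(colnames(genotypes), annotation$variant_id), ]

  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage_counts <- integer(0)
  record <- function(stage, n) stage_counts[[stage]] <<- n

  # stage 1: imputation
  n_missing <- sum(is.na(genotypes))
  genotypes <- impute_genotypes(genotypes)
  note("stage 1 (imputation): %d missing genotype entries imputed by per-variant rounded mean",
       n_missing)
  record("input", ncol(genotypes))

  # stage 2: logistic association filter (full cohort: cases + controls)
  assoc <- fit_variant_logistic(genotypes, subjects$status,
                                subjects[, c("age", "sex", "bmi")])
  selected <- select_by_association(assoc, config$logistic_p_cutoff,
                                    config$positive_only)
  selection <- list(association = selected)
  note("stage 2 (logistic %s p<%g): %d -> %d variants",
       if (config$positive_only) "positive-effect," else "",
       config$logistic_p_cutoff, ncol(genotypes), length(selected))
  record("association", length(selected))

  # stages 3-4: annotation filters; also define the F-ranking pool
  pool <- annotation$variant_id
  if (config$use_rare_filter) {
    rare <- select_rare(annotation, config$rare_threshold)
    pool <- intersect(pool, rare)
    before <- length(selected)
    selected <- intersect(selected, rare)
    note("stage 3 (rare, folded freq < %g): %d -> %d variants",
         config$rare_threshold, before, length(selected))
    record("rare", length(selected))
  }
  if (config$use_deleterious_filter) {
    del <- select_deleterious(annotation)
    pool <- intersect(pool, del)
    before <- length(selected)
    selected <- intersect(selected, del)
    note("stage 4 (deleterious in >=1 source): %d -> %d variants",
         before, length(selected))
    record("deleterious", length(selected))
  }

  # stage 5: F ranking on the pre-intersection pool, cut, then intersect
  if (config$use_f_ranking) {
    scores <- f_scores(genotypes[, pool, drop = FALSE], subjects$status)
    top <- rank_and_cut(scores, config$f_top_fraction)
    before <- length(selected)
    selected <- intersect(selected, top)
    note("stage 5 (F ranking, top %g%% of %d pool variants): %d -> %d variants",
         100 * config$f_top_fraction, length(pool), before, length(selected))
    record("f_ranking", length(selected))
  }
  if (!length(selected))
    stop("empty variant selection after filtering; relax the cutoffs",
         call. = FALSE)
  selection$final <- selected

  # stage 6: feature matrix over affected patients
  patients <- subjects$subject_id[subjects$status == 1L]
  gene_map <- setNames(annotation$gene_region, annotation$variant_id)
  A <- build_feature_matrix(genotypes, selected, patients,
                            aggregate = config$aggregate_genes,
                            gene_map = gene_map)
  note("stage 6 (feature matrix%s): %d features x %d patients (%d zero rows, %d zero columns dropped)",
       if (config$aggregate_genes) ", gene-aggregated" else "",
       nrow(A), ncol(A), length(attr(A, "dropped_rows")),
       length(attr(A, "dropped_cols")))
  record("features", nrow(A))

  # stage 7: consensus NMF rank selection and assignment
  rs <- select_rank(A, K_values = config$ranks, n_runs = config$nmf_runs,
                    base_seed = config$nmf_seed,
                    max_iter = config$nmf_max_iter)
  best <- rs$results[[as.character(rs$best_K)]]
  assignment <- assign_clusters(best$last_fit$H)
  note("stage 7 (consensus NMF, %d restarts): best rank K=%d (CCC %s)",
       config$nmf_runs, rs$best_K,
       paste(sprintf("%d:%.3f", as.integer(names(rs$results)),
                     vapply(rs$results, `[[`, numeric(1), "ccc")),
             collapse = " "))

  # stage 8: Kruskal-Wallis evaluation
  evaluation <- evaluate_subtypes(phenotypes, assignment, config$kw_alpha)
  note("stage 8 (Kruskal-Wallis, alpha=%g): %d significant outcome variable(s)",
       config$kw_alpha, evaluation$n_significant)

  structure(list(config = config, association = assoc, selection = selection,
                 stage_counts = stage_counts, feature_matrix = A,
                 rank_selection = rs, best_K = rs$best_K, consensus = best,
                 assignment = assignment, evaluation = evaluation,
                 log = log_lines),
            class = "gensubtype")
}

#' @export
print.gensubtype <- function(x, ...) {
  cat("Genetic subtype fit\n")
  cat(sprintf("  %d informative variants -> %d features x %d patients\n",
              length(x$selection$final), nrow(x$feature_matrix),
              ncol(x$feature_matrix)))
  sizes <- table(x$assignment$cluster)
  cat(sprintf("  best rank K = %d (CCC = %.4f); cluster sizes: %s\n",
              x$best_K, x$consensus$ccc,
              paste(sizes, collapse = "/")))
  cat(sprintf("  %d outcome variable(s) significant at alpha = %g\n",
              x$evaluation$n_significant, x$config$kw_alpha))
  invisible(x)
}

#' @export
summary.gensubtype <- function(object, ...) {
  structure(list(fit = object), class = "summary.gensubtype")
}

#' @export
print.summary.gensubtype <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\nStage log:\n")
  cat(paste0("  ", fit$log, collapse = "\n"), "\n\n")
  cat("Cophenetic correlation by rank:\n")
  ccc <- vapply(fit$rank_selection$results, `[[`, numeric(1), "ccc")
  print(round(ccc, 4))
  cat("\n")
  print(fit$evaluation)
  invisible(x)
}

#' Plot a genetic subtype fit
#'
#' Draws the consensus matrix of the selected rank (samples ordered by
#' cluster) and the cophenetic correlation profile over candidate ranks.
#'
#' @param x A `"gensubtype"` fit.
#' @param ... Unused.
#' @export
plot.gensubtype <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  ord <- order(x$assignment$cluster)
  C <- x$consensus$consensus[ord, ord]
  graphics::image(seq_len(nrow(C)), seq_len(ncol(C)), C[, rev(seq_len(ncol(C)))],
                  col = grDevices::grey.colors(64, start = 1, end = 0),
                  xlab = "patients", ylab = "patients",
                  main = sprintf("Consensus (K = %d)", x$best_K))
  ks <- as.integer(names(x$rank_selection$results))
  ccc <- vapply(x$rank_selection$results, `[[`, numeric(1), "ccc")
  graphics::plot(ks, ccc, type = "b", pch = 19, xlab = "rank K",
                 ylab = "cophenetic correlation", ylim = c(0, 1),
                 main = "Rank selection")
  graphics::abline(v = x$best_K, lty = 2)
  invisible(x)
}
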