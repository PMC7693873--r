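## Burden-style aggregation of selected positive-effect variants into
## gene-region counts, and assembly of the nonnegative feature matrix fed to
## the NMF subtyping step.

#' Aggregate variant counts into gene-region burdens
#'
#' Entry (gene g, patient m) is the sum of 0/1/2 allele counts over the
#' variants mapped to g — a burden score. The input is expected to contain
#' only variants that already passed positive-effect selection, so all
#' aggregated effects share a direction. Total genotype mass is conserved.
#'
#' @param x Variants x patients numeric matrix (rows named by variant id).
#' @param gene_map Named character vector mapping variant id -> gene region.
#' @return Genes x patients matrix, rows ordered by first appearance of each
#'   gene in `rownames(x)`.
#' @export
aggregate_by_gene <- function(x, gene_map) {
  x <- as.matrix(x)
  ids <- rownames(x)
  if (is.null(ids)) stop("variant rows must be named", call. = FALSE)
  missing <- setdiff(ids, names(gene_map))
  if (length(missing))
    stop(sprintf("variant(s) missing from gene_map: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  genes <- unname(gene_map[ids])
  agg <- rowsum(x, group = genes, reorder = FALSE)
  agg[unique(genes), , drop = FALSE]
}

#' Build the nonnegative feature matrix for NMF subtyping
#'
#' Restricts the genotype matrix to the selected variants and the affected
#' (hypertensive) patients, transposes it into features x patients
#' orientation, optionally aggregates variants into gene burdens, and drops
#' all-zero rows and columns (the KL-divergence objective is degenerate on
#' all-zero slices). Dropped ids are reported with a message and attached as
#' attributes `dropped_rows` / `dropped_cols`.
#'
#' @param genotypes Subjects x variants matrix of 0/1/2 counts (imputed).
#' @param selected_variants Character vector of variant ids to keep.
#' @param patients Character vector of affected subject ids (columns of the
#'   result).
#' @param aggregate Aggregate into gene burdens?
#' @param gene_map Named variant -> gene map; required when `aggregate`.
#' @return Features x patients numeric matrix.
#' @export
build_feature_matrix <- function(genotypes, selected_variants, patients,
                                 aggregate = FALSE, gene_map = NULL) {
  if (!length(selected_variants))
    stop("no informative features: empty variant selection", call. = FALSE)
  missing_v <- setdiff(selected_variants, colnames(genotypes))
  if (length(missing_v))
    stop(sprintf("selected variant(s) absent from genotypes: %s",
                 paste(missing_v, collapse = ", ")), call. = FALSE)
  missing_p <- setdiff(patients, rownames(genotypes))
  if (length(missing_p))
    stop(sprintf("patient(s) absent from genotypes: %s",
                 paste(missing_p, collapse = ", ")), call. = FALSE)
  A <- t(genotypes[patients, selected_variants, drop = FALSE])
  if (aggregate) {
    if (is.null(gene_map))
      stop("gene_map is required when aggregate = TRUE", call. = FALSE)
    A <- aggregate_by_gene(A, gene_map)
  }
  zr <- rowSums(A) == 0
  zc <- colSums(A) == 0
  dropped_rows <- rownames(A)[zr]
  dropped_cols <- colnames(A)[zc]
  if (any(zr) || any(zc))
    message(sprintf("dropping %d all-zero feature row(s) and %d all-zero patient column(s)",
                    sum(zr), sum(zc)))
  A <- A[!zr, !zc, drop = FALSE]
  if (!nrow(A) || !ncol(A))
    stop("no informative features left after dropping all-zero rows/columns",
         call. = FALSE)
  structure(A, dropped_rows = dropped_rows, dropped_cols = dropped_cols)
}
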