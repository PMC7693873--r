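## Fixation-index-style F statistic for ranking variants by between-class
## allele-frequency divergence, with a configurable top-fraction cut.

#' Per-class alternate-allele frequencies
#'
#' For one variant, computes the alternate-allele frequency separately in the
#' two status classes: `p_c = (sum of genotype counts in class c) /
#' (2 * class size)`. Missing genotypes are excluded from both numerator and
#' denominator.
#'
#' @param genotypes Numeric vector of 0/1/2 counts over subjects (`NA`
#'   allowed).
#' @param status Binary 0/1 vector; class 1 = affected.
#' @return Named numeric `c(p1, p2)`: frequency among cases then controls.
#' @export
class_allele_freq <- function(genotypes, status) {
  status <- as.integer(status)
  if (length(genotypes) != length(status))
    stop("genotypes and status must have equal length", call. = FALSE)
  p_of <- function(cls) {
    g <- genotypes[status == cls]
    g <- g[!is.na(g)]
    if (!length(g)) stop("empty status class", call. = FALSE)
    sum(g) / (2 * length(g))
  }
  c(p1 = p_of(1L), p2 = p_of(0L))
}

#' Two-class F statistic of allele-frequency divergence
#'
#' `F = Var(p) / (pbar * qbar)` with `pbar = (p1 + p2) / 2`,
#' `qbar = 1 - pbar` and `Var(p) = ((p1 - pbar)^2 + (p2 - pbar)^2) / 2`.
#' For two classes F is bounded in `[0, 1]`, equals 0 iff `p1 = p2`, and is
#' symmetric under swapping the allele (`p -> 1 - p`) or the classes. When
#' `pbar` is 0 or 1 (monomorphic) the ratio is 0/0 and F is defined as 0: an
#' uninformative variant must rank last.
#'
#' @param p1,p2 Allele frequencies in `[0, 1]` (vectorized).
#' @return The F value(s) in `[0, 1]`.
#' @export
f_statistic <- function(p1, p2) {
  if (any(!is.finite(p1) | p1 < 0 | p1 > 1) ||
      any(!is.finite(p2) | p2 < 0 | p2 > 1))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  pbar <- (p1 + p2) / 2
  qbar <- 1 - pbar
  v <- ((p1 - pbar)^2 + (p2 - pbar)^2) / 2
  f <- ifelse(pbar <= 0 | pbar >= 1, 0, v / (pbar * qbar))
  unname(f)
}

#' F scores for every variant of a genotype matrix
#'
#' @param genotypes Subjects x variants matrix of 0/1/2 counts.
#' @param status Binary 0/1 vector over subjects.
#' @return Data frame with `variant_id`, `p1`, `p2`, `f_value` and `rank`
#'   (1-based, decreasing `f_value`, ties by `variant_id`).
#' @export
f_scores <- function(genotypes, status) {
  genotypes <- as.matrix(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("V%04d", seq_len(ncol(genotypes)))
  pc <- t(apply(genotypes, 2L, class_allele_freq, status = status))
  out <- data.frame(variant_id = ids, p1 = pc[, "p1"], p2 = pc[, "p2"],
                    f_value = f_statistic(pc[, "p1"], pc[, "p2"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-out$f_value, out$variant_id)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_len(nrow(out))
  out
}

#' Keep the top fraction of F-ranked variants
#'
#' Returns the `ceiling(top_fraction * N)` variants of highest `f_value`, in
#' decreasing order, ties broken by lexicographic `variant_id`. The ceiling
#' guarantees a non-empty selection at small fractions.
#'
#' @param scores Data frame with `variant_id` and `f_value` (e.g.
#'   [f_scores()]).
#' @param top_fraction Fraction in (0, 1] of variants to keep.
#' @return Character vector of kept variant ids, ranked.
#' @export
rank_and_cut <- function(scores, top_fraction) {
  if (!nrow(scores)) stop("empty score list", call. = FALSE)
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1)
    stop_field("top_fraction", "must be a single number in (0, 1]")
  ord <- order(-scores$f_value, scores$variant_id)
  n_keep <- ceiling(top_fraction * nrow(scores))
  scores$variant_id[ord][seq_len(n_keep)]
}
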