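## Kullback-Leibler (Poisson likelihood) non-negative matrix factorization
## with multiplicative updates, multi-restart consensus clustering, and
## cophenetic-correlation rank selection.

#' KL-divergence NMF by multiplicative updates
#'
#' Factorizes a nonnegative matrix `A` (N features x M samples) as
#' `A ~ W H` with `W >= 0` (N x K) and `H >= 0` (K x M) by minimizing the
#' generalized Kullback-Leibler divergence
#' `D(A || WH) = sum(a * log(a / wh) - a + wh)` — the objective matching a
#' Poisson likelihood on count data — with the classic multiplicative
#' updates:
#' `H <- H * (W' (A / WH)) / colSums(W)` and
#' `W <- W * ((A / WH) H') / rowSums(H)`.
#' `W` and `H` are initialized uniform random in (0, 1] from `seed`. Every
#' `check_interval` iterations the sample connectivity matrix (from max-H
#' cluster assignment) is inspected; the run stops once it has been unchanged
#' for `conv_checks` consecutive checks, or at `max_iter`.
#'
#' @param A Nonnegative numeric matrix without all-zero rows or columns.
#' @param K Factorization rank, `1 <= K < min(N, M)` (consensus rank
#'   selection only uses `K >= 2`).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Maximum number of update iterations.
#' @param conv_checks Consecutive unchanged connectivity checks required to
#'   declare convergence.
#' @param check_interval Iterations between connectivity checks.
#' @param eps Guard added inside divisions to protect exact zeros.
#' @return List of class `"nmf_fit"`: `W`, `H`, `divergence_trace` (objective
#'   at each check, non-increasing), `n_iter`, `seed`, `K`.
#' @export
nmf_brunet <- function(A, K, seed = 1L, max_iter = 2000L, conv_checks = 40L,
                       check_interval = 10L, eps = 1e-12) {
  A <- as.matrix(A)
  if (any(!is.finite(A)) || any(A < 0))
    stop("A must be finite and nonnegative", call. = FALSE)
  if (any(rowSums(A) == 0) || any(colSums(A) == 0))
    stop("A has all-zero rows or columns; drop them first (see build_feature_matrix)",
         call. = FALSE)
  N <- nrow(A); M <- ncol(A)
  K <- check_count(K, "K")
  if (K >= min(N, M))
    stop_field("K", sprintf("must satisfy 1 <= K < min(N, M) = %d", min(N, M)))

  run <- function() {
    W <- matrix(runif(N * K), N, K)
    H <- matrix(runif(K * M), K, M)
    trace <- numeric(0)
    conn_old <- NULL
    stable <- 0L
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      WH <- W %*% H
      H <- H * (crossprod(W, A / (WH + eps))) / (colSums(W) + eps)
      WH <- W %*% H
      W <- W * ((A / (WH + eps)) %*% t(H)) /
        rep(rowSums(H) + eps, each = N)
      if (it %% check_interval == 0L || it == max_iter) {
        WH <- W %*% H
        trace <- c(trace, kl_divergence(A, WH, eps))
        conn <- outer_equal(max_h_labels(H))
        if (!is.null(conn_old) && identical(conn, conn_old)) {
          stable <- stable + 1L
        } else {
          stable <- 0L
        }
        conn_old <- conn
        if (stable >= conv_checks) break
      }
    }
    structure(list(W = W, H = H, divergence_trace = trace, n_iter = it,
                   seed = as.integer(seed), K = K),
              class = "nmf_fit")
  }
  with_seed(seed, run())
}

kl_divergence <- function(A, WH, eps = 1e-12) {
  pos <- A > 0
  sum(A[pos] * log(A[pos] / (WH[pos] + eps))) - sum(A) + sum(WH)
}

max_h_labels <- function(H) {
  apply(H, 2L, which.max)
}

outer_equal <- function(labels) {
  matrix(as.integer(outer(labels, labels, "==")), length(labels))
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("KL-NMF fit: rank %d, %d x %d, %d iterations, divergence %.6g\n",
              x$K, nrow(x$W), ncol(x$H), x$n_iter,
              x$divergence_trace[length(x$divergence_trace)]))
  invisible(x)
}

#' Assign samples to subtypes from the H matrix
#'
#' Sample m belongs to the cluster whose meta-feature level `H[k, m]` is
#' highest (ties to the smallest row index). The margin — the gap between the
#' largest and second-largest entry of the column, normalized by the column
#' sum — quantifies how ambiguous the allocation is; patients that switch
#' clusters between pipeline configurations are typically low-margin.
#'
#' @param H Nonnegative K x M matrix with no all-zero columns.
#' @return List of class `"subtype_assignment"`: `cluster` (named integer
#'   vector in 1..K), `margin` (named numeric in `[0, 1]`), `K`.
#' @export
assign_clusters <- function(H) {
  H <- as.matrix(H)
  if (any(H < 0)) stop("H must be nonnegative", call. = FALSE)
  cs <- colSums(H)
  if (any(cs == 0)) stop("H has an all-zero column", call. = FALSE)
  labels <- integer(ncol(H))
  margin <- numeric(ncol(H))
  for (m in seq_len(ncol(H))) {
    col <- H[, m]
    labels[m] <- which.max(col)            # ties -> smallest index
    sorted <- sort(col, decreasing = TRUE)
    second <- if (length(sorted) > 1L) sorted[2L] else 0
    margin[m] <- (sorted[1L] - second) / cs[m]
  }
  ids <- colnames(H)
  if (!is.null(ids)) {
    names(labels) <- ids
    names(margin) <- ids
  }
  structure(list(cluster = labels, margin = margin, K = nrow(H)),
            class = "subtype_assignment")
}

#' Consensus clustering over random NMF restarts
#'
#' Runs [nmf_brunet()] with seeds `base_seed .. base_seed + n_runs - 1`,
#' builds each run's binary sample connectivity matrix from the max-H
#' assignment, and averages them into the consensus matrix whose entries are
#' co-clustering frequencies. If rank K fits the data, the partitions agree
#' across restarts and the consensus is nearly binary; the cophenetic
#' correlation coefficient summarizes that consistency.
#'
#' @param A Feature x sample matrix (see [nmf_brunet()]).
#' @param K Rank.
#' @param n_runs Number of restarts (>= 2).
#' @param base_seed First restart seed.
#' @param ... Passed to [nmf_brunet()].
#' @return List of class `"consensus_result"`: `K`, `consensus` (M x M,
#'   symmetric, unit diagonal, entries in `[0, 1]`), `ccc`, `n_runs`, and
#'   `last_fit` (the final restart's `"nmf_fit"`, kept for assignment).
#' @export
consensus_run <- function(A, K, n_runs = 30L, base_seed = 1L, ...) {
  n_runs <- check_count(n_runs, "n_runs", min = 2L)
  M <- ncol(A)
  acc <- matrix(0, M, M)
  fit <- NULL
  for (r in seq_len(n_runs)) {
    fit <- nmf_brunet(A, K, seed = base_seed + r - 1L, ...)
    acc <- acc + outer_equal(max_h_labels(fit$H))
  }
  consensus <- acc / n_runs
  dimnames(consensus) <- list(colnames(A), colnames(A))
  structure(list(K = K, consensus = consensus,
                 ccc = cophenetic_coefficient(consensus),
                 n_runs = n_runs, last_fit = fit),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus NMF: rank %d over %d restarts, CCC = %.4f\n",
              x$K, x$n_runs, x$ccc))
  invisible(x)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Average-linkage hierarchical clustering is applied to the dissimilarity
#' `1 - consensus`; the CCC is the Pearson correlation between the cophenetic
#' distances of the resulting dendrogram and the original dissimilarities,
#' over all sample pairs. A perfectly reproducible clustering (consensus
#' entries all 0/1 forming a valid partition) yields exactly 1; a consensus
#' with zero distance variance and no such structure carries no cluster
#' signal and returns 0 by convention.
#'
#' @param consensus Symmetric matrix, unit diagonal, entries in `[0, 1]`, at
#'   least 3 samples.
#' @return The CCC in `[0, 1]`.
#' @export
cophenetic_coefficient <- function(consensus) {
  consensus <- as.matrix(consensus)
  M <- nrow(consensus)
  if (M < 3L)
    stop("cophenetic correlation needs at least 3 samples", call. = FALSE)
  if (!isTRUE(all.equal(consensus, t(consensus), tolerance = 1e-10)) ||
      any(consensus < -1e-12 | consensus > 1 + 1e-12) ||
      any(abs(diag(consensus) - 1) > 1e-12))
    stop("consensus must be symmetric with unit diagonal and entries in [0, 1]",
         call. = FALSE)
  d <- as.dist(1 - consensus)
  binary <- all(abs(consensus) < 1e-12 | abs(consensus - 1) < 1e-12)
  if (binary && is_valid_partition(consensus)) return(1)
  if (stats::sd(d) < 1e-15) return(0)
  hc <- hclust(d, method = "average")
  cd <- cophenetic(hc)
  if (stats::sd(cd) < 1e-15) return(0)
  cor(d, cd)
}

# TRUE when a 0/1 consensus encodes a transitive co-clustering relation.
is_valid_partition <- function(consensus) {
  b <- consensus > 0.5
  seen <- rep(FALSE, nrow(b))
  for (i in seq_len(nrow(b))) {
    if (seen[i]) next
    members <- which(b[i, ])
    # every member must share exactly this block
    for (j in members) if (!identical(which(b[j, ]), members)) return(FALSE)
    seen[members] <- TRUE
  }
  TRUE
}

#' Select the factorization rank by cophenetic correlation
#'
#' Runs [consensus_run()] at each candidate rank and returns the rank with
#' the highest CCC; ties break toward the smaller (more parsimonious) rank.
#'
#' @param A Feature x sample matrix.
#' @param K_values Candidate ranks (each >= 2), default `2:5`.
#' @param n_runs Restarts per rank.
#' @param base_seed First restart seed (shared across ranks).
#' @param ... Passed to [nmf_brunet()].
#' @return List with `best_K` and `results` (named list of
#'   `"consensus_result"` per rank).
#' @export
select_rank <- function(A, K_values = 2:5, n_runs = 30L, base_seed = 1L, ...) {
  K_values <- sort(unique(as.integer(K_values)))
  if (any(K_values < 2L))
    stop_field("K_values", "candidate ranks must be >= 2")
  results <- lapply(K_values, function(K)
    consensus_run(A, K, n_runs = n_runs, base_seed = base_seed, ...))
  names(results) <- as.character(K_values)
  ccc <- vapply(results, `[[`, numeric(1), "ccc")
  list(best_K = best_rank_from_ccc(ccc, K_values), results = results)
}

# Parsimony tie-break: among ranks within numerical tolerance of the maximum
# CCC, take the smallest.
best_rank_from_ccc <- function(ccc, K_values, tol = 1e-12) {
  ord <- order(K_values)
  ccc <- ccc[ord]; K_values <- K_values[ord]
  K_values[which(ccc >= max(ccc) - tol)[1L]]
}
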