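# Independent oracles, implemented without touching the code paths they
# check.

# Two-parameter (intercept + slope) logistic maximum likelihood by
# Newton-Raphson, for covariate-free genotype fits.
logistic_newton_oracle <- function(y, g, tol = 1e-12, max_iter = 200) {
  theta <- c(0, 0)
  X <- cbind(1, g)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% theta)
    p <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(X, y - p))
    W <- p * (1 - p)
    Hm <- crossprod(X * W, X)
    step <- solve(Hm, grad)
    theta <- theta + step
    if (max(abs(step)) < tol) break
  }
  unname(theta[2])
}

# Kruskal-Wallis H from the textbook midrank formula with tie correction.
kw_h_manual <- function(values, groups) {
  r <- rank(values)
  N <- length(r)
  groups <- factor(groups)
  R <- tapply(r, groups, sum)
  n <- tapply(r, groups, length)
  h <- 12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / correction
}

# Permutation p-value for the Kruskal-Wallis H statistic.
kw_perm_p <- function(values, groups, B = 10000, seed = 1) {
  set.seed(seed)
  h_obs <- kw_h_manual(values, groups)
  hits <- 0L
  for (b in seq_len(B)) {
    h_b <- kw_h_manual(values, sample(groups))
    if (h_b >= h_obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# Squared standardized Wilcoxon rank-sum statistic (tie-free two-group case);
# equals the Kruskal-Wallis H analytically.
wilcoxon_z_squared <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  r <- rank(values)
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  W <- sum(r[groups == levels(groups)[1]])
  mu <- n1 * (n1 + n2 + 1) / 2
  sigma2 <- n1 * n2 * (n1 + n2 + 1) / 12
  (W - mu)^2 / sigma2
}

# Naive average-linkage agglomeration returning the full cophenetic distance
# matrix by direct dendrogram traversal (clusters merged at the average of
# the original pairwise distances between their members).
avg_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, length(members))
  coph <- matrix(0, n, n)
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(idx)) for (b in seq_len(a - 1)) {
      i <- idx[a]; j <- idx[b]
      d_ij <- mean(D[members[[i]], members[[j]]])
      if (d_ij < best_d) { best_d <- d_ij; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    for (u in members[[i]]) for (v in members[[j]]) {
      coph[u, v] <- best_d; coph[v, u] <- best_d
    }
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
  }
  coph
}

# Adjusted Rand index from the contingency-table formula.
ari_manual <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)
  (sum_ij - expected) / (max_idx - expected)
}

# Closed-form optimal rank-1 KL factorization target.
kl_rank1_target <- function(A) {
  outer(rowSums(A), colSums(A)) / sum(A)
}
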