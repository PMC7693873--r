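test_that("rank-1 KL factorization reaches the closed-form optimum", {
  set.seed(11)
  A <- matrix(runif(48, 0.5, 4), 8, 6)
  fit <- nmf_brunet(A, K = 1, seed = 2, max_iter = 1000)
  target <- kl_rank1_target(A)
  WH <- fit$W %*% fit$H
  expect_lt(max(abs(WH - target) / target), 1e-4)

  # exactly factorizable input: divergence collapses
  w <- runif(7, 0.2, 2); h <- runif(5, 0.2, 2)
  A1 <- outer(w, h)
  fit1 <- nmf_brunet(A1, K = 1, seed = 3, max_iter = 1000)
  expect_lt(fit1$divergence_trace[length(fit1$divergence_trace)],
            1e-6 * sum(A1))
})

test_that("divergence is non-increasing across updates for random problems", {
  set.seed(21)
  for (s in 1:50) {
    A <- matrix(rpois(120, 3) + runif(120, 0, 0.5), 12, 10)
    fit <- nmf_brunet(A, K = 3, seed = s, max_iter = 200, check_interval = 5)
    tr <- fit$divergence_trace
    expect_true(all(diff(tr) <= 1e-8 * (1 + abs(tr[-length(tr)]))))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  }
})

test_that("a two-block matrix is separated exactly at rank 2", {
  A <- block_matrix()
  fit <- nmf_brunet(A, K = 2, seed = 1)
  labels <- assign_clusters(fit$H)$cluster
  expect_equal(length(unique(labels[1:4])), 1L)
  expect_equal(length(unique(labels[5:8])), 1L)
  expect_true(labels[1] != labels[5])
})

test_that("rescaling W and H inversely leaves WH and the assignment unchanged", {
  A <- block_matrix()
  fit <- nmf_brunet(A, K = 2, seed = 6)
  lambda <- c(3, 0.2)
  W2 <- sweep(fit$W, 2, lambda, "*")
  H2 <- sweep(fit$H, 1, lambda, "/")
  expect_equal(W2 %*% H2, fit$W %*% fit$H)
  expect_equal(assign_clusters(H2)$cluster, assign_clusters(fit$H)$cluster)
})

test_that("nmf input validation rejects degenerate matrices and ranks", {
  A <- block_matrix()
  bad <- A; bad[, 1] <- 0
  expect_error(nmf_brunet(bad, 2), "all-zero")
  expect_error(nmf_brunet(A, 6), "K")
  expect_error(nmf_brunet(-A, 2), "nonnegative")
})

test_that("max-H assignment uses argmax with smallest-index ties and normalized margins", {
  H <- cbind(a = c(0.6, 0.4), b = c(0.5, 0.5), c = c(0.1, 0.9))
  asg <- assign_clusters(H)
  expect_equal(unname(asg$cluster), c(1L, 1L, 2L))
  expect_equal(unname(asg$margin), c(0.2, 0, 0.8))
  expect_error(assign_clusters(cbind(c(0, 0))), "all-zero")
})

test_that("consensus matrices are well-formed co-clustering frequencies", {
  A <- block_matrix()
  cr <- consensus_run(A, K = 2, n_runs = 5, base_seed = 1, max_iter = 400)
  C <- cr$consensus
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, ncol(A)))
  expect_true(all(C >= 0 & C <= 1))
  # the block structure is recovered identically in every restart
  expect_true(all(C %in% c(0, 1)))
  expect_equal(cr$ccc, 1)
  expect_error(consensus_run(A, K = 2, n_runs = 1), "n_runs")
})

test_that("averaging connectivities of two crossed partitions halves the consensus", {
  conn <- function(labels) outer(labels, labels, function(a, b) as.numeric(a == b))
  C <- (conn(c(1, 1, 2, 2)) + conn(c(1, 2, 1, 2))) / 2
  off <- C[upper.tri(C)]
  expect_true(all(off %in% c(0, 0.5)))
  expect_equal(diag(C), rep(1, 4))
})

test_that("cophenetic coefficient matches an independent dendrogram traversal", {
  # perfect two-block consensus
  C <- matrix(0, 6, 6); C[1:3, 1:3] <- 1; C[4:6, 4:6] <- 1
  expect_equal(cophenetic_coefficient(C), 1)

  # all runs identical partition (single block): zero variance but perfect
  expect_equal(cophenetic_coefficient(matrix(1, 4, 4)), 1)

  # constant 0.5 off-diagonal: no structure, 0 by convention
  C2 <- matrix(0.5, 5, 5); diag(C2) <- 1
  expect_equal(cophenetic_coefficient(C2), 0)

  # noisy two-block 5-sample fixture against the naive average-linkage oracle
  C3 <- matrix(c(1.00, 0.90, 0.85, 0.10, 0.05,
                 0.90, 1.00, 0.80, 0.15, 0.10,
                 0.85, 0.80, 1.00, 0.20, 0.15,
                 0.10, 0.15, 0.20, 1.00, 0.95,
                 0.05, 0.10, 0.15, 0.95, 1.00), 5, 5)
  D <- 1 - C3
  coph <- avg_linkage_cophenetic(D)
  expected <- cor(as.dist(D), as.dist(coph))
  expect_equal(cophenetic_coefficient(C3), expected, tolerance = 1e-10)

  expect_error(cophenetic_coefficient(matrix(1, 2, 2)), "at least 3")
  expect_error(cophenetic_coefficient(matrix(2, 4, 4)), "unit diagonal")
})

test_that("rank selection maximizes CCC with a parsimony tie-break", {
  A <- block_matrix()
  rs <- select_rank(A, K_values = 2, n_runs = 4, base_seed = 1, max_iter = 400)
  expect_equal(rs$best_K, 2L)
  expect_named(rs$results, "2")

  # the tie rule itself: equal CCC -> smaller rank
  expect_equal(gensubtype:::best_rank_from_ccc(c(0.9, 0.9, 0.7), c(2, 3, 4)), 2)
  expect_equal(gensubtype:::best_rank_from_ccc(c(0.7, 0.9, 0.9), c(2, 3, 4)), 3)
  expect_error(select_rank(A, K_values = 1), "K_values")
})

test_that("planted two-subtype structure beats the no-signal null in consensus stability", {
  cfg_base <- function(shift, seed)
    cohort_config(n_cases = 100, n_controls = 100, n_variants = 120,
                  n_risk_variants = 10, n_subtype_variants = 15,
                  subtype_freq_shift = shift, seed = seed)
  diffs <- vapply(1:10, function(s) {
    ccc_of <- function(shift) {
      ch <- generate_cohort(cfg_base(shift, s))
      cases <- names(ch$status)[ch$status == 1]
      sub_vars <- ch$variant_info$variant_id[ch$variant_info$role == "subtype"]
      A <- suppressMessages(build_feature_matrix(ch$genotypes, sub_vars, cases))
      consensus_run(A, K = 2, n_runs = 6, base_seed = 100 + s,
                    max_iter = 500)$ccc
    }
    ccc_of(0.25) - ccc_of(0)
  }, numeric(1))
  expect_gt(median(diffs), 0)
})
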