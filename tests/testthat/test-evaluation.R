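test_that("Kruskal-Wallis H matches the hand rank formula and conventions", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 2, 2, 2))
  # 12/(6*7) * (6^2/3 + 15^2/3) - 3*7
  expect_equal(round(kw$h_statistic, 3), 3.857)
  expect_equal(kw$h_statistic, kw_h_manual(1:6, rep(1:2, each = 3)))
  expect_equal(kw$p_value, stats::pchisq(kw$h_statistic, 1, lower.tail = FALSE))
  expect_equal(unname(kw$n_per_group), c(3L, 3L))

  # all values identical -> H = 0, p = 1 by convention
  tied <- kruskal_wallis(rep(2, 8), rep(1:2, each = 4))
  expect_equal(tied$h_statistic, 0)
  expect_equal(tied$p_value, 1)

  # missing values dropped pairwise
  kw_na <- kruskal_wallis(c(1, 2, 3, NA, 5, 6, 7), c(1, 1, 1, 1, 2, 2, 2))
  expect_equal(unname(kw_na$n_per_group), c(3L, 3L))

  expect_error(kruskal_wallis(1:5, rep(1, 5)), "two non-empty groups")
})

test_that("chi-square p-values agree with a 10,000-permutation oracle on small fixtures", {
  set.seed(31)
  vals <- c(2.3, 1.1, 3.8, 2.9, 4.1, 0.7, 3.3, 2.0, 1.9, 4.4,
            2.6, 3.1, 1.4, 2.2, 3.6, 2.8, 1.8, 3.0)
  grp <- rep(1:2, each = 9)
  # the chi-square approximation carries its own small-sample error on top of
  # the oracle's Monte-Carlo noise; 0.05 covers both at n = 18
  kw <- kruskal_wallis(vals, grp)
  p_perm <- kw_perm_p(vals, grp, B = 10000, seed = 2)
  expect_lt(abs(kw$p_value - p_perm), 0.05)

  # three-group fixture
  grp3 <- rep(1:3, each = 6)
  kw3 <- kruskal_wallis(vals, grp3)
  p_perm3 <- kw_perm_p(vals, grp3, B = 10000, seed = 3)
  expect_lt(abs(kw3$p_value - p_perm3), 0.05)
})

test_that("two-group H equals the squared standardized Wilcoxon statistic", {
  set.seed(17)
  for (rep in 1:10) {
    vals <- sample(seq_len(30))   # tie-free
    grp <- rep(1:2, times = c(12, 18))
    kw <- kruskal_wallis(vals, grp)
    expect_equal(kw$h_statistic, wilcoxon_z_squared(vals, grp))
  }
})

test_that("subtype evaluation counts significant variables and flags untestable ones", {
  set.seed(5)
  n <- 80
  ids <- sprintf("p%03d", 1:n)
  cluster <- setNames(rep(1:2, each = n / 2), ids)
  ph <- data.frame(subject_id = ids,
                   shifted = rnorm(n) + (cluster - 1) * 2,
                   flat = rnorm(n),
                   empty = NA_real_,
                   check.names = FALSE)
  asg <- structure(list(cluster = cluster,
                        margin = setNames(runif(n), ids), K = 2L),
                   class = "subtype_assignment")
  ev <- evaluate_subtypes(ph, asg, alpha = 0.1)
  rep_ <- ev$report
  expect_true(rep_$significant[rep_$variable == "shifted"])
  expect_false(rep_$testable[rep_$variable == "empty"])
  expect_true(ev$n_significant >= 1)

  # degenerate single-cluster assignment: nothing testable
  asg1 <- structure(list(cluster = setNames(rep(1L, n), ids),
                         margin = setNames(rep(1, n), ids), K = 1L),
                    class = "subtype_assignment")
  ev1 <- evaluate_subtypes(ph, asg1)
  expect_false(any(ev1$report$testable))
  expect_equal(ev1$n_significant, 0L)

  expect_error(evaluate_subtypes(ph[-1, ], asg), "absent from phenotype")
})

test_that("null phenotypes are flagged at roughly the alpha rate", {
  set.seed(8)
  alpha <- 0.1
  hits <- replicate(25, {
    n <- 100
    ids <- sprintf("p%03d", 1:n)
    cluster <- setNames(sample(rep(1:2, each = n / 2)), ids)
    ph <- data.frame(subject_id = ids, matrix(rnorm(n * 9), n, 9,
                     dimnames = list(NULL, phenotype_variables())),
                     check.names = FALSE)
    asg <- structure(list(cluster = cluster, margin = setNames(rep(1, n), ids),
                          K = 2L), class = "subtype_assignment")
    evaluate_subtypes(ph, asg, alpha = alpha)$n_significant
  })
  expect_lt(abs(mean(hits) / 9 - alpha), 0.07)
})

test_that("the adjusted Rand helper agrees with an established implementation", {
  set.seed(23)
  for (rep in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(ari_manual(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(ari_manual(rep(1:2, 10), rep(1:2, 10)), 1)
})

test_that("allocation stability matches labels before counting changes", {
  ids <- sprintf("p%02d", 1:20)
  a <- setNames(rep(1:2, each = 10), ids)
  margins <- setNames(seq(0.05, 1, length.out = 20), ids)

  # global label swap: all patients unchanged after matching
  swapped <- setNames(3L - a, ids)
  st <- allocation_stability(a, swapped, margins)
  expect_equal(st$n_unchanged, 20L)
  expect_equal(st$n_total, 20L)

  # exactly 3 patients differ after matching
  b <- a; b[c(2, 11, 15)] <- 3L - b[c(2, 11, 15)]
  st3 <- allocation_stability(a, b, margins)
  expect_equal(st3$n_unchanged, 17L)

  # symmetry of the unchanged count
  expect_equal(allocation_stability(b, a)$n_unchanged, 17L)

  expect_error(allocation_stability(a, b[-1]), "patient sets differ")
})

test_that("changed patients drawn from the lowest-margin decile have lower mean margin", {
  ids <- sprintf("p%03d", 1:100)
  a <- setNames(rep(1:2, 50), ids)
  margins <- setNames(seq(0.01, 1, length.out = 100), ids)
  low_decile <- names(sort(margins))[1:10]
  b <- a
  b[low_decile] <- 3L - b[low_decile]
  st <- allocation_stability(a, b, margins)
  expect_equal(st$n_unchanged, 90L)
  expect_lt(st$mean_margin_changed, st$mean_margin_unchanged)
})
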