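test_that("cohort generation is reproducible and honours the design", {
  cfg <- cohort_config(n_cases = 60, n_controls = 60, n_variants = 80,
                       n_risk_variants = 8, n_subtype_variants = 10, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  expect_equal(sum(a$status == 1), 60)
  expect_equal(sum(a$status == 0), 60)
  expect_equal(dim(a$genotypes), c(120L, 80L))
  expect_true(all(a$genotypes %in% 0:2))          # missing_rate = 0 -> complete
  expect_true(all(is.na(a$truth_subtype[a$status == 0])))

  # balanced planted labels among cases (within 10%)
  sizes <- table(a$truth_subtype)
  expect_lt(max(sizes) / min(sizes), 1.1 / 0.9)

  # masking is applied at roughly the requested rate
  cfg_miss <- cohort_config(n_cases = 60, n_controls = 60, n_variants = 80,
                            n_risk_variants = 8, n_subtype_variants = 10,
                            missing_rate = 0.1, seed = 7)
  m <- generate_cohort(cfg_miss)
  expect_gt(mean(is.na(m$genotypes)), 0.07)
  expect_lt(mean(is.na(m$genotypes)), 0.13)
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_cases = 0), "n_cases")
  expect_error(cohort_config(rare_fraction = 1.5), "rare_fraction")
  expect_error(cohort_config(subtype_freq_shift = 0.96), "subtype_freq_shift")
  expect_error(cohort_config(n_variants = 50, n_subtype_variants = 30,
                             n_subtypes = 2), "n_subtype_variants")
  expect_error(cohort_config(covariate_effects = c(1, 2)), "covariate_effects")
})

test_that("subtype-informative variants carry the planted frequency shift", {
  ch <- default_cohort()
  cfg <- ch$config
  info <- ch$variant_info
  sub_vars <- info[info$role == "subtype", ]
  truth <- ch$truth_subtype[!is.na(ch$truth_subtype)]
  cases <- names(truth)
  z <- vapply(seq_len(nrow(sub_vars)), function(i) {
    v <- sub_vars$variant_id[i]
    s <- sub_vars$subtype[i]
    g_in <- ch$genotypes[cases[truth == s], v]
    g_out <- ch$genotypes[cases[truth != s], v]
    diff <- sum(g_in) / (2 * length(g_in)) - sum(g_out) / (2 * length(g_out))
    f_in <- sub_vars$base_freq[i] + cfg$subtype_freq_shift
    f_out <- sub_vars$base_freq[i]
    se <- sqrt(f_in * (1 - f_in) / (2 * length(g_in)) +
                 f_out * (1 - f_out) / (2 * length(g_out)))
    abs(diff - cfg$subtype_freq_shift) / se
  }, numeric(1))
  # each shift sits within binomial sampling error of the planted 0.25: with
  # 60 variants a rare ~3 sigma excursion is expected, none beyond 4
  expect_true(all(z < 4))
  expect_gte(mean(z < 3), 0.9)
})

test_that("the full-null configuration produces uniform association p-values", {
  assoc <- null_assoc()
  p <- assoc$p_value[assoc$converged]
  expect_gt(length(p), 250)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("no-signal cohorts give chance-level planted-cluster recovery", {
  cfg <- cohort_config(n_cases = 100, n_controls = 100, n_variants = 120,
                       n_risk_variants = 10, n_subtype_variants = 15,
                       subtype_freq_shift = 0, phenotype_shift = 0, seed = 3)
  ch <- generate_cohort(cfg)
  cases <- names(ch$status)[ch$status == 1]
  A <- suppressMessages(
    build_feature_matrix(ch$genotypes, colnames(ch$genotypes)[1:60], cases))
  fit <- nmf_brunet(A, K = 2, seed = 5, max_iter = 600)
  labels <- assign_clusters(fit$H)$cluster
  truth <- ch$truth_subtype[colnames(A)]
  expect_lt(abs(ari_manual(labels, truth)), 0.1)
})

test_that("annotation generation hits the deleterious fraction and is seeded", {
  cfg <- cohort_config(n_variants = 400, seed = 2)
  is_del <- function(ann)
    apply(ann[, c("class_source1", "class_source2", "class_source3")], 1,
          function(r) any(r %in% c("nonsynonymous", "stopgain", "stoploss")))

  none <- generate_annotation(cfg, deleterious_fraction = 0)
  expect_false(any(is_del(none)))
  all_del <- generate_annotation(cfg, deleterious_fraction = 1)
  expect_true(all(is_del(all_del)))

  ann <- generate_annotation(cfg, deleterious_fraction = 0.3)
  expect_lt(abs(mean(is_del(ann)) - 0.3), 0.05)
  expect_identical(ann, generate_annotation(cfg, deleterious_fraction = 0.3))
  expect_true(all(ann$reference_freq > 0 & ann$reference_freq < 1))

  # reference frequencies track the generating frequencies
  ch <- generate_cohort(cfg)
  expect_lt(max(abs(ann$reference_freq - ch$variant_info$base_freq)), 0.01)
})
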