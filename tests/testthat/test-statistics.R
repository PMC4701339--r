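# Rank-sum comparison, Spearman correlation, and the report stage.

test_that("the exact rank-sum p matches full enumeration for separated groups", {
  a <- c(1, 2, 3, 4); b <- c(10, 11, 12, 13)
  got <- rank_sum_compare(a, b)
  expect_equal(got$p_value, oracle_ranksum_exact_p(a, b))
  expect_equal(got$p_value, 2 / 70)
  # a non-extreme configuration as well
  a2 <- c(1, 4, 6, 9); b2 <- c(2, 3, 7, 12)
  expect_equal(rank_sum_compare(a2, b2)$p_value, oracle_ranksum_exact_p(a2, b2))
})

test_that("identical groups are maximally non-significant", {
  got <- rank_sum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(got$p_value, 1)
  expect_false(got$degenerate)
  const <- rank_sum_compare(c(2, 2, 2), c(2, 2, 2))
  expect_true(const$degenerate)
  expect_true(is.na(const$p_value))
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(41)
  a <- rnorm(12); b <- rnorm(15, mean = 0.5)
  expect_equal(rank_sum_compare(a, b)$p_value,
               rank_sum_compare(exp(a), exp(b))$p_value, tolerance = 1e-12)
})

test_that("spearman correlation handles monotone, reversed, and random inputs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_corr(x, 2 * x + 1)$estimate, 1)
  expect_equal(spearman_corr(x, -x^3)$estimate, -1)
  expect_equal(spearman_corr(x, 2 * x + 1)$p_value, 0)

  set.seed(42)
  u <- rnorm(10); v <- rnorm(10)
  got <- spearman_corr(u, v)
  ref <- suppressWarnings(stats::cor.test(u, v, method = "spearman", exact = FALSE))
  expect_equal(got$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$estimate, cor(rank(u), rank(v)), tolerance = 1e-12)
  # symmetry and monotone-transform invariance
  expect_equal(spearman_corr(v, u)$estimate, got$estimate)
  expect_equal(spearman_corr(exp(u), v)$estimate, got$estimate)
  expect_error(spearman_corr(u, v[1:5]), class = "fallrisk_parameter_error")
})

test_that("correlation categories follow the half-open magnitude bands", {
  expect_identical(as.character(categorize_correlation(0.547)), "high")
  expect_identical(as.character(categorize_correlation(0.493)), "moderate")
  expect_identical(as.character(categorize_correlation(-0.05)), "negligible")
  expect_identical(as.character(categorize_correlation(c(0.5, 0.3, 0.1, -0.6))),
                   c("high", "moderate", "weak", "high"))
  expect_identical(as.character(categorize_correlation(0.2999)), "weak")
  expect_error(categorize_correlation(1.2), class = "fallrisk_parameter_error")
})

test_that("the comparison report has one row per channel and a symmetric correlation matrix", {
  set.seed(43)
  fe <- make_feature_table(12, 10, rep(0.3, 8), rep(0.35, 8), sd = 0.08)
  rep_ <- comparison_report(fe, selected = grf_channels()$feature)
  expect_equal(nrow(rep_$comparison), 8)
  expect_equal(rep_$comparison$feature, grf_channels()$feature)
  M <- rep_$corr_matrix
  expect_equal(M, t(M), tolerance = 1e-12)
  expect_equal(unname(diag(M)), rep(1, 8))
  expect_s3_class(autoplot(rep_), "ggplot")
  expect_equal(tidy(rep_), rep_$comparison)
  expect_equal(glance(rep_)$n_features, 8)
})

test_that("a constant feature column is flagged degenerate, not fatal", {
  set.seed(44)
  fe <- make_feature_table(6, 6, rep(0.3, 8), rep(0.4, 8), sd = 0.05)
  fe$L_ML_F <- 0.25
  rep_ <- comparison_report(fe, selected = grf_channels()$feature)
  row <- rep_$comparison[rep_$comparison$feature == "L_ML_F", ]
  expect_true(row$degenerate)
  expect_false(row$significant)
})

test_that("group differences planted in the sit-to-stand channels are the ones starred", {
  tg <- default_entropy_targets()
  mu_f <- tg$mean[tg$group == "faller"]
  mu_n <- tg$mean[tg$group == "nonfaller"]
  # separation only in channels 7-8 (L_V_F, R_V_F); others share means
  mu_f[1:6] <- mu_n[1:6]
  v_hits <- 0L
  false_stars <- 0L
  set.seed(45)
  for (rep in 1:10) {
    fe <- make_feature_table(100, 100, mu_f, mu_n, sd = 0.032)
    rep_ <- comparison_report(fe, alpha = 0.1)
    starred <- rep_$comparison$feature[rep_$comparison$significant]
    if (all(c("L_V_F", "R_V_F") %in% starred)) v_hits <- v_hits + 1L
    false_stars <- false_stars + length(setdiff(starred, c("L_V_F", "R_V_F")))
  }
  # the planted channels are starred essentially always; null channels only
  # at the type-I rate (6 nulls at alpha = 0.1 -> ~0.6 false stars per run)
  expect_gte(v_hits, 9L)
  expect_lte(false_stars / 10, 1.5)
})
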