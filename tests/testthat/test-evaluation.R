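# LOOCV scoring, subset enumeration, and the sensitivity-first selection.

test_that("metric edge cases: perfect classifier and zero denominators", {
  perfect <- classification_metrics(tp = 14, fn = 0, fp = 0, tn = 24)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  zd <- classification_metrics(tp = 0, fn = 0, fp = 2, tn = 3)
  expect_true(is.na(zd$sensitivity))
  expect_equal(zd$specificity, 0.6)
  expect_error(classification_metrics(tp = -1, fn = 0, fp = 0, tn = 1),
               class = "fallrisk_parameter_error")
})

test_that("LOOCV on a 4-point set matches the hand-traced folds", {
  # interleaved groups: every held-out point's nearest neighbour is from
  # the other class, so 1-NN LOOCV gets everything wrong
  bad <- tibble::tibble(group = c("faller", "faller", "nonfaller", "nonfaller"),
                        x = c(0, 10, 1, 11))
  for (m in fall_classifiers()) {
    cm <- loocv_confusion(bad, classifier = m, k = 1)
    expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(0, 2, 2, 0))
  }
  # separated groups: every fold is classified correctly
  good <- tibble::tibble(group = c("faller", "faller", "nonfaller", "nonfaller"),
                         x = c(0, 1, 10, 11))
  cm <- loocv_confusion(good, classifier = "lmpnn", k = 1)
  expect_equal(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2, 0, 0, 2))
})

test_that("LOOCV confusion satisfies the margin identities and is deterministic", {
  set.seed(31)
  fe <- make_feature_table(9, 7, rep(0.3, 8), rep(0.4, 8), sd = 0.1)
  for (m in fall_classifiers()) {
    cm <- loocv_confusion(fe, classifier = m, k = 2)
    expect_equal(cm$tp + cm$fn, 9)
    expect_equal(cm$fp + cm$tn, 7)
  }
  expect_identical(loocv_confusion(fe, "pnn", 3), loocv_confusion(fe, "pnn", 3))
})

test_that("widely separated groups give a perfect LOOCV confusion", {
  set.seed(32)
  fe <- make_feature_table(8, 6, rep(0.2, 8), rep(0.8, 8), sd = 0.05)
  for (m in fall_classifiers()) {
    cm <- loocv_confusion(fe, classifier = m, k = 2)
    expect_equal(c(cm$tp, cm$tn), c(8, 6))
  }
})

test_that("with permuted labels LOOCV accuracy hovers near chance", {
  set.seed(33)
  fe <- make_feature_table(10, 10, rep(0.2, 8), rep(0.8, 8), sd = 0.05)
  acc <- replicate(20, {
    perm <- fe
    perm$group <- sample(perm$group)
    loocv_confusion(perm, classifier = "lmknn", k = 1)$accuracy
  })
  expect_gt(mean(acc), 0.2)
  expect_lt(mean(acc), 0.8)
})

test_that("subset enumeration is complete, distinct, and ordered", {
  s3 <- enumerate_subsets(3)
  expect_identical(s3, list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L),
                            1:3))
  expect_identical(enumerate_subsets(1), list(1L))
  s8 <- enumerate_subsets(8)
  expect_length(s8, 255)
  expect_length(unique(s8), 255)
  expect_true(all(lengths(s8) >= 1))
})

eval_row <- function(subset_id, size, k, sens, acc, spec, classifier = "pnn") {
  tibble::tibble(subset_id = subset_id, subset = as.character(subset_id),
                 size = size, classifier = classifier, k = k,
                 accuracy = acc, sensitivity = sens, specificity = spec)
}

test_that("selection puts sensitivity before accuracy and prefers small subsets", {
  evals <- dplyr::bind_rows(
    eval_row(1, 2, 1, sens = 0.9, acc = 0.70, spec = 0.9),
    eval_row(2, 2, 1, sens = 0.8, acc = 0.99, spec = 0.9))
  expect_equal(select_best(evals)$subset_id, 1)
  expect_equal(select_best(evals, selection = "accuracy_first")$subset_id, 2)

  ties <- dplyr::bind_rows(
    eval_row(10, 5, 1, 0.9, 0.9, 0.9),
    eval_row(11, 4, 1, 0.9, 0.9, 0.9))
  expect_equal(select_best(ties)$subset_id, 11)

  single <- eval_row(7, 3, 2, 0.5, 0.5, 0.5)
  expect_equal(select_best(single)$subset_id, 7)

  # duplicating the winner never changes the outcome (total order)
  dup <- dplyr::bind_rows(ties, ties[2, ])
  expect_equal(select_best(dup)$subset_id, 11)

  # undefined sensitivity ranks below any defined value
  nas <- dplyr::bind_rows(
    eval_row(1, 1, 1, NA_real_, 1, 1),
    eval_row(2, 1, 1, 0.1, 0.1, 0.1))
  expect_equal(select_best(nas)$subset_id, 2)

  expect_error(select_best(evals[0, ]), class = "fallrisk_parameter_error")
  mixed <- dplyr::bind_rows(eval_row(1, 1, 1, 1, 1, 1, "pnn"),
                            eval_row(2, 1, 1, 1, 1, 1, "lmknn"))
  expect_error(select_best(mixed), class = "fallrisk_parameter_error")
})

test_that("all k values sharing the winning metrics are reported", {
  evals <- dplyr::bind_rows(lapply(1:4, function(k) eval_row(3, 2, k, 0.9, 0.9, 1)))
  evals <- dplyr::bind_rows(evals, eval_row(3, 2, 5, 0.8, 0.9, 1))
  expect_equal(select_best(evals)$k_values, "1/2/3/4")
})

test_that("the search grid agrees with fold-by-fold classification through the R rules", {
  set.seed(34)
  fe <- make_feature_table(6, 5, rep(0.35, 8), rep(0.45, 8), sd = 0.08)
  fs <- full_search(fe, k_max = 3)
  X <- as.matrix(fe[, grf_channels()$feature])
  y <- factor(fe$group, levels = c("faller", "nonfaller"))
  classify <- list(lmknn = lmknn_classify, pnn = pnn_classify, lmpnn = lmpnn_classify)
  some <- fs$grid[fs$grid$subset_id %in% c(3, 40, 200), ]
  for (ri in seq_len(nrow(some))) {
    row <- some[ri, ]
    cols <- split_subset(row$subset)
    Xs <- X[, cols, drop = FALSE]
    pred <- vapply(seq_len(nrow(Xs)), function(i) {
      as.character(classify[[row$classifier]](Xs[i, ], Xs[-i, , drop = FALSE],
                                              y[-i], row$k))
    }, character(1))
    expect_equal(row$tp, sum(pred == "faller" & y == "faller"))
    expect_equal(row$tn, sum(pred == "nonfaller" & y == "nonfaller"))
  }
})

test_that("a perfectly separating feature is always recovered with perfect metrics", {
  set.seed(35)
  mu_f <- rep(0.4, 8); mu_n <- rep(0.4, 8)
  mu_f[7] <- 0.1; mu_n[7] <- 0.9  # plant the signal in L_V_F only
  fe <- make_feature_table(10, 8, mu_f, mu_n, sd = 0.05)
  fs <- full_search(fe, k_max = 5)
  for (ri in seq_len(nrow(fs$best))) {
    expect_equal(fs$best$sensitivity[ri], 1)
    expect_equal(fs$best$specificity[ri], 1)
    expect_true("L_V_F" %in% split_subset(fs$best$subset[ri]))
  }
})

test_that("the search handles two subjects per class and is deterministic", {
  set.seed(36)
  fe <- make_feature_table(2, 2, rep(0.3, 8), rep(0.5, 8), sd = 0.05)
  fs1 <- full_search(fe, k_max = 10)
  fs2 <- full_search(fe, k_max = 10)
  expect_equal(fs1$k_max, 1)  # capped at smallest class size - 1
  expect_identical(fs1$grid, fs2$grid)
})

test_that("tidy, glance and autoplot expose the search results", {
  set.seed(37)
  fe <- make_feature_table(5, 4, rep(0.3, 8), rep(0.5, 8), sd = 0.1)
  fs <- full_search(fe, k_max = 2)
  expect_identical(tidy(fs), fs$grid)
  expect_identical(glance(fs), fs$best)
  expect_s3_class(autoplot(fs), "ggplot")
})
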