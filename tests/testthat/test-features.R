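# Preprocessing and the sample-entropy feature pipeline.

test_that("standardization matches the closed form and is idempotent", {
  expect_equal(standardize_series(c(1, 2, 3)),
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  z <- standardize_series(rnorm(100))
  expect_equal(standardize_series(z), z, tolerance = 1e-9)
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-9)
  expect_error(standardize_series(c(5, 5, 5)), class = "fallrisk_degenerate_error")
})

test_that("weight normalization is a pure rescaling and vanishes after standardization", {
  expect_equal(normalize_by_weight(rep(686.7, 10), 70), rep(1, 10))
  s <- runif(50, 100, 900)
  expect_equal(normalize_by_weight(s, 63) * 63 * 9.81, s)
  expect_equal(standardize_series(normalize_by_weight(s, 63)),
               standardize_series(s), tolerance = 1e-12)
  expect_error(normalize_by_weight(s, 0), class = "fallrisk_parameter_error")
})

test_that("sample entropy agrees with the direct pair-count oracle", {
  set.seed(77)
  for (case in 1:24) {
    n <- sample(10:120, 1)
    m <- sample(1:2, 1)
    r <- sample(c(0.1, 0.25), 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                standardize_series(sin(2 * pi * (1:n) / 20) + rnorm(n, sd = 0.3)),
                runif(n, -2, 2))
    got <- sample_entropy_counts(x, m = m, r = r)
    ref <- oracle_sampen_counts(x, m, r)
    expect_identical(got$A, as.double(ref$A))
    expect_identical(got$B, as.double(ref$B))
  }
})

test_that("sample entropy is invariant to affine rescaling and near-invariant to reversal", {
  set.seed(8)
  for (i in 1:10) {
    s <- rnorm(150)
    c0 <- runif(1, 0.1, 50) * sample(c(-1, 1), 1)
    d0 <- runif(1, -10, 10)
    expect_equal(sample_entropy(standardize_series(c0 * s + d0)),
                 sample_entropy(standardize_series(s)), tolerance = 1e-12)
    # the (m+1)-point templates of the reversed series are exactly the
    # reversed originals, so A is strictly symmetric; B uses N - m of the
    # N - m + 1 m-point windows, so reversal swaps which window is left
    # out and the entropy can shift by a boundary term of order 1/N
    fwd <- sample_entropy_counts(s, 2, 0.25)
    bwd <- sample_entropy_counts(rev(s), 2, 0.25)
    expect_identical(bwd$A, fwd$A)
    expect_lt(abs(-log(bwd$A / bwd$B) + log(fwd$A / fwd$B)), 0.05)
  }
})

test_that("sample entropy returns the undefined sentinel when no (m+1)-match exists", {
  # one m-template pair matches but diverges at the next point
  x <- c(0, 0.1, 5, 0.1, 0, 9)
  cnt <- sample_entropy_counts(x, m = 2, r = 0.25)
  expect_gt(cnt$B, 0)
  expect_identical(cnt$A, 0)
  expect_true(is.na(sample_entropy(x, m = 2, r = 0.25)))
  expect_error(sample_entropy(c(1, 2, 3), m = 2), class = "fallrisk_parameter_error")
})

make_manual_cohort <- function(n_len = 150, seed = 3) {
  ch <- grf_channels()
  set.seed(seed)
  recordings <- dplyr::bind_rows(lapply(c("S1", "S2"), function(sid) {
    tibble::tibble(
      subject_id = sid,
      activity = ch$activity, foot = ch$foot, axis = ch$axis,
      feature = ch$feature,
      series = lapply(seq_len(nrow(ch)),
                      function(i) 300 + 50 * sin(2 * pi * (1:n_len) / 25) + rnorm(n_len, sd = 20))
    )
  }))
  list(metadata = tibble::tibble(subject_id = c("S1", "S2"),
                                 group = c("faller", "nonfaller"),
                                 weight_kg = c(70, 55)),
       recordings = recordings)
}

test_that("extract_features returns 8 finite entropies per subject in channel order", {
  co <- make_manual_cohort()
  fe <- extract_features(co)
  expect_equal(names(fe), c("subject_id", "group", grf_channels()$feature))
  vals <- as.matrix(fe[, grf_channels()$feature])
  expect_true(all(is.finite(vals)) && all(vals >= 0))
})

test_that("a missing channel is reported by name", {
  co <- make_manual_cohort()
  co$recordings <- co$recordings[co$recordings$feature != "R_V_F" |
                                   co$recordings$subject_id != "S2", ]
  expect_error(extract_features(co), "R_V_F")
})

test_that("entropies do not depend on whether weight normalization is applied", {
  co <- make_manual_cohort()
  f1 <- extract_features(co, weight_normalize = TRUE)
  f2 <- extract_features(co, weight_normalize = FALSE)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("multi-trial channels are entropy-averaged in average mode and rejected in single mode", {
  co <- make_manual_cohort()
  extra <- co$recordings[co$recordings$subject_id == "S1" &
                           co$recordings$feature == "L_ML_F", ]
  set.seed(9)
  extra$series <- list(400 + 40 * sin(2 * pi * (1:150) / 30) + rnorm(150, sd = 15))
  co2 <- co
  co2$recordings <- dplyr::bind_rows(co$recordings, extra)
  expect_error(extract_features(co2, trial_mode = "single"), "trials")
  fe <- extract_features(co2, trial_mode = "average")
  e1 <- sample_entropy(standardize_series(
    co$recordings$series[co$recordings$subject_id == "S1" &
                           co$recordings$feature == "L_ML_F"][[1]]))
  e2 <- sample_entropy(standardize_series(extra$series[[1]]))
  expect_equal(fe$L_ML_F[fe$subject_id == "S1"], mean(c(e1, e2)), tolerance = 1e-12)
})
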