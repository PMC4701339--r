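# Independent reference implementations used to cross-check the package.
# These are deliberately naive transliterations of the definitions and are
# never shared with the production code paths.

# Direct pair-count sample entropy: embed, compare every ordered pair.
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  E <- sapply(0:m, function(l) x[(1:nt) + l])  # nt x (m + 1) embeddings
  A <- 0L
  B <- 0L
  for (i in seq_len(nt)) {
    dm <- abs(E[, 1] - E[i, 1])
    if (m >= 2) {
      for (l in 2:m) dm <- pmax(dm, abs(E[, l] - E[i, l]))
    }
    dm1 <- pmax(dm, abs(E[, m + 1] - E[i, m + 1]))
    B <- B + sum(dm <= r) - 1L   # remove the self-match
    A <- A + sum(dm1 <= r) - 1L
  }
  list(A = A, B = B)
}

oracle_sampen <- function(x, m, r) {
  cnt <- oracle_sampen_counts(x, m, r)
  if (cnt$A == 0 || cnt$B == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

# Transliterated per-class scores of the three decision rules, written as
# plain loops over the defining equations.
oracle_class_scores <- function(x, train, labels, k) {
  labels <- factor(labels)
  classes <- levels(labels)
  euc <- function(a, b) sqrt(sum((a - b)^2))
  out <- list(lmknn = numeric(length(classes)),
              pnn = numeric(length(classes)),
              lmpnn = numeric(length(classes)))
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    d <- vapply(idx, function(j) euc(train[j, ], x), numeric(1))
    ord <- order(d)  # stable: ties keep ascending original index
    kk <- min(k, length(idx))
    nb <- train[idx[ord][seq_len(kk)], , drop = FALSE]
    ds <- d[ord][seq_len(kk)]
    # local mean of the k nearest neighbours
    out$lmknn[ci] <- euc(colMeans(nb), x)
    # 1/j weighted distance sum
    s <- 0
    for (j in seq_len(kk)) s <- s + (1 / j) * ds[j]
    out$pnn[ci] <- s
    # 1/j weighted distances to cumulative local means
    s <- 0
    for (j in seq_len(kk)) {
      s <- s + (1 / j) * euc(colMeans(nb[seq_len(j), , drop = FALSE]), x)
    }
    out$lmpnn[ci] <- s
  }
  out
}

# Exact two-sided rank-sum p-value by full enumeration of the group-A rank
# assignments (tie-free data only).
oracle_ranksum_exact_p <- function(a, b) {
  n_a <- length(a)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(length(pooled), n_a)
  u_all <- apply(combs, 2, function(ix) sum(rk[ix]) - n_a * (n_a + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Random small labelled dataset for classifier checks.
random_dataset <- function(n_class = sample(2:3, 1), d = sample(1:4, 1),
                           per_class = sample(2:8, 1)) {
  n <- n_class * per_class
  X <- matrix(rnorm(n * d, sd = 2), n, d)
  y <- factor(rep(letters[seq_len(n_class)], each = per_class))
  list(X = X, y = y, query = rnorm(d, sd = 2))
}

# Feature table drawn directly from per-group normal entropy levels (skips
# the signal-generation stage; for evaluation / statistics checks).
make_feature_table <- function(n_faller, n_nonfaller,
                               faller_mean, nonfaller_mean, sd = 0.05) {
  ch <- grf_channels()$feature
  stopifnot(length(faller_mean) == 8, length(nonfaller_mean) == 8)
  draw <- function(n, mu) {
    vapply(seq_along(ch), function(ci) rnorm(n, mu[ci], sd), numeric(n))
  }
  Xf <- draw(n_faller, faller_mean)
  Xn <- draw(n_nonfaller, nonfaller_mean)
  out <- tibble::as_tibble(as.data.frame(rbind(Xf, Xn)))
  names(out) <- ch
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n_faller + n_nonfaller)),
      group = c(rep("faller", n_faller), rep("nonfaller", n_nonfaller))),
    out)
}

# Cohort entropy targets with group separation planted only in `planted`.
planted_targets <- function(planted = c("L_SI_F", "R_ML_F", "R_AP_F", "L_V_F"),
                            faller_mean = 0.30, nonfaller_mean = 0.38,
                            base_mean = 0.45, sd = 0.06) {
  ch <- grf_channels()$feature
  fm <- ifelse(ch %in% planted, faller_mean, base_mean)
  nm <- ifelse(ch %in% planted, nonfaller_mean, base_mean)
  dplyr::bind_rows(
    tibble::tibble(feature = ch, group = "faller", mean = fm, sd = sd),
    tibble::tibble(feature = ch, group = "nonfaller", mean = nm, sd = sd))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

split_subset <- function(label) strsplit(label, "+", fixed = TRUE)[[1]]
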