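test_that("SoS contrast follows the median arithmetic of inclusion vs ring", {
  g <- imaging_grid(15, 15, 1, 1)
  vals <- matrix(1500, 15, 15)
  inc <- matrix(FALSE, 15, 15); inc[7:9, 7:9] <- TRUE
  ring <- ring_background_mask(inc, g, 5)

  # constant map: no contrast
  expect_equal(sos_contrast(sos_map(vals, g), inc)$delta_c, 0)

  # planted values: medians 1550 (inclusion) and 1505 (ring)
  v2 <- vals
  incv <- rep(c(1540, 1550, 1560), length.out = sum(inc))
  ringv <- rep(c(1500, 1500, 1510, 1520), length.out = sum(ring))
  v2[inc] <- incv; v2[ring] <- ringv
  ct <- sos_contrast(sos_map(v2, g), inc)
  expect_equal(ct$c_inc_median, median(incv))
  expect_equal(ct$c_bkg_median, median(ringv))
  expect_equal(ct$delta_c, abs(median(incv) - median(ringv)))

  # contrast is symmetric: inclusion brighter or darker gives the same delta_c
  v3 <- vals; v3[inc] <- 1500 - (incv - 1500); v3[ring] <- ringv
  ct3 <- sos_contrast(sos_map(v3, g), inc)
  v4 <- vals; v4[inc] <- incv; v4[ring] <- ringv
  expect_equal(ct3$delta_c,
               abs(median(1500 - (incv - 1500)) - median(ringv)))
  expect_error(sos_contrast(sos_map(vals, g), matrix(FALSE, 15, 15)), "empty inclusion")
})

test_that("RMSE matches the naive loop oracle and closed forms", {
  g <- imaging_grid(4, 4, 1, 1)
  a <- matrix(runif(16, 1400, 1600), 4, 4)
  expect_equal(rmse(sos_map(a, g), sos_map(a, g)), 0)
  expect_equal(rmse(a + 10, a), 10)
  set.seed(4)
  b <- a + rnorm(16, sd = 5)
  acc <- 0
  for (i in 1:4) for (j in 1:4) acc <- acc + (a[i, j] - b[i, j])^2
  expect_equal(rmse(b, a), sqrt(acc / 16), tolerance = 1e-12)
  expect_error(rmse(a, a[1:3, ]), "shape mismatch")
})

test_that("ROC/AUC agrees with exhaustive pair counting and handles boundary cases", {
  # worked example: concordant pairs 3 of 4
  rep1 <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(rep1$auc, 0.75)

  # perfectly separated and uninformative scorers
  expect_equal(roc_auc(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  # randomized agreement with the exhaustive oracle, including ties
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(runif(n, 0, 1), 1))  # coarse grid forces ties
    expect_equal(roc_auc(scores, labels)$auc, auc_pair_oracle(scores, labels),
                 tolerance = 1e-12)
  }

  # operating point maximizes sens + spec; F1/sens/spec are consistent there
  sc <- c(0.1, 0.2, 0.6, 0.7, 0.8); lb <- c(0, 0, 1, 1, 0)
  rp <- roc_auc(sc, lb)
  sums <- sapply(sort(unique(sc)), function(t) {
    sum(sc >= t & lb == 1) / 2 + sum(sc < t & lb == 0) / 3
  })
  expect_equal(rp$sensitivity + rp$specificity, max(sums))
  tp <- sum(sc >= rp$threshold & lb == 1)
  fp <- sum(sc >= rp$threshold & lb == 0)
  fn <- sum(sc < rp$threshold & lb == 1)
  expect_equal(rp$f1, tp / (tp + 0.5 * (fp + fn)))

  # AUC equals U / (n_pos * n_neg) from the rank-sum statistic
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- rnorm(n)
    U <- rank_sum_test(scores[labels == 1], scores[labels == 0])$statistic
    expect_equal(roc_auc(scores, labels)$auc,
                 U / (sum(labels) * sum(!labels)), tolerance = 1e-12)
  }
})

test_that("rank-sum p-values match exhaustive permutation enumeration", {
  # fully separated toy case: U = 0, exact two-sided p = 1/3
  rs <- rank_sum_test(c(1, 2), c(10, 11))
  expect_equal(rs$statistic, 0)
  expect_equal(rs$p_value, 1 / 3, tolerance = 1e-12)

  # identical groups are exchangeable: p = 1
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)

  # enumeration oracle on random continuous inputs (combined n <= 10)
  set.seed(31)
  for (rep in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = runif(1, -1, 1))
    expect_equal(rank_sum_test(a, b)$p_value, ranksum_perm_oracle(a, b),
                 tolerance = 1e-10)
  }

  # rank-based: invariant under strictly monotone transforms
  a <- c(0.3, 1.4, 2.2); b <- c(0.9, 3.1, 4.0, 5.5)
  expect_equal(rank_sum_test(exp(a), exp(b))$p_value, rank_sum_test(a, b)$p_value)
  expect_equal(rank_sum_test(exp(a), exp(b))$statistic, rank_sum_test(a, b)$statistic)
})
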