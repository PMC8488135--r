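test_that("paired t matches the textbook formula and stats::t.test", {
  y <- c(10, 12, 9, 14)
  x <- y + c(1, 2, 3, 4)
  res <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # Bonferroni-corrected default threshold for three comparisons
  expect_equal(res$alpha, 0.05 / 3, tolerance = 1e-12)
  expect_lt(abs(res$alpha - 0.0167), 2e-4)
})

test_that("degenerate paired data raise a statistic-undefined error", {
  x <- c(1, 2, 3)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x, x + 5), "zero variance")
  expect_error(paired_t(1, 2), "n >= 2")
})

test_that("ICC(A,k) is exact for identical columns and penalizes offsets", {
  set.seed(81)
  v <- rnorm(30, 100, 20)
  expect_equal(icc_a_k(cbind(v, v, v))$icc, 1, tolerance = 1e-12)
  shifted <- icc_a_k(cbind(v, v + 15, v))
  expect_lt(shifted$icc, 1)
  expect_error(icc_a_k(cbind(v, ifelse(seq_along(v) == 1, NA, v))), "missing")
  expect_error(icc_a_k(matrix(1:2, 1)), "n >= 2")
})

test_that("ICC(A,k) matches an independent aov mean-squares decomposition", {
  set.seed(82)
  for (i in 1:5) {
    X <- matrix(rnorm(70 * 3, 100, 15), 70, 3) + rnorm(70, 0, 25)
    df <- data.frame(y = as.vector(X),
                     subj = factor(rep(seq_len(70), 3)),
                     meth = factor(rep(1:3, each = 70)))
    ms <- summary(aov(y ~ subj + meth, data = df))[[1]][["Mean Sq"]]
    icc_oracle <- (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / 70)
    expect_equal(icc_a_k(X)$icc, icc_oracle, tolerance = 1e-10)
  }
})

test_that("ICC decreases monotonically as noise is added", {
  set.seed(83)
  base <- matrix(rep(rnorm(40, 100, 20), 3), 40, 3)
  noise <- matrix(rnorm(120), 40, 3)
  iccs <- sapply(c(0.5, 2, 8, 20), function(s) icc_a_k(base + s * noise)$icc)
  expect_true(all(diff(iccs) < 0))
})

test_that("two-method Bland-Altman recovers closed-form bias and limits", {
  x <- c(1, 2, 3)
  res0 <- bland_altman_two(x, x)
  expect_equal(res0$bias, 0)
  expect_equal(unname(res0$loa), c(0, 0))
  expect_error(bland_altman_two(1:2, 1:2), "n >= 3")

  set.seed(84)
  y <- rnorm(10000, 100, 10)
  x2 <- y + rnorm(10000, 5, 2)
  res <- bland_altman_two(x2, y)
  expect_equal(res$bias, 5, tolerance = 0.1)
  expect_equal(res$half_width, 1.96 * 2, tolerance = 0.1)
  # adding a constant shifts bias and both limits by exactly that constant
  res_c <- bland_altman_two(x2 + 7, y)
  expect_equal(res_c$bias, res$bias + 7, tolerance = 1e-12)
  expect_equal(unname(res_c$loa), unname(res$loa) + 7, tolerance = 1e-12)
})

test_that("multi-method Bland-Altman matches its closed-form structure", {
  set.seed(85)
  X0 <- matrix(rep(rnorm(20, 100, 10), 3), 20, 3)
  res0 <- bland_altman_multi(X0)
  expect_true(all(abs(res0$bias) < 1e-12))
  expect_equal(res0$half_width, 0)
  expect_error(bland_altman_multi(X0[, 1:2]), "k >= 3")

  n <- 10000; k <- 3; sigma <- 4
  b <- c(-2, 5, -3)  # method offsets summing to zero
  s <- rnorm(n, 120, 25)
  X <- outer(s, rep(1, k)) + outer(rep(1, n), b) +
    matrix(rnorm(n * k, 0, sigma), n, k)
  res <- bland_altman_multi(X)
  expect_lt(abs(sum(res$bias)), 1e-12)  # algebraic identity
  expect_equal(unname(res$bias), b, tolerance = 0.2)
  expect_equal(res$half_width, 1.96 * sigma * sqrt((k - 1) / k),
               tolerance = 0.02 * 1.96 * sigma)
})

test_that("agreement statistics are invariant under subject reordering", {
  set.seed(86)
  X <- matrix(rnorm(60, 100, 15), 20, 3)
  perm <- sample(20)
  expect_equal(icc_a_k(X)$icc, icc_a_k(X[perm, ])$icc, tolerance = 1e-12)
  expect_equal(bland_altman_multi(X)$half_width,
               bland_altman_multi(X[perm, ])$half_width, tolerance = 1e-12)
  pt1 <- paired_t(X[, 1], X[, 2]); pt2 <- paired_t(X[perm, 1], X[perm, 2])
  expect_equal(pt1$t, pt2$t, tolerance = 1e-12)
})
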