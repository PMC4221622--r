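test_that("signed-rank statistic follows direct ranking rules", {
  # all differences positive: W = sum of all ranks
  r1 <- wilcoxon_signed_mc(c(2, 4, 6), c(1, 2, 3), n_rand = 99, seed = 1)
  expect_equal(r1$statistic, 6)
  expect_equal(r1$n_pairs_used, 3)

  # zero differences dropped, midranks for tied |d|
  r2 <- wilcoxon_signed_mc(c(5, 5, 3, 1), c(5, 4, 4, 3), n_rand = 99,
                           seed = 1)
  # d = (0, 1, -1, -2): drop 0; |d| ranks = (1.5, 1.5, 3); W over d>0 = 1.5
  expect_equal(r2$statistic, 1.5)
  expect_equal(r2$n_pairs_used, 3)

  expect_warning(res <- wilcoxon_signed_mc(1:4, 1:4, n_rand = 9, seed = 1),
                 "degenerate")
  expect_equal(res$p_value, 1)
  expect_error(wilcoxon_signed_mc(1:3, 1:2), "paired")
})

test_that("signed-rank W matches the classical statistic from wilcox.test", {
  withr::with_seed(2, {
    x <- rnorm(15); y <- rnorm(15)
  })
  ours <- wilcoxon_signed_mc(x, y, n_rand = 99, seed = 3)
  classical <- suppressWarnings(wilcox.test(x, y, paired = TRUE))
  expect_equal(ours$statistic, unname(classical$statistic))
})

test_that("Monte Carlo signed-rank p converges to the 2^m enumeration", {
  withr::with_seed(4, {
    x <- rnorm(12, mean = 0.6)
    y <- rnorm(12)
  })
  ex <- wilcoxon_signed_exact(x, y)
  expect_equal(ex$n_randomizations, 0)
  mc <- wilcoxon_signed_mc(x, y, n_rand = 20000, seed = 5)
  expect_equal(mc$statistic, ex$statistic)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 20000)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / 20000)

  # and the exact version agrees with wilcox.test's exact p when there are
  # no ties or zeros
  withr::with_seed(6, {
    x2 <- rnorm(10); y2 <- rnorm(10)
  })
  expect_equal(wilcoxon_signed_exact(x2, y2)$p_value,
               wilcox.test(x2, y2, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("sign test matches the closed-form and cumulative-binomial oracle", {
  # every pair positive, m = 5: p = 2 * (1/2)^5
  r <- sign_test(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 5)
  expect_equal(r$p_value, 2 * (1 / 2)^5)

  # a balanced split caps at 1
  expect_equal(sign_test(c(1, 2, 5, 6), c(3, 4, 2, 3))$p_value, 1)

  # ties are excluded from m
  rt <- sign_test(c(1, 5, 5), c(1, 2, 2))
  expect_equal(rt$n_pairs_used, 2)

  expect_warning(res <- sign_test(1:3, 1:3), "degenerate")
  expect_equal(res$p_value, 1)

  # independent oracle: doubled smaller binomial tail, all m <= 40, all s
  for (m in c(1:12, 20, 36, 40)) {
    for (s in 0:m) {
      x <- c(rep(1, s), rep(-1, m - s))
      got <- sign_test(x, rep(0, m))$p_value
      lower <- sum(choose(m, 0:s)) / 2^m
      upper <- sum(choose(m, s:m)) / 2^m
      expect_equal(got, min(1, 2 * min(lower, upper)), tolerance = 1e-12)
    }
  }
})

test_that("Mann-Whitney min-U behaves at the extremes and matches wilcox.test", {
  sep <- mann_whitney_mc(c(1, 2), c(3, 4), n_rand = 99, seed = 1)
  expect_equal(sep$statistic, 0)

  same <- mann_whitney_mc(1:10, 1:10, n_rand = 999, seed = 2)
  expect_gt(same$p_value, 0.5)

  withr::with_seed(3, {
    x <- rnorm(9); y <- rnorm(13, 1)
  })
  ours <- mann_whitney_mc(x, y, n_rand = 99, seed = 4)
  u_x <- unname(wilcox.test(x, y)$statistic)
  expect_equal(ours$statistic, min(u_x, length(x) * length(y) - u_x))
  expect_error(mann_whitney_mc(numeric(0), 1:3), "nonempty")
})

test_that("Monte Carlo U p converges to the exact permutation p on small samples", {
  withr::with_seed(5, {
    x <- rnorm(5, 1.2); y <- rnorm(5)
  })
  # exact two-sided p via full enumeration of assignments
  pooled <- c(x, y)
  rk <- rank(pooled)
  nx <- 5; ny <- 5
  combos <- combn(10, nx)
  u_of <- function(idx) {
    ux <- sum(rk[idx]) - nx * (nx + 1) / 2
    min(ux, nx * ny - ux)
  }
  obs <- u_of(1:5)
  null_u <- apply(combos, 2, u_of)
  p_exact <- mean(null_u <= obs + 1e-9)
  mc <- mann_whitney_mc(x, y, n_rand = 20000, seed = 6)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(mc$p_value - p_exact), 3 * se + 2 / 20000)
})

test_that("rank statistics are seed-invariant; only p fluctuates", {
  withr::with_seed(7, {
    x <- rnorm(20, 0.3); y <- rnorm(20)
  })
  w1 <- wilcoxon_signed_mc(x, y, n_rand = 999, seed = 1)
  w2 <- wilcoxon_signed_mc(x, y, n_rand = 999, seed = 99)
  expect_identical(w1$statistic, w2$statistic)
  u1 <- mann_whitney_mc(x, y, n_rand = 999, seed = 1)
  u2 <- mann_whitney_mc(x, y, n_rand = 999, seed = 99)
  expect_identical(u1$statistic, u2$statistic)
  expect_lt(abs(w1$p_value - w2$p_value), 0.1)
})

test_that("diversity contrast verdicts: identity, scaling, swapping, polarity", {
  ref <- random_distance_matrix(9, seed = 8)

  # identical matrices: both paired tests degenerate (warned) and no call
  suppressMessages({
    expect_warning(
      expect_warning(
        same <- diversity_selection_test(ref, ref, n_rand_wilcoxon = 499,
                                         n_rand_mw = 499, seed = 1),
        "degenerate"),
      "degenerate")
  })
  expect_equal(same$call, "not_detected")

  half <- pairwise_matrix(ref$values * 0.5, ref$labels,
                          polarity = "distance")
  suppressMessages({
    v <- diversity_selection_test(half, ref, n_rand_wilcoxon = 1999,
                                  n_rand_mw = 1999, seed = 2)
  })
  expect_equal(v$call, "purifying")
  expect_equal(v$tests$sign$statistic, 0)
  expect_equal(v$tests$sign$p_value, min(1, 2 * (1 / 2)^36))
  expect_lt(v$focal_mean, v$reference_mean)

  suppressMessages({
    sw <- diversity_selection_test(ref, half, n_rand_wilcoxon = 1999,
                                   n_rand_mw = 1999, seed = 3)
  })
  expect_equal(sw$call, "diversifying")
  expect_equal(sw$tests$sign$p_value, v$tests$sign$p_value)
  expect_identical(sw$tests$wilcoxon$statistic + v$tests$wilcoxon$statistic,
                   36 * 37 / 2)   # rank sums over complementary sign sets

  sim <- convert_polarity(ref, "similarity")
  expect_error(suppressMessages(diversity_selection_test(sim, ref)),
               "distance polarity")
  mism <- random_distance_matrix(9, seed = 9, labels = paste0("z", 1:9))
  expect_error(suppressMessages(diversity_selection_test(mism, ref)),
               "label mismatch")
})
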