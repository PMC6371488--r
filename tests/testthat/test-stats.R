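test_that("Bland-Altman summary matches a worked hand calculation", {
  a <- c(100, 102, 98, 104)
  b <- c(98, 104, 94, 104)
  # differences 2, -2, 4, 0: mean 1, sample variance ((1+9+9+1)/3) = 20/3
  ba <- bland_altman(paired_measurements(a, b, "hand"))
  expect_equal(ba$n, 4L)
  expect_equal(ba$mean_diff, 1)
  expect_equal(ba$sd_diff, sqrt(20 / 3))
  expect_equal(ba$loa_lo, 1 - 1.96 * sqrt(20 / 3))
  expect_equal(ba$loa_hi, 1 + 1.96 * sqrt(20 / 3))
  # relative %: 100*d/((a+b)/2) computed pairwise
  rel <- 100 * c(2, -2, 4, 0) / c(99, 103, 96, 104)
  expect_equal(ba$mean_rel_pct, mean(rel))
  expect_equal(ba$rel_loa_hi, mean(rel) + 1.96 * stats::sd(rel))

  ident <- bland_altman(c(3, 5, 9), c(3, 5, 9))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$sd_diff, 0)
  expect_equal(ident$loa_lo, 0)

  expect_warning(z <- bland_altman(c(1, -2, 5), c(-1, 2, 4)),
                 "2 pair\\(s\\) with a \\+ b = 0 excluded")
  expect_equal(z$n, 3L)
  expect_equal(z$mean_rel_pct, 100 * 1 / 4.5)  # only the (5, 4) pair survives
})

test_that("the limits of agreement cover about 95% of normal differences", {
  set.seed(81)
  n <- 20000
  b <- stats::rnorm(n, 100, 10)
  a <- b + stats::rnorm(n, 5, 2)
  ba <- bland_altman(a, b)
  coverage <- mean((a - b) >= ba$loa_lo & (a - b) <= ba$loa_hi)
  expect_lt(abs(coverage - 0.95), 0.01)
  expect_lt(abs(ba$mean_diff - 5), 0.05)
  expect_lt(abs(ba$sd_diff - 2), 0.05)
})

test_that("Spearman correlation matches the rank-difference formula", {
  set.seed(82)
  x <- sample(seq(1, 500), 40)  # tie-free
  y <- x^3 + 2                  # monotone transform
  expect_equal(spearman_rho(paired_measurements(x, y)), 1)
  expect_equal(spearman_rho(paired_measurements(x, -y)), -1)
  z <- sample(seq(1, 500), 40)
  # oracle: 1 - 6 sum(d^2) / (n(n^2-1)) for tie-free data
  d <- rank(x) - rank(z)
  expect_equal(spearman_rho(paired_measurements(x, z)),
               1 - 6 * sum(d^2) / (40 * (40^2 - 1)))
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  expect_error(spearman_rho(c(1, 2), c(1, 2)))
})

test_that("ICC(2,1) matches an analysis-of-variance oracle and known limits", {
  set.seed(83)
  n <- 12
  subj <- stats::rnorm(n, 50, 8)
  a <- subj + stats::rnorm(n, 0, 2)
  b <- subj + 1.5 + stats::rnorm(n, 0, 2)
  got <- icc_absolute(paired_measurements(a, b))

  # oracle: two-way ANOVA mean squares via stats::aov on the long table
  long <- data.frame(y = c(a, b),
                     subject = factor(rep(seq_len(n), 2)),
                     method = factor(rep(c("A", "B"), each = n)))
  ms <- summary(stats::aov(y ~ subject + method, data = long))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + mse + (2 / n) * (msc - mse))
  expect_equal(got, oracle)

  # perfect agreement -> 1; huge systematic bias -> near 0
  expect_equal(icc_absolute(paired_measurements(a, a)), 1)
  expect_lt(icc_absolute(paired_measurements(a, a + 1000)), 0.01)
  expect_error(icc_absolute(paired_measurements(c(1, 1), c(1, 1))))
})

test_that("ICC recovers the variance-ratio used to construct the data", {
  set.seed(84)
  n <- 8000
  sb <- 3; se <- 1   # true ICC = 9 / (9 + 1) = 0.9
  subj <- stats::rnorm(n, 0, sb)
  a <- subj + stats::rnorm(n, 0, se)
  b <- subj + stats::rnorm(n, 0, se)
  expect_lt(abs(icc_absolute(paired_measurements(a, b)) - 0.9), 0.01)
})

test_that("ICC test power equals the size under the null and grows with n and effect", {
  expect_equal(icc_power(0.6, 0.6, 30), 0.05)
  expect_equal(icc_power(0.6, 0.6, 30, alpha = 0.10), 0.10)
  p <- vapply(c(10, 20, 40, 80), function(n) icc_power(0.6, 0.8, n), numeric(1))
  expect_true(all(diff(p) > 0))
  q <- vapply(c(0.7, 0.8, 0.9), function(r) icc_power(0.6, r, 30), numeric(1))
  expect_true(all(diff(q) > 0))
  expect_gt(icc_power(0.6, 0.8, 30, k = 3), icc_power(0.6, 0.8, 30, k = 2))
  expect_error(icc_power(0.8, 0.6, 30))
  expect_error(icc_power(0.5, 1, 30))
})

test_that("ICC test power matches a Monte Carlo rejection rate", {
  # simulate the one-way design at the alternative and count rejections of
  # the F test calibrated at the null
  rho0 <- 0.6; rho1 <- 0.8; n <- 30; k <- 2; alpha <- 0.05
  theta <- function(rho) (1 + (k - 1) * rho) / (1 - rho)
  crit <- theta(rho0) * stats::qf(1 - alpha, n - 1, n * (k - 1))
  set.seed(85)
  reps <- 20000
  rej <- 0L
  for (i in seq_len(reps)) {
    subj <- stats::rnorm(n, 0, sqrt(rho1))
    y <- matrix(subj, n, k) + matrix(stats::rnorm(n * k, 0, sqrt(1 - rho1)), n, k)
    msb <- k * stats::var(rowMeans(y))
    msw <- sum((y - rowMeans(y))^2) / (n * (k - 1))
    if (msb / msw > crit) rej <- rej + 1L
  }
  expect_lt(abs(rej / reps - icc_power(rho0, rho1, n, k, alpha)), 0.01)
})

test_that("the combined report and CSV comparison agree with the components", {
  set.seed(86)
  a <- stats::rnorm(20, 100, 15); b <- a + stats::rnorm(20, 1, 3)
  p <- paired_measurements(a, b)
  rep <- agreement_report(p)
  expect_equal(rep$mean_diff, bland_altman(p)$mean_diff)
  expect_equal(rep$spearman_rho, spearman_rho(p))
  expect_equal(rep$icc, icc_absolute(p))
  out <- capture.output(print(rep))
  expect_match(out[1], "n = 20")
  expect_match(paste(out, collapse = "\n"), "ICC\\(2,1\\)")
})
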