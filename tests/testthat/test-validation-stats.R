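# independent oracle for the Passing-Bablok slope: plain double loop,
# shifted median written out longhand
pb_slope_oracle <- function(x, y) {
  S <- c()
  n <- length(x)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next
    s <- if (dx == 0) sign(dy) * Inf else dy / dx
    if (s != -1) S <- c(S, s)
  }
  S <- sort(S)
  N <- length(S)
  K <- sum(S < -1)
  if (N %% 2 == 1) S[(N + 1) / 2 + K]
  else (S[N / 2 + K] + S[N / 2 + 1 + K]) / 2
}

test_that("Bland-Altman reproduces bias and limits on closed-form cases", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$loa_lower, 0)
  ba1 <- bland_altman(c(2, 3, 4), c(1, 2, 3))
  expect_equal(ba1$bias, 1)
  expect_equal(ba1$sd_diff, 0)
  expect_equal(c(ba1$loa_lower, ba1$loa_upper), c(1, 1))
  expect_error(bland_altman(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman recovers an injected offset within sampling error", {
  set.seed(7)
  ref <- runif(50, 5, 10)
  test <- ref + 0.5 + rnorm(50, 0, 0.2)
  ba <- bland_altman(test, ref)
  expect_lt(abs(ba$bias - 0.5), 3 * 0.2 / sqrt(50))
  expect_equal(ba$loa_upper, ba$bias + 1.96 * ba$sd_diff)
  # translation property: adding c shifts bias only
  ba2 <- bland_altman(test + 2, ref)
  expect_equal(ba2$bias, ba$bias + 2)
  expect_equal(ba2$sd_diff, ba$sd_diff)
})

test_that("Pearson correlation matches the product-moment formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2.0, 2.9, 4.2, 4.8, 6.3)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), hand)
  expect_error(pearson_r(rep(1, 5), y), "zero variance")
})

test_that("paired t behaves on identities and matches the formula", {
  x <- c(1, 2, 3, 4)
  r0 <- paired_t(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  set.seed(3)
  a <- rnorm(10); b <- rnorm(10)
  r <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(r$t, t_hand)
  expect_equal(r$df, 9)
  expect_equal(r$p, 2 * pt(-abs(t_hand), 9))
  # antisymmetry
  expect_equal(paired_t(b, a)$t, -r$t)
  # degenerate: constant nonzero difference
  rz <- paired_t(x + 1, x)
  expect_true(rz$degenerate)
  expect_equal(rz$p, 0)
})

test_that("paired t rejects at the nominal rate under the null", {
  set.seed(123)
  rejections <- 0
  for (i in 1:10000) {
    d <- rnorm(12)
    t_stat <- mean(d) / (sd(d) / sqrt(12))
    if (2 * pt(-abs(t_stat), 11) <= 0.05) rejections <- rejections + 1
  }
  # same statistic path as paired_t; spot-check agreement on a few draws
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(paired_t(a, b)$p,
                 2 * pt(-abs(mean(a - b) / (sd(a - b) / sqrt(12))), 11))
  }
  expect_lt(abs(rejections / 10000 - 0.05), 0.015)
})

test_that("Passing-Bablok recovers exact affine relations", {
  x <- as.numeric(1:12)
  f1 <- passing_bablok(x, x)
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 0)
  f2 <- passing_bablok(x, 2 * x + 1)
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 1)
  expect_error(passing_bablok(1:5, 1:5), "at least 10")
  expect_error(passing_bablok(rep(1, 12), x), "identical")
})

test_that("Passing-Bablok equals the exhaustive pairwise-slope oracle", {
  set.seed(21)
  for (case in 1:15) {
    n <- sample(10:15, 1)
    x <- round(runif(n, 1, 10), 2)
    y <- round(1.1 * x + rnorm(n, 0, 0.5), 2)
    fit <- passing_bablok(x, y)
    expect_equal(fit$slope, pb_slope_oracle(x, y))
    expect_equal(fit$intercept, median(y - fit$slope * x))
    expect_true(fit$slope_ci[1] <= fit$slope &&
                  fit$slope <= fit$slope_ci[2])
  }
})

test_that("Passing-Bablok is scale equivariant", {
  set.seed(5)
  x <- runif(14, 2, 9)
  y <- 1.3 * x + rnorm(14, 0, 0.3)
  f <- passing_bablok(x, y)
  a <- 3.7
  fs <- passing_bablok(a * x, a * y)
  expect_equal(fs$slope, f$slope)
  expect_equal(fs$intercept, a * f$intercept)
})

test_that("KS normality separates normal from uniform data", {
  # the fitted-parameter KS is conservative, so power against the
  # uniform needs a reasonably large sample
  set.seed(31)
  pn <- replicate(20, ks_normality(rnorm(1000))$p)
  expect_gt(median(pn), 0.05)
  pu <- replicate(20, ks_normality(runif(1000))$p)
  expect_lt(max(pu), 0.05)
  expect_error(ks_normality(rep(1, 10)), "constant")
})

test_that("precision summary computes range statistics with n-1 SD", {
  tab <- data.frame(analyte = "rbc", range = "4.0",
                    value = c(4.0, 4.1, 3.9, 4.0))
  rep_ <- precision_summary(tab)
  expect_equal(rep_$ranges$mean, 4.0)
  expect_equal(rep_$ranges$sd, sd(c(4.0, 4.1, 3.9, 4.0)))
  expect_equal(rep_$ranges$cv, 100 * rep_$ranges$sd / 4.0,
               tolerance = 1e-12)
  expect_equal(round(rep_$ranges$cv, 2), 2.04)
  # missing range reported as NA, not dropped
  tab2 <- rbind(tab, data.frame(analyte = "rbc", range = "5.0",
                                value = NA_real_))
  rep2 <- precision_summary(tab2)
  expect_equal(nrow(rep2$ranges), 2)
  expect_true(is.na(rep2$ranges$cv[2]))
  expect_true(is.na(rep2$analytes$mean_cv))
})

test_that("range concordance classifies by sex-specific interval", {
  # outside range = positive class
  tp_ <- data.frame(analyte = "hb", value = c(10, 14, 16, 9),
                    sex = c("F", "F", "M", "M"))
  rp_ <- data.frame(analyte = "hb", value = c(10.5, 13.8, 16.2, 13),
                    sex = c("F", "F", "M", "M"))
  cm <- range_concordance(tp_, rp_)[["hb"]]
  expect_equal(cm$tp, 1)   # female at 10 vs 10.5: both below 11.3
  expect_equal(cm$fp, 1)   # male 9 vs 13: test abnormal, reference normal
  expect_equal(cm$tn, 2)
  expect_error(range_concordance(
    data.frame(analyte = "hb", value = 1, sex = "X"),
    data.frame(analyte = "hb", value = 1, sex = "X")), "sex")
})

test_that("the method-comparison battery is exact on self-comparison", {
  set.seed(8)
  vals <- runif(20, 3.5, 6)
  paired <- data.frame(sample_id = 1:20, analyte = "rbc", test = vals,
                       reference = vals,
                       sex = rep(c("F", "M"), 10))
  rep_ <- run_method_comparison(paired)
  expect_equal(rep_$comparison$bias, 0)
  expect_equal(rep_$comparison$r, 1)
  expect_equal(rep_$comparison$pb_slope, 1)
  expect_equal(rep_$concordance$kappa, 1)
  expect_error(run_method_comparison(paired[1:2, ]), "at least 3")
})
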