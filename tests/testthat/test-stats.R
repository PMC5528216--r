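test_that("the normality screen behaves across null, alternative and degenerate input", {
  expect_error(test_normality(rep(5, 20)), "zero variance")
  expect_error(test_normality(c(1, 2)), "n >= 3")
  set.seed(71)
  skewed <- rlnorm(500, 0, 1)
  expect_lt(test_normality(skewed)$p_value, 0.05)
  # type-I error near nominal on normal data
  rejections <- sum(replicate(200, {
    test_normality(rnorm(50))$p_value < 0.05
  }))
  expect_gte(rejections, 1)
  expect_lte(rejections, 25)
})

test_that("the Levene screen detects variance heterogeneity and handles ties", {
  x <- c(1, 2, 3, 4)
  lt <- levene_test(c(x, x), rep(c("a", "b"), each = 4))
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p_value, 1)
  set.seed(72)
  g1 <- rnorm(200, sd = 1); g2 <- rnorm(200, sd = 3)  # variance ratio 9
  lt <- levene_test(c(g1, g2), rep(c("a", "b"), each = 200))
  expect_lt(lt$p_value, 0.05)
  expect_error(levene_test(rep(c(1, 2), each = 3),
                           rep(c("a", "b"), each = 3)), "degenerate")
  # equal-variance data: type-I near nominal
  rejections <- sum(replicate(200, {
    v <- rnorm(60)
    levene_test(v, rep(c("a", "b"), each = 30))$p_value < 0.05
  }))
  expect_lte(rejections, 25)
})

test_that("the IQR screen flags a constructed extreme point and nothing else", {
  x <- c(10, 11, 12, 13, 14, 100)
  # type-7 quartiles: Q1 = 11.25, Q3 = 13.75, fences 5.75 / 19.25
  expect_identical(iqr_outliers(x, k = 2.2),
                   c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outliers(rep(3, 10))))
  expect_false(any(iqr_outliers(x, k = Inf)))
  expect_warning(flags <- iqr_outliers(c(1, 2, 3)), "fewer than 4")
  expect_false(any(flags))
})

test_that("variance inflation factors match their closed forms", {
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))  # orthogonal
  expect_equal(unname(vif(x)), c(1, 1))
  set.seed(73)
  z <- rnorm(5000)
  x2 <- cbind(p = z + rnorm(5000, sd = 0.75), q = z + rnorm(5000, sd = 0.75))
  # corr 0.64 => VIF = 1/(1 - 0.64^2) ... computed from realized correlation
  r <- cor(x2[, 1], x2[, 2])
  expect_equal(unname(vif(x2)), rep(1 / (1 - r^2), 2), tolerance = 1e-6)
  dup <- cbind(u = z, v = z)
  expect_true(all(is.infinite(vif(dup))))
})

test_that("the pooled t-test covers identity, strong signal and the log identity", {
  a <- c(1, 2, 3, 4, 5)
  tt <- independent_t_test(a, a)
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  set.seed(74)
  g1 <- rnorm(50); g2 <- rnorm(50, mean = 5)
  expect_lt(independent_t_test(g1, g2)$p_value, 0.001)
  pos <- rlnorm(30, 2, 0.4)
  tt <- independent_t_test(pos, 10 * pos, log10_first = TRUE)
  expect_equal(tt$mean_difference, -1)
  expect_error(independent_t_test(rep(2, 5), rep(2, 5)), "zero pooled")
  expect_error(independent_t_test(c(1, 2), 5 * rlnorm(3), log10_first = FALSE),
               NA)
})

test_that("Pearson correlation honours affine relations and degenerate input", {
  x <- c(1, 3, 5, 7, 11)
  expect_equal(pearson_cor(x, 2 * x + 3)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  expect_error(pearson_cor(x, rep(4, 5)), "zero variance")
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "n >= 3")
  # pairs with missing values are dropped
  r <- pearson_cor(c(x, NA), c(2 * x + 3, 9))
  expect_identical(r$n, 5L)
})

test_that("an intercept-only logistic fit recovers the log odds in closed form", {
  y <- c(rep(1, 7), rep(0, 3))
  fit <- fit_logistic(NULL, y)
  expect_equal(unname(fit$coefficients), log(7 / 3), tolerance = 1e-8)
  expect_identical(fit$n, 10L)
  expect_true(fit$converged)
})

test_that("a binary predictor's coefficient equals the 2x2 log odds ratio", {
  # contingency table: x=0 -> 8/20 events; x=1 -> 15/20 events
  x <- rep(c(0, 1), each = 20)
  y <- c(rep(1, 8), rep(0, 12), rep(1, 15), rep(0, 5))
  fit <- fit_logistic(data.frame(x = x), y)
  lor <- log((15 * 12) / (5 * 8))  # cross-product ratio
  expect_equal(unname(fit$coefficients["x"]), lor, tolerance = 1e-8)
  expect_equal(unname(fit$odds_ratio["x"]), exp(lor), tolerance = 1e-8)
})

test_that("the IRLS fit matches a brute-force grid-search oracle", {
  # 12 constructed points, two predictors
  x1 <- c(-1.5, -1.0, -0.5, 0.0, 0.5, 1.0, 1.5, 2.0, -2.0, 0.3, -0.7, 1.2)
  x2 <- c(0.5, -0.5, 1.0, -1.0, 0.0, 0.5, -0.5, 1.5, -1.5, 0.8, 0.2, -0.2)
  y <- c(0, 0, 0, 0, 1, 0, 1, 1, 0, 1, 0, 1)
  fit <- fit_logistic(data.frame(x1 = x1, x2 = x2), y)
  X <- cbind(1, x1, x2)
  oracle <- grid_logistic_oracle(X, y)
  expect_lt(max(abs(unname(fit$coefficients) - oracle)), 1e-3)

  # single-predictor problem against the same oracle
  fit1 <- fit_logistic(data.frame(x1 = x1), y)
  o1 <- grid_logistic_oracle(cbind(1, x1), y)
  expect_lt(max(abs(unname(fit1$coefficients) - o1)), 1e-3)
})

test_that("odds ratios and Wald intervals are exact transforms of the coefficients", {
  set.seed(75)
  x <- data.frame(a = rnorm(120), b = rnorm(120))
  y <- rbinom(120, 1, plogis(0.3 + 0.8 * x$a))
  fit <- fit_logistic(x, y)
  expect_identical(fit$odds_ratio, exp(fit$coefficients))
  expect_equal(fit$ci_lower, exp(fit$coefficients - 1.959964 * fit$se))
  expect_equal(fit$ci_upper, exp(fit$coefficients + 1.959964 * fit$se))
  expect_true(all(fit$ci_lower < fit$ci_upper))
})

test_that("complete separation is detected and flagged distinctly", {
  x <- data.frame(z = c(-3, -2, -1, 1, 2, 3))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(x, y)
  expect_true(fit$separation)
})

test_that("logistic parameter recovery stays within 3 SE at large n", {
  set.seed(76)
  hits <- replicate(20, {
    x <- rnorm(5000, mean = 0, sd = 10)
    y <- rbinom(5000, 1, plogis(-2 + 0.12 * x))
    fit <- fit_logistic(data.frame(x = x), y)
    all(abs(fit$coefficients - c(-2, 0.12)) <= 3 * fit$se)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Nagelkerke R2 is zero for null fits, near one under separation, and bounded", {
  y <- rbinom(80, 1, 0.4)
  null_fit <- fit_logistic(NULL, y)
  expect_equal(nagelkerke_r2(null_fit), 0)
  x <- data.frame(z = c(rnorm(40, -4), rnorm(40, 4)))
  ysep <- rep(c(0, 1), each = 40)
  sep_fit <- fit_logistic(x, ysep)
  expect_gt(nagelkerke_r2(sep_fit), 0.99)
  set.seed(77)
  for (i in 1:10) {
    xx <- data.frame(a = rnorm(60))
    yy <- rbinom(60, 1, plogis(xx$a))
    r2 <- nagelkerke_r2(fit_logistic(xx, yy))
    expect_gte(r2, 0)
    expect_lte(r2, 1)
  }
})

test_that("Hosmer-Lemeshow has df = groups - 2 and is zero under exact calibration", {
  set.seed(78)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(x))
  hl <- hosmer_lemeshow(fit_logistic(data.frame(x = x), y), groups = 10)
  expect_identical(hl$df, 8L)
  # perfectly calibrated blocks: 10 tied probability levels, observed
  # counts equal to expected counts exactly
  p <- rep(seq(0.05, 0.95, by = 0.1), each = 20)
  yy <- unlist(lapply(seq(0.05, 0.95, by = 0.1), function(pk) {
    c(rep(1, round(20 * pk)), rep(0, 20 - round(20 * pk)))
  }))
  fake <- structure(list(glm = list(fitted.values = p, y = yy)),
                    class = "logistic_fit")
  hl0 <- hosmer_lemeshow(fake, groups = 10)
  expect_equal(hl0$chi_square, 0)
  expect_identical(hl0$df, 8L)
})

test_that("Hosmer-Lemeshow rejects near the nominal rate on well-specified data", {
  set.seed(79)
  rej <- mean(replicate(100, {
    x <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(-0.5 + x))
    hosmer_lemeshow(fit_logistic(data.frame(x = x), y))$p_value < 0.05
  }))
  expect_lte(rej, 0.13)
})

test_that("backward LR selection keeps strong predictors and prunes noise", {
  set.seed(80)
  x <- data.frame(a = rnorm(500), b = rnorm(500))
  y <- rbinom(500, 1, plogis(1.2 * x$a + 1.0 * x$b))
  sel <- backward_lr_selection(x, y, p_out = 0.10)
  expect_setequal(sel$fit$predictors, c("a", "b"))
  expect_identical(max(sel$trace$step), 1L)

  x$noise <- rnorm(500)
  sel2 <- backward_lr_selection(x, y, p_out = 0.10)
  expect_false("noise" %in% sel2$fit$predictors)
  # the trace shrinks strictly and records the removal
  steps <- split(sel2$trace$predictor, sel2$trace$step)
  expect_true(all(diff(lengths(steps)) < 0))
  expect_identical(sel2$trace$predictor[sel2$trace$removed], "noise")
})

test_that("backward LR selection can empty the model to intercept only", {
  set.seed(82)
  x <- data.frame(n1 = rnorm(200), n2 = rnorm(200))
  y <- rbinom(200, 1, 0.5)
  sel <- backward_lr_selection(x, y, p_out = 0.10)
  expect_identical(sel$fit$predictors, character(0))
  expect_identical(sel$trace$predictor[nrow(sel$trace)], "(none)")
})
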