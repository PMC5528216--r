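#' Shapiro-Wilk normality test
#'
#' Thin wrapper with explicit degenerate-input handling: constant vectors
#' cannot be tested for normality and raise an error naming the problem.
#'
#' @param values Numeric vector, n >= 3 (NA dropped).
#' @return List with `statistic` and `p_value`.
#' @export
test_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("normality test requires n >= 3")
  if (sd(values) == 0) stop("degenerate input: zero variance")
  st <- shapiro.test(values)
  list(statistic = unname(st$statistic), p_value = st$p.value)
}

#' Levene test of homogeneity of variances
#'
#' Classical Levene test on absolute deviations from the group mean
#' (`center = "mean"`, the default of the original test); the
#' Brown-Forsythe median-centred variant is available via `center`.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, at least two groups with n >= 2 each.
#' @param center `"mean"` (classical) or `"median"`.
#' @return List with `statistic` (F), `df`, `p_value`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop("Levene test requires >= 2 groups with n >= 2 each")
  }
  if (all(tapply(values, groups, sd) == 0)) {
    stop("degenerate groups: zero variance within every group")
  }
  cfun <- if (center == "mean") mean else stats::median
  dev <- abs(values - stats::ave(values, groups, FUN = cfun))
  if (sd(dev) == 0) {
    # Deviations identical everywhere: no evidence of variance difference.
    return(list(statistic = 0, df = c(nlevels(groups) - 1L,
                                      length(values) - nlevels(groups)),
                p_value = 1))
  }
  lt <- car::leveneTest(values, groups, center = cfun)
  list(statistic = lt[1, "F value"],
       df = c(lt[1, "Df"], lt[2, "Df"]),
       p_value = lt[1, "Pr(>F)"])
}

#' Interquartile-range outlier screen
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]`. Quartiles use linear
#' interpolation (type 7), which matters for flag decisions near the
#' fence. The default `k = 2.2` is the conservative fence recommended for
#' moderately sized biological samples.
#'
#' @param values Numeric vector (`NA` never flagged).
#' @param k Fence multiplier (default 2.2; `Inf` flags nothing).
#' @return Logical vector of flags, same length as `values`.
#' @export
iqr_outliers <- function(values, k = 2.2) {
  obs <- values[!is.na(values)]
  if (length(obs) < 4) {
    warning("fewer than 4 observations: no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  q <- quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr
  hi <- q[2] + k * iqr
  out <- !is.na(values) & (values < lo | values > hi)
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from the least-squares
#' regression of predictor j on the remaining predictors. Perfect
#' collinearity is reported as `Inf`, not an error, so the screen can
#' still name the offending column.
#'
#' @param x Numeric matrix or data frame of predictors (>= 2 columns,
#'   more rows than columns).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(x) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("VIF requires at least two predictors")
  if (nrow(x) <= ncol(x)) stop("VIF requires n > number of predictors")
  vapply(seq_along(x), function(j) {
    fit <- lm(x[[j]] ~ ., data = x[-j])
    # summary warns about "essentially perfect fit" exactly in the
    # collinear case we want to report as Inf
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(names(x))
}

#' Independent two-sample Student t-test
#'
#' Pooled-variance Student t-test (two-sided) — the classical form used
#' once homogeneity of variances has been verified. A Welch correction is
#' available via `welch = TRUE`. For positively skewed metrics an optional
#' log10 transform is applied to both groups first.
#'
#' @param a,b Numeric vectors (NA dropped), each n >= 2.
#' @param log10_first Apply log10 to both groups before testing.
#' @param welch Use the Welch (unequal-variance) form.
#' @return List with `t`, `df`, `p_value`, `mean_difference` (on the
#'   analysis scale).
#' @export
independent_t_test <- function(a, b, log10_first = FALSE, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group requires n >= 2")
  if (log10_first) {
    if (any(a <= 0) || any(b <= 0)) stop("log10 transform requires positive values")
    a <- log10(a); b <- log10(b)
  }
  if (!welch && sd(c(a - mean(a), b - mean(b))) == 0) {
    stop("zero pooled variance: t statistic undefined")
  }
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_difference = mean(a) - mean(b))
}

#' Pearson correlation with two-sided test
#'
#' @param x,y Paired numeric vectors; pairs with any `NA` are dropped;
#'   n >= 3 and nonzero variances required.
#' @return List with `r`, `n`, `p_value`.
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("Pearson correlation requires n >= 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one of the variables")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value)
}

#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares)
#' of a 0/1 response on a set of predictors, with Wald inference: standard
#' errors from the inverse observed information, odds ratios `exp(B)`, and
#' 95% Wald confidence intervals `exp(B +/- 1.959964 SE)`. Rows with any
#' missing value among the model variables are removed (listwise
#' deletion). Non-convergence and (quasi-)complete separation are detected
#' and reported as distinct flags.
#'
#' @param x Data frame or matrix of predictors, or `NULL` for an
#'   intercept-only fit.
#' @param y Binary response (0/1, logical, or two-level factor); both
#'   classes must be present after deletion.
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return An object of class `logistic_fit`: `coefficients`, `se`,
#'   `wald_p`, `odds_ratio`, `ci_lower`, `ci_upper`, `log_lik`,
#'   `null_log_lik`, `deviance`, `null_deviance`, `n`, `converged`,
#'   `separation`, `predictors`, and the underlying `glm` object.
#' @export
fit_logistic <- function(x, y, epsilon = 1e-8, maxit = 100L) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1), na.rm = TRUE)) stop("y must be binary 0/1")
  if (is.null(x) || (is.data.frame(x) && ncol(x) == 0)) {
    dat <- data.frame(.y = y)
  } else {
    x <- as.data.frame(x)
    if (is.null(names(x)) || any(names(x) == "")) {
      names(x) <- paste0("x", seq_along(x))
    }
    dat <- cbind(.y = y, x)
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$.y)) < 2) {
    stop("both response classes must be present after listwise deletion")
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial(),
        control = list(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  b <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  null_dev <- fit$null.deviance
  structure(
    list(predictors = setdiff(names(dat), ".y"),
         coefficients = b, se = se,
         wald_p = co[, "Pr(>|z|)"],
         odds_ratio = exp(b),
         ci_lower = exp(b - Z_95 * se),
         ci_upper = exp(b + Z_95 * se),
         log_lik = as.numeric(logLik(fit)),
         null_log_lik = -null_dev / 2,
         deviance = fit$deviance, null_deviance = null_dev,
         n = nrow(dat), converged = fit$converged,
         separation = sep_warn || any(abs(b) > 1e4),
         glm = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d, predictors: %s\n", x$n,
              if (length(x$predictors)) paste(x$predictors, collapse = ", ")
              else "(intercept only)"))
  tab <- data.frame(B = x$coefficients, SE = x$se, p = x$wald_p,
                    OR = x$odds_ratio, ci_lo = x$ci_lower,
                    ci_hi = x$ci_upper)
  print(round(tab, 4))
  if (!x$converged) cat("!! IRLS did not converge\n")
  if (x$separation) cat("!! separation suspected\n")
  invisible(x)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell `R2 = 1 - exp(2 (LL0 - LL1) / n)` rescaled by its attainable
#' maximum `1 - exp(2 LL0 / n)`, giving a statistic in \[0, 1\] that is 0
#' exactly when the fitted model matches the null model. A fitted
#' log-likelihood below the null value (beyond numerical tolerance)
#' signals a broken fit and raises an error rather than a negative R2.
#'
#' @param fit A [fit_logistic()] result.
#' @param null_fit Intercept-only fit on the same data; defaults to the
#'   null deviance stored in `fit`.
#' @param n Sample size (defaults to `fit$n`).
#' @return Nagelkerke R-squared.
#' @export
nagelkerke_r2 <- function(fit, null_fit = NULL, n = fit$n) {
  ll1 <- fit$log_lik
  ll0 <- if (is.null(null_fit)) fit$null_log_lik else null_fit$log_lik
  if (ll1 < ll0 - 1e-6) {
    stop("fitted log-likelihood below the null model: fitting bug upstream")
  }
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  mx <- 1 - exp(2 * ll0 / n)
  max(0, min(1, cs / mx))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Ranks cases by fitted probability, splits them into `groups` near-equal
#' bins (ties kept together), and forms
#' `chi2 = sum (O - E)^2 / (E (1 - E/n_g))` over bins, with
#' `df = bins - 2`. Bins whose expected count is zero are merged into a
#' neighbour with a warning.
#'
#' @param fit A [fit_logistic()] result.
#' @param groups Number of bins (default 10).
#' @return List with `chi_square`, `df`, `p_value`, `groups_used`, and the
#'   per-bin `table`.
#' @export
hosmer_lemeshow <- function(fit, groups = 10) {
  p <- fit$glm$fitted.values
  y <- fit$glm$y
  n <- length(p)
  if (groups < 3) stop("Hosmer-Lemeshow requires at least 3 groups")
  # Quantile breaks keep tied fitted probabilities in one bin.
  br <- unique(quantile(p, probs = seq(0, 1, length.out = groups + 1),
                        type = 7, names = FALSE))
  if (length(br) < 3) stop("fitted probabilities too degenerate to bin")
  bin <- cut(p, breaks = br, include.lowest = TRUE)
  ng <- tapply(rep(1, n), bin, sum, default = 0)
  obs <- tapply(y, bin, sum, default = 0)
  expd <- tapply(p, bin, sum, default = 0)
  keep <- ng > 0
  ng <- ng[keep]; obs <- obs[keep]; expd <- expd[keep]
  # Merge bins with degenerate expectation into their left neighbour.
  bad <- which(expd <= 0 | expd >= ng)
  if (length(bad)) {
    warning("merging ", length(bad), " degenerate bin(s)")
    for (b in rev(bad)) {
      tgt <- if (b > 1) b - 1 else 2
      if (tgt > length(ng)) next
      ng[tgt] <- ng[tgt] + ng[b]; obs[tgt] <- obs[tgt] + obs[b]
      expd[tgt] <- expd[tgt] + expd[b]
      ng <- ng[-b]; obs <- obs[-b]; expd <- expd[-b]
    }
  }
  chi2 <- sum((obs - expd)^2 / (expd * (1 - expd / ng)))
  df <- length(ng) - 2L
  list(chi_square = chi2, df = df,
       p_value = pchisq(chi2, df, lower.tail = FALSE),
       groups_used = length(ng),
       table = data.frame(n = as.numeric(ng), observed = as.numeric(obs),
                          expected = as.numeric(expd)))
}

#' Backward likelihood-ratio variable selection
#'
#' Starts from the full model and, at each step, computes the
#' likelihood-ratio (deviance difference, 1 df) removal test for every
#' current predictor; the predictor with the largest removal p-value is
#' dropped if that p-value is at least `p_out`, and the procedure repeats
#' until no predictor is removable (possibly leaving an intercept-only
#' model). The trace records every step's retained predictors, their
#' removal p-values, and the variable removed.
#'
#' @param x Data frame of candidate predictors.
#' @param y Binary response.
#' @param p_out Removal threshold (default 0.10, the conventional
#'   backward-LR default of mainstream statistical software).
#' @return List with `fit` (final [fit_logistic()]) and `trace` (data
#'   frame: `step`, `predictor`, `p_remove`, `removed`).
#' @export
backward_lr_selection <- function(x, y, p_out = 0.10) {
  x <- as.data.frame(x)
  dat <- cbind(.y = if (is.factor(y)) as.integer(y) - 1L else y, x)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  current <- names(x)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    fit <- fit_logistic(dat[current], dat$.y)
    if (length(current) == 0) {
      trace[[step]] <- data.frame(step = step, predictor = "(none)",
                                  p_remove = NA_real_, removed = FALSE)
      break
    }
    lrt <- drop1(fit$glm, test = "LRT")
    pr <- lrt[current, "Pr(>Chi)"]
    names(pr) <- current
    worst <- names(pr)[which.max(pr)]
    drop_it <- pr[[worst]] >= p_out
    trace[[step]] <- data.frame(step = step, predictor = current,
                                p_remove = unname(pr),
                                removed = drop_it & current == worst)
    if (!drop_it) break
    current <- setdiff(current, worst)
  }
  list(fit = fit_logistic(dat[current], dat$.y),
       trace = do.call(rbind, trace))
}
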