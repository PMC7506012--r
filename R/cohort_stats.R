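# The cohort statistical workflow: normality-routed descriptives,
# two-group tests, correlations, propensity matching, reproducibility
# metrics (Bland-Altman, CV, ICC) and the t-test sample-size calculation.

shapiro_p <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
  n <- length(x)
  if (n > 5000) x <- x[seq(1, n, length.out = 5000)]
  stats::shapiro.test(x)$p.value
}

#' Describe a variable with normality routing
#'
#' Continuous variables are summarised as mean +/- SD when the
#' Shapiro-Wilk test does not reject normality (p >= 0.05) and as
#' median (IQR) otherwise; binary variables as count (%). A constant
#' vector has undefined normality and is routed to median (IQR) with a
#' warning.
#'
#' @param values numeric (continuous) or 0/1-logical (binary) vector.
#' @param kind `"continuous"` or `"binary"`.
#' @return List with the chosen `route`, the formatted `text` summary and
#'   the underlying statistics.
#' @export
describe <- function(values, kind = c("continuous", "binary")) {
  kind <- match.arg(kind)
  values <- values[!is.na(values)]
  if (kind == "binary") {
    v <- as.numeric(values)
    if (!all(v %in% c(0, 1)))
      stop("validation error: binary variable must be 0/1")
    k <- sum(v)
    return(list(kind = "binary", route = "count",
                n = length(v), count = k, percent = 100 * k / length(v),
                text = sprintf("%d (%.0f%%)", k, 100 * k / length(v))))
  }
  if (length(values) < 3)
    stop("validation error: need n >= 3 for normality testing")
  sw <- shapiro_p(values)
  if (is.na(sw)) {
    warning("constant vector: normality undefined, using median (IQR)")
    route <- "median_iqr"
  } else route <- if (sw >= 0.05) "mean_sd" else "median_iqr"
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  text <- if (route == "mean_sd")
    sprintf("%.1f ± %.1f", mean(values), stats::sd(values))
  else sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  list(kind = "continuous", route = route, n = length(values),
       mean = mean(values), sd = stats::sd(values),
       median = q[2], q1 = q[1], q3 = q[3],
       shapiro_p = sw, text = text)
}

#' Compare a variable between two groups
#'
#' Continuous variables use the two-sided independent t test when both
#' groups pass Shapiro-Wilk normality (p >= 0.05), else the Mann-Whitney
#' U test. Binary variables use the Pearson chi-square test (uncorrected)
#' unless any expected cell count is below 5, in which case Fisher's exact
#' test is used. If both groups have zero variance, the parametric test is
#' undefined and the comparison routes to the exact/rank test.
#'
#' @param x,y values in the two groups.
#' @param kind `"continuous"` or `"binary"`.
#' @param test `"auto"` (normality routing) or an explicit `"t"`,
#'   `"wilcoxon"`, `"chisq"`, `"fisher"`.
#' @param var_equal use the pooled-variance Student t (default) rather
#'   than Welch.
#' @return List of class `group_comparison`: summaries, the `test` used,
#'   `statistic` and two-sided `p_value`.
#' @export
compare_groups <- function(x, y, kind = c("continuous", "binary"),
                           test = "auto", var_equal = TRUE) {
  kind <- match.arg(kind)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("validation error: both groups must be non-empty")
  if (kind == "binary") {
    tab <- rbind(c(sum(x), length(x) - sum(x)),
                 c(sum(y), length(y) - sum(y)))
    if (test == "auto") {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      test <- if (any(expected < 5)) "fisher" else "chisq"
    }
    res <- if (test == "fisher") {
      ft <- stats::fisher.test(tab)
      list(statistic = unname(ft$estimate), p = ft$p.value)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      list(statistic = unname(ct$statistic), p = ct$p.value)
    }
  } else {
    if (test == "auto") {
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        test <- "wilcoxon"
      } else {
        px <- shapiro_p(x); py <- shapiro_p(y)
        normal <- !is.na(px) && !is.na(py) && px >= 0.05 && py >= 0.05
        test <- if (normal) "t" else "wilcoxon"
      }
    }
    if (test == "t" && stats::sd(x) == 0 && stats::sd(y) == 0)
      test <- "wilcoxon"
    res <- if (test == "t") {
      tt <- stats::t.test(x, y, var.equal = var_equal)
      list(statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      p <- wt$p.value
      if (is.nan(p)) p <- 1  # every observation tied across both groups
      list(statistic = unname(wt$statistic), p = p)
    }
  }
  structure(list(
    kind = kind, test = test,
    summary_x = if (kind == "binary") sprintf("%d (%.0f%%)", sum(x),
                                              100 * mean(x)) else
      describe_quiet(x),
    summary_y = if (kind == "binary") sprintf("%d (%.0f%%)", sum(y),
                                              100 * mean(y)) else
      describe_quiet(y),
    statistic = res$statistic, p_value = res$p
  ), class = "group_comparison")
}

describe_quiet <- function(v) {
  if (length(v) < 3 || stats::sd(v) == 0)
    return(sprintf("%.1f", stats::median(v)))
  suppressWarnings(describe(v, "continuous")$text)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s; %s test, p = %.4g\n",
              x$summary_x, x$summary_y, x$test, x$p_value))
  invisible(x)
}

#' Correlation with normality routing
#'
#' Pearson when both variables pass Shapiro-Wilk normality (p >= 0.05),
#' Spearman otherwise; two-sided p value.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return List with `r`, `p` and `method`.
#' @export
correlate <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("validation error: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  px <- shapiro_p(x); py <- shapiro_p(y)
  method <- if (!is.na(px) && !is.na(py) && px >= 0.05 && py >= 0.05)
    "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method)
}

#' 1:1 propensity matching on the logit scale
#'
#' Fits a logistic regression of group membership on the covariates,
#' then greedily matches each treated subject (processed in descending
#' propensity score) to the nearest unmatched control on the
#' logit-transformed score, without replacement, within an absolute
#' caliper on the logit scale. Equidistant controls are broken at random
#' (seed the session RNG for reproducibility).
#'
#' @param data data.frame of covariates.
#' @param treatment logical/0-1 vector, or the name of a column of `data`.
#' @param covariates character vector of covariate column names.
#' @param caliper maximum |logit difference| allowed in a pair.
#' @return List of class `match_result`: model `coefficients`, per-subject
#'   `scores` (propensity and logit), `pairs` (row indices and distance),
#'   `caliper` and unmatched counts.
#' @export
propensity_match <- function(data, treatment, covariates, caliper = 0.05) {
  data <- as.data.frame(data)
  if (is.character(treatment) && length(treatment) == 1) {
    tr <- data[[treatment]]
  } else tr <- treatment
  tr <- as.logical(as.numeric(tr))
  if (!any(tr) || all(tr))
    stop("validation error: both arms must be non-empty")
  fml <- stats::as.formula(paste("..tr ~", paste(covariates, collapse = " + ")))
  df <- data[, covariates, drop = FALSE]
  df$..tr <- tr
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged)
    stop("estimation error: propensity model did not converge ",
         "(possible perfect separation of the arms)")
  logit <- as.numeric(stats::predict(fit, type = "link"))
  score <- stats::plogis(logit)
  treated_idx <- which(tr)[order(score[tr], decreasing = TRUE)]
  control_idx <- which(!tr)
  available <- rep(TRUE, length(control_idx))
  pairs <- data.frame(treated = integer(), control = integer(),
                      distance = numeric())
  for (i in treated_idx) {
    d <- abs(logit[control_idx] - logit[i])
    d[!available] <- Inf
    dmin <- min(d)
    if (!is.finite(dmin) || dmin > caliper) next
    cand <- which(d == dmin)
    j <- if (length(cand) > 1) cand[sample.int(length(cand), 1)] else cand
    available[j] <- FALSE
    pairs <- rbind(pairs, data.frame(treated = i,
                                     control = control_idx[j],
                                     distance = dmin))
  }
  structure(list(
    coefficients = stats::coef(fit),
    scores = data.frame(id = seq_along(tr), treated = tr,
                        score = score, logit = logit),
    pairs = pairs, caliper = caliper,
    n_unmatched_treated = sum(tr) - nrow(pairs),
    n_unmatched_control = sum(!tr) - nrow(pairs)
  ), class = "match_result")
}

#' Standardised mean differences for matching balance
#'
#' @param data data.frame of covariates.
#' @param treatment logical vector of arm membership.
#' @param covariates covariate names.
#' @param subset optional row indices to restrict to (e.g. matched rows).
#' @return Named vector of absolute standardised mean differences.
#' @export
standardized_differences <- function(data, treatment, covariates,
                                     subset = NULL) {
  if (!is.null(subset)) {
    data <- data[subset, , drop = FALSE]
    treatment <- treatment[subset]
  }
  vapply(covariates, function(v) {
    a <- as.numeric(data[[v]][treatment])
    b <- as.numeric(data[[v]][!treatment])
    sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
    if (!is.finite(sp) || sp == 0) return(0)
    abs(mean(a) - mean(b)) / sp
  }, numeric(1))
}

#' Bland-Altman agreement
#'
#' Mean bias of paired measurements and the 95% limits of agreement,
#' `bias +/- 1.96 x SD` of the differences.
#'
#' @param a,b paired measurement vectors (length >= 2).
#' @return List with `bias`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    stop("validation error: paired vectors must have equal length")
  if (length(a) < 2) stop("validation error: need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Within-subject coefficient of variation
#'
#' `CV = (SD of paired differences / sqrt(2)) / grand mean x 100`,
#' the square-root-of-two convention for duplicate measurements.
#'
#' @param a,b paired measurement vectors.
#' @return CV in percent.
#' @export
cv_reproducibility <- function(a, b) {
  if (length(a) != length(b))
    stop("validation error: paired vectors must have equal length")
  gm <- mean(c(a, b))
  if (!(gm > 0)) stop("validation error: grand mean must be positive")
  (stats::sd(a - b) / sqrt(2)) / gm * 100
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects model, absolute agreement, single measures,
#' with the F-based 95% confidence interval. `type = "ICC3"` gives the
#' two-way mixed consistency form instead.
#'
#' @param a,b paired measurements (two raters/readings), n >= 5.
#' @param type `"ICC2"` (default, absolute agreement) or `"ICC3"`.
#' @param conf_level confidence level for the interval.
#' @return List with `icc`, `ci_lower`, `ci_upper` and a `degenerate`
#'   flag (no between-subject variance).
#' @export
icc <- function(a, b, type = c("ICC2", "ICC3"), conf_level = 0.95) {
  type <- match.arg(type)
  if (length(a) != length(b))
    stop("validation error: paired vectors must have equal length")
  n <- length(a)
  if (n < 5) stop("validation error: need n >= 5 pairs")
  m <- cbind(a, b)
  k <- 2
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(m)
  msr <- k * stats::var(row_means)
  msc <- n * stats::var(col_means)
  sst <- sum((m - grand)^2)
  sse <- sst - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= mse) {
    warning("degenerate ICC: no between-subject variance beyond error")
    return(list(icc = 0, ci_lower = NA_real_, ci_upper = NA_real_,
                degenerate = TRUE))
  }
  alpha <- 1 - conf_level
  if (type == "ICC3") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fv <- msr / mse
    fl <- fv / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fv * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    return(list(icc = est, ci_lower = (fl - 1) / (fl + k - 1),
                ci_upper = (fu - 1) / (fu + k - 1), degenerate = FALSE))
  }
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # McGraw & Wong (1996) F-based interval for ICC(A,1)
  aa <- k * est / (n * (1 - est))
  bb <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = est, ci_lower = lower, ci_upper = upper, degenerate = FALSE)
}

#' Sample size for a two-sample t test
#'
#' Smallest per-group n so that the two-sided two-sample t test (equal n,
#' common SD) reaches the requested power, computed from the noncentral t
#' distribution. The normal approximation
#' `2 (z_{1-alpha/2} + z_{power})^2 (sd/delta)^2` underestimates n by one
#' at small samples, which is why the exact t-based search is used.
#'
#' @param delta true mean difference (> 0).
#' @param sd common standard deviation (> 0).
#' @param power target power in (0, 1).
#' @param alpha two-sided type-I error in (0, 1), greater than `1 - power`
#'   makes no sense so `power <= alpha` errors.
#' @return Integer n per group (>= 2).
#' @examples
#' sample_size_ttest(5, 5, 0.80, 0.05)
#' @export
sample_size_ttest <- function(delta, sd, power = 0.80, alpha = 0.05) {
  if (delta <= 0 || sd <= 0)
    stop("validation error: delta and sd must be positive")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("validation error: power and alpha must lie in (0, 1)")
  if (power <= alpha)
    stop("validation error: power must exceed alpha")
  for (n in 2:1000000) {
    df <- 2 * (n - 1)
    tc <- stats::qt(1 - alpha / 2, df)
    ncp <- delta / (sd * sqrt(2 / n))
    pw <- 1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
    if (pw >= power) return(n)
  }
  stop("no attainable sample size below 1e6")
}
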