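#' Bin folded angles into an angular distribution
#'
#' @param angles_deg angles in `[0, 90]` (folded; 0 = ML, 90 = RC).
#' @param bin_width_deg bin width in degrees; default 15 (6 bins on
#'   `[0, 90]`).
#' @return list of class `angular_distribution`: `counts`, `bin_edges`, `n`.
#' @export
angular_distribution <- function(angles_deg, bin_width_deg = 15) {
  if (any(angles_deg < 0 | angles_deg > 90))
    stop("angles must be folded to [0, 90] (see fold_angle())")
  edges <- seq(0, 90, by = bin_width_deg)
  if (edges[length(edges)] < 90) edges <- c(edges, 90)
  # right-open bins, except the last which closes at 90
  counts <- as.vector(table(cut(angles_deg, edges, include.lowest = TRUE,
                                right = FALSE)))
  structure(list(counts = counts, bin_edges = edges, n = length(angles_deg)),
            class = "angular_distribution")
}

as_counts <- function(dist) {
  if (inherits(dist, "angular_distribution")) return(dist)
  if (is.numeric(dist) && is.null(dim(dist)))
    return(structure(list(counts = as.vector(dist),
                          bin_edges = seq(0, 90,
                                          length.out = length(dist) + 1L),
                          n = sum(dist)), class = "angular_distribution"))
  stop("expected an angular_distribution or a vector of bin counts")
}

#' Chi-square test of an angular distribution against randomness
#'
#' Pearson chi-square of binned folded orientations against expected counts
#' proportional to bin widths (a uniform distribution on `[0, 90]`); df =
#' bins - 1. With the default equal-width bins this asks whether orientations
#' deviate from "the expected proportions in a random distribution". Expected
#' counts below 5 trigger a warning; setting `merge_bins = TRUE` instead
#' merges adjacent bins until all expectations reach 5.
#'
#' @param dist an [angular_distribution()] or a vector of bin counts (equal
#'   widths assumed for a bare vector).
#' @param merge_bins merge adjacent bins when expected counts fall below 5
#'   (default FALSE: warn only, keep the stated binning).
#' @return list `chi2`, `df`, `p`, `observed`, `expected`.
#' @export
chi_square_vs_random <- function(dist, merge_bins = FALSE) {
  d <- as_counts(dist)
  counts <- d$counts
  widths <- diff(d$bin_edges)
  expected <- d$n * widths / sum(widths)
  if (any(expected < 5)) {
    if (merge_bins) {
      # accumulate adjacent bins left to right until each group's
      # expectation reaches 5; a short final group is folded into the
      # previous one
      grp <- integer(length(counts)); gid <- 1L; acc <- 0
      for (i in seq_along(counts)) {
        grp[i] <- gid
        acc <- acc + expected[i]
        if (acc >= 5 && i < length(counts)) { gid <- gid + 1L; acc <- 0 }
      }
      if (acc < 5 && gid > 1L) grp[grp == gid] <- gid - 1L
      counts <- as.vector(tapply(counts, grp, sum))
      widths <- as.vector(tapply(widths, grp, sum))
      expected <- d$n * widths / sum(widths)
      if (any(expected < 5))
        warning("expected counts below 5 remain after merging")
    } else {
      warning("expected count below 5 in ", sum(expected < 5),
              " bin(s); chi-square approximation may be poor ",
              "(set merge_bins = TRUE to merge)")
    }
  }
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       observed = counts, expected = expected)
}

#' Chi-square comparison of two angular distributions
#'
#' Pearson contingency-table chi-square (no continuity correction) on the
#' binned counts of two groups; df = bins - 1.
#'
#' @param dist_a,dist_b [angular_distribution()]s or count vectors with the
#'   same binning.
#' @return list `chi2`, `df`, `p`.
#' @export
chi_square_between_groups <- function(dist_a, dist_b) {
  a <- as_counts(dist_a)$counts; b <- as_counts(dist_b)$counts
  if (length(a) != length(b)) stop("distributions must share their binning")
  keep <- a + b > 0
  ht <- suppressWarnings(
    stats::chisq.test(rbind(a[keep], b[keep]), correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' One-sample Student's t-test
#'
#' Two-tailed test of the mean of `values` against `mu0` (default 1, the null
#' of no mediolateral enrichment for embryo scores).
#'
#' @param values numeric vector (n >= 2).
#' @param mu0 null mean.
#' @return list `t`, `df`, `p`, `mean`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 1) {
  if (stats::sd(values) == 0) {
    if (all(values == mu0))
      return(list(t = 0, df = length(values) - 1L, p = 1,
                  mean = mu0, n = length(values)))
    stop("degenerate case: zero variance with mean different from mu0")
  }
  ht <- stats::t.test(values, mu = mu0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean = mean(values), n = length(values))
}

#' Two-sample Student's t-test accounting for homogeneity of variance
#'
#' Two-tailed comparison of two groups. `variance_rule = "auto"` (default)
#' performs an F-test on the two variances at alpha = 0.05 and uses the
#' pooled-variance test when homogeneity is not rejected, Welch's test
#' otherwise; `"pooled"` and `"welch"` force either form.
#'
#' @param a,b numeric vectors.
#' @param variance_rule `"auto"`, `"pooled"` or `"welch"`.
#' @return list `t`, `df`, `p`, `variance_rule_used`.
#' @export
two_sample_t <- function(a, b, variance_rule = c("auto", "pooled", "welch")) {
  variance_rule <- match.arg(variance_rule)
  if (identical(a, b) || (stats::sd(c(a, b)) == 0))
    return(list(t = 0, df = length(a) + length(b) - 2L, p = 1,
                variance_rule_used = "pooled"))
  if (length(a) < 2L || length(b) < 2L)
    stop("two_sample_t needs at least 2 observations per group")
  rule <- variance_rule
  if (rule == "auto")
    rule <- if (stats::var.test(a, b)$p.value < 0.05) "welch" else "pooled"
  ht <- stats::t.test(a, b, var.equal = (rule == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), variance_rule_used = rule)
}

#' Paired Student's t-test
#'
#' One-sample t-test of the within-pair differences against zero (pairs are
#' typically the two measurements of one embryo). Identical inputs return
#' p = 1; constant non-zero differences have no variance to test against and
#' raise an error.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list `t`, `df`, `p`, `mean_difference`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = length(d) - 1L, p = 1, mean_difference = 0))
    stop("degenerate case: constant non-zero differences have zero variance")
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean_difference = mean(d))
}

#' One-way ANOVA with Bonferroni post hoc pairwise tests
#'
#' Standard one-way decomposition across groups, followed by pooled-variance
#' pairwise t-tests with Bonferroni correction (pairwise p multiplied by the
#' number of comparisons, capped at 1). Degenerate inputs (zero within-group
#' variance) are guarded: F is 0 with p = 1 when all values are identical,
#' infinite (p = 0) when groups are distinct constants.
#'
#' @param groups list of numeric vectors, or a data.frame with columns
#'   `value` and `group`.
#' @return list `F`, `df1`, `df2`, `p`, `pairwise` (matrix of Bonferroni-
#'   adjusted p-values), `degenerate`.
#' @export
anova_oneway <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups$value, groups$group)
  if (length(groups) < 2L) stop("at least two groups are required")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)),
              labels = names(groups) %||% seq_along(groups))
  ssw <- sum(unlist(lapply(groups, function(x) sum((x - mean(x))^2))))
  if (ssw == 0) {
    ssb <- sum(lengths(groups) *
                 (vapply(groups, mean, numeric(1)) - mean(values))^2)
    Fv <- if (ssb == 0) 0 else Inf
    return(list(F = Fv, df1 = length(groups) - 1L,
                df2 = length(values) - length(groups),
                p = if (ssb == 0) 1 else 0, pairwise = NULL,
                degenerate = TRUE))
  }
  fit <- stats::aov(values ~ g)
  s <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(values, g, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p = s[["Pr(>F)"]][1], pairwise = pw$p.value, degenerate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ols_fit <- function(x, y) {
  if (length(unique(x)) < 2L)
    stop("rank error: constant x within a group, slope is undefined")
  fit <- stats::lm(y ~ x)
  # a perfectly collinear group is legal input; the caller flags it
  # degenerate, so silence summary()'s perfect-fit warning here
  cf <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       slope_se = unname(cf["x", "Std. Error"]),
       residual_ss = sum(stats::residuals(fit)^2),
       df = length(x) - 2L,
       p_slope_zero = unname(cf["x", "Pr(>|t|)"]),
       n = length(x), fit = fit)
}

#' Per-group regression slope tests and between-group slope comparison
#'
#' Fits ordinary least squares within each of two groups, tests each slope
#' against zero (two-tailed t), and compares the slopes with an F-test: the
#' common-slope model (shared slope, separate intercepts) is nested in the
#' separate-slopes model, and
#' F = ((RSS_common - RSS_separate) / 1) / (RSS_separate / (n_a + n_b - 4)).
#' With perfectly collinear data (RSS = 0) the comparison is flagged
#' degenerate instead of reporting an unstable F.
#'
#' @param x_a,y_a,x_b,y_b numeric vectors, >= 3 points per group.
#' @return list `group_a`, `group_b` (each with `slope`, `intercept`,
#'   `slope_se`, `residual_ss`, `df`, `p_slope_zero`, `n`), `F`,
#'   `p_slopes_equal`, `degenerate`.
#' @export
regression_slope_tests <- function(x_a, y_a, x_b, y_b) {
  if (length(x_a) < 3L || length(x_b) < 3L)
    stop("at least 3 points per group are required")
  fa <- ols_fit(x_a, y_a); fb <- ols_fit(x_b, y_b)
  x <- c(x_a, x_b); y <- c(y_a, y_b)
  grp <- factor(rep(c("a", "b"), c(length(x_a), length(x_b))))
  rss_sep <- fa$residual_ss + fb$residual_ss
  m_common <- stats::lm(y ~ grp + x)
  rss_common <- sum(stats::residuals(m_common)^2)
  df2 <- length(x) - 4L
  degenerate <- rss_sep <= .Machine$double.eps * sum(y^2)
  if (degenerate) {
    Fv <- NA_real_; pv <- NA_real_
  } else {
    Fv <- (rss_common - rss_sep) / (rss_sep / df2)
    pv <- stats::pf(Fv, 1, df2, lower.tail = FALSE)
  }
  fa$fit <- NULL; fb$fit <- NULL
  list(group_a = fa, group_b = fb, F = Fv, p_slopes_equal = pv,
       degenerate = degenerate)
}

#' Confidence band of an ordinary least squares mean response
#'
#' The standard OLS confidence interval for the mean response at each
#' requested x (default: the observed x), e.g. the shaded 95% band around a
#' regression line.
#'
#' @param x,y numeric vectors.
#' @param level confidence level (default 0.95).
#' @param at x values at which to evaluate the band.
#' @return data.frame `x`, `fit`, `lwr`, `upr`.
#' @export
confidence_band <- function(x, y, level = 0.95, at = x) {
  fit <- stats::lm(y ~ x)
  pr <- stats::predict(fit, newdata = data.frame(x = at),
                       interval = "confidence", level = level)
  data.frame(x = at, fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
}

#' One-row audit summary of a test result
#'
#' @param name test name.
#' @param result a result list from one of the test functions.
#' @param n sample size(s), collapsed to a string.
#' @param options option string (e.g. the variance rule).
#' @return one-row data.frame `test`, `statistic`, `df`, `p`, `n`, `options`.
#' @export
stat_summary_row <- function(name, result, n = NA, options = "") {
  stat <- result$chi2 %||% result$t %||% result$F %||% NA_real_
  df <- result$df %||% paste(result$df1 %||% "", result$df2 %||% "")
  data.frame(test = name, statistic = as.numeric(stat)[1],
             df = paste(df, collapse = ","),
             p = result$p %||% result$p_slopes_equal %||% NA_real_,
             n = paste(n, collapse = ";"), options = options)
}
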