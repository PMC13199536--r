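#' Coefficient of variation
#'
#' Sample SD (n - 1 denominator) divided by the mean.
#' @param values numeric vector, length >= 2, nonzero mean.
#' @export
coefficient_of_variation <- function(values) {
  stop_if_not(length(values) >= 2, "CV needs at least 2 values")
  m <- mean(values)
  stop_if_not(abs(m) > 0, "CV undefined for zero mean")
  sd(values) / m
}

#' Precision error across vertebrae
#'
#' Root-mean-square of the per-vertebra CVs:
#' `PE = sqrt(sum(CV_j^2) / n)`.
#' @param cv_per_vertebra numeric vector of CVs.
#' @export
precision_error <- function(cv_per_vertebra) {
  stop_if_not(length(cv_per_vertebra) >= 1, "PE needs at least one CV")
  sqrt(mean(cv_per_vertebra^2))
}

#' Absolute relative difference of a pair, percent
#'
#' `|(a - b) / ((a + b)/2)| * 100`; symmetric in its arguments.
#' @param a,b the paired values.
#' @export
absolute_relative_difference <- function(a, b) {
  m <- (a + b) / 2
  stop_if_not(all(abs(m) > 0), "ARD undefined for zero pair mean")
  abs((a - b) / m) * 100
}

#' Paired comparison of intra- vs inter-operator metric means
#'
#' Paired t-test (two-sided, alpha 0.05) on per-vertebra means, with
#' normality (Shapiro-Wilk on the paired differences) and equal-variance
#' (F-test) checks reported as flags; the checks never silently replace
#' the t-test. Significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param intra_means,inter_means equal-length per-vertebra means, n >= 3.
#' @return list with `t`, `p`, `stars`, `normality_p`, `equal_variance_p`,
#'   `degenerate` (zero-variance differences flag).
#' @export
paired_intra_inter_test <- function(intra_means, inter_means) {
  n <- length(intra_means)
  stop_if_not(n == length(inter_means), "paired vectors must have equal length")
  stop_if_not(n >= 3, "paired test needs n >= 3")
  d <- intra_means - inter_means
  degenerate <- sd(d) == 0
  if (degenerate) {
    return(list(t = if (all(d == 0)) 0 else sign(mean(d)) * Inf,
                p = if (all(d == 0)) 1 else 0,
                stars = "", normality_p = NA_real_,
                equal_variance_p = NA_real_, degenerate = TRUE))
  }
  tt <- t.test(intra_means, inter_means, paired = TRUE)
  norm_p <- tryCatch(shapiro.test(d)$p.value, error = function(e) NA_real_)
  var_p <- tryCatch(var.test(intra_means, inter_means)$p.value,
                    error = function(e) NA_real_)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(t = unname(tt$statistic), p = p, stars = stars,
       normality_p = norm_p, equal_variance_p = var_p, degenerate = FALSE)
}

#' Exploratory regression of geometric spread on mechanical variability
#'
#' OLS of the per-vertebra CV of a mechanical metric on the per-vertebra SD
#' of a geometric metric, with R^2 and the slope t-test p-value. Labelled
#' exploratory: with few vertebrae this is a screening analysis, not a
#' confirmatory model.
#'
#' @param sd_geometric per-vertebra SD of the geometric metric.
#' @param cv_mechanical per-vertebra CV of the mechanical metric.
#' @return list with `slope`, `intercept`, `r_squared`, `p`, `n`,
#'   `exploratory = TRUE`.
#' @export
geometric_mechanical_regression <- function(sd_geometric, cv_mechanical) {
  n <- length(sd_geometric)
  stop_if_not(n == length(cv_mechanical), "vectors must have equal length")
  stop_if_not(n >= 3, "regression needs n >= 3")
  stop_if_not(sd(sd_geometric) > 0, "zero variance in predictor")
  fit <- lm(cv_mechanical ~ sd_geometric)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a benign warning
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4], n = n, exploratory = TRUE)
}
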