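# Correlation, model-fit and group-comparison statistics for the
# force / angle / contact-area vs lesion-dimension analysis.

# Two-sided p for a correlation coefficient via the exact t transform,
# t = r * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2.
.cor_p_value <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

new_correlation_result <- function(method, coefficient, n, p) {
  structure(list(method = method,
                 coefficient = coefficient,
                 n = n,
                 p_two_sided = p,
                 evans_label = evans_label(coefficient)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: %s%.4f (%s), n = %d, two-sided P = %.4g\n",
              if (x$method == "pearson") "Pearson" else "Spearman",
              if (x$coefficient >= 0) "(+) " else "(-) ",
              abs(x$coefficient), x$evans_label, x$n, x$p_two_sided))
  invisible(x)
}

#' Pearson correlation with t-distribution p-value and Evans label
#'
#' Product-moment correlation between two paired vectors. The two-sided
#' p-value uses the exact t transform with n - 2 degrees of freedom, the
#' convention used throughout the lesion-dimension analysis.
#'
#' @param x,y paired numeric vectors, n >= 3, each with non-zero variance
#' @return a \code{correlation_result}: \code{method}, \code{coefficient},
#'   \code{n}, \code{p_two_sided} and the Evans verbal label of |r|
#' @examples
#' area <- load_lesion_area_table()
#' pearson_test(area$angle_deg, area$mean)  # r = -0.3688, P = 0.0192
#' @export
pearson_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in x or y", call. = FALSE)
  r <- stats::cor(x, y)
  new_correlation_result("pearson", r, n, .cor_p_value(r, n))
}

#' Spearman rank correlation (tie-corrected) with t-distribution p-value
#'
#' Pearson correlation of average-ranked data (ties receive mean ranks);
#' the p-value uses the same t transform as \code{\link{pearson_test}}.
#'
#' @inheritParams pearson_test
#' @return a \code{correlation_result}
#' @examples
#' ratio <- load_ratio_table()
#' spearman_test(ratio$force_gf, ratio$mean)  # r_s = 0.1068, P = 0.5118
#' @export
spearman_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("rank correlation undefined: zero rank variance", call. = FALSE)
  rs <- stats::cor(rx, ry)
  new_correlation_result("spearman", rs, n, .cor_p_value(rs, n))
}

#' Replicate-level Pearson correlation from cell means and SDs
#'
#' Reconstructs the Pearson correlation that the full replicate-level data
#' would give, using only per-cell summaries, for a balanced design in which
#' the predictor is constant within each cell. With equal replicate count m
#' per cell, cell means \eqn{\bar{y}_i}, cell SDs \eqn{s_i} and predictor
#' values \eqn{z_i}:
#' \deqn{S_{zy} = m \sum_i (z_i - \bar z)(\bar y_i - \bar y)}
#' \deqn{S_{zz} = m \sum_i (z_i - \bar z)^2}
#' \deqn{S_{yy} = m \sum_i (\bar y_i - \bar y)^2 + \sum_i (m - 1) s_i^2}
#' and \eqn{r = S_{zy} / \sqrt{S_{zz} S_{yy}}}. The within-cell replicate
#' scatter enters only the response sum of squares because the predictor does
#' not vary within a cell.
#'
#' @param cells a \code{condition_table} with \code{mean}, \code{sd}, \code{n}
#' @param predictor per-cell predictor: a numeric vector aligned with the
#'   table rows, or the name of a table column (e.g. \code{"force_gf"})
#' @return a \code{correlation_result} with \code{n} equal to the total
#'   replicate count (sum of cell n)
#' @examples
#' pearson_balanced_raw(load_lesion_area_table(), "force_gf")  # r = 0.7816
#' @export
pearson_balanced_raw <- function(cells, predictor) {
  stopifnot(inherits(cells, "condition_table") || is.data.frame(cells))
  if (is.character(predictor)) {
    stopifnot(length(predictor) == 1L, predictor %in% names(cells))
    z <- cells[[predictor]]
  } else {
    z <- predictor
  }
  stopifnot(is.numeric(z), length(z) == nrow(cells))
  if (any(!is.finite(cells$sd)))
    stop("cell SDs are required for the replicate-level reconstruction",
         call. = FALSE)
  m <- unique(cells$n)
  if (length(m) != 1L || is.na(m) || m < 1)
    stop("balanced design required: equal replicate count in every cell",
         call. = FALSE)
  ybar <- cells$mean
  szy <- m * sum((z - mean(z)) * (ybar - mean(ybar)))
  szz <- m * sum((z - mean(z))^2)
  syy <- m * sum((ybar - mean(ybar))^2) + sum((m - 1) * cells$sd^2)
  if (szz == 0 || syy == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- szy / sqrt(szz * syy)
  n_tot <- as.integer(m * nrow(cells))
  new_correlation_result("pearson", r, n_tot, .cor_p_value(r, n_tot))
}

#' Evans verbal label for a correlation coefficient
#'
#' Bands on |r|: 0.00-0.19 very weak, 0.20-0.39 weak, 0.40-0.59 moderate,
#' 0.60-0.79 strong, 0.80-1.0 very strong; exactly 0 denotes no correlation.
#' The bands are applied to |r| at full precision, with half-open boundaries
#' at 0.20, 0.40, 0.60 and 0.80.
#'
#' @param coefficient a correlation coefficient in [-1, 1]
#' @return one of \code{"none"}, \code{"very weak"}, \code{"weak"},
#'   \code{"moderate"}, \code{"strong"}, \code{"very strong"}
#' @export
evans_label <- function(coefficient) {
  stopifnot(is.numeric(coefficient), length(coefficient) == 1L,
            is.finite(coefficient))
  a <- abs(coefficient)
  if (a > 1) stop("|coefficient| must be <= 1", call. = FALSE)
  if (a == 0) return("none")
  if (a < 0.20) "very weak"
  else if (a < 0.40) "weak"
  else if (a < 0.60) "moderate"
  else if (a < 0.80) "strong"
  else "very strong"
}

# R^2 = 1 - SS_res / SS_tot, computed from the residuals directly
.r_squared <- function(fit, y) {
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

new_fit_result <- function(form, a, b, r2, n) {
  structure(list(form = form, a = a, b = b, r_squared = r2, n = n),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  rhs <- if (x$form == "log") "ln(z)" else "x"
  cat(sprintf("y = %.4g %s %s %.4g   (R^2 = %.4g, n = %d)\n",
              x$a, rhs, if (x$b >= 0) "+" else "-", abs(x$b),
              x$r_squared, x$n))
  invisible(x)
}

#' Ordinary least-squares fits: linear and logarithmic
#'
#' \code{fit_linear} fits y = a x + b; \code{fit_log} fits y = a ln(z) + b
#' (z strictly positive). R^2 = 1 - SS_res / SS_tot.
#'
#' @param x,z predictor values (z > 0 for the log form)
#' @param y response values
#' @return a \code{fit_result}: \code{form}, slope \code{a}, intercept
#'   \code{b}, \code{r_squared}, \code{n}
#' @examples
#' X <- recover_contact_area_table()
#' x90 <- subset(X, angle_deg == 90)
#' fit_log(x90$force_gf, x90$mean)  # a = 2.693, b = 0.892, R^2 = 0.893
#' @export
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor: zero variance",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  new_fit_result("linear", unname(stats::coef(fit)[2]),
                 unname(stats::coef(fit)[1]), .r_squared(fit, y), n)
}

#' @rdname fit_linear
#' @export
fit_log <- function(z, y) {
  stopifnot(is.numeric(z), is.numeric(y), length(z) == length(y))
  if (any(z <= 0)) stop("log fit requires strictly positive predictor",
                        call. = FALSE)
  n <- length(z)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  lz <- log(z)
  if (stats::sd(lz) == 0) stop("degenerate predictor: zero variance",
                               call. = FALSE)
  fit <- stats::lm(y ~ lz)
  new_fit_result("log", unname(stats::coef(fit)[2]),
                 unname(stats::coef(fit)[1]), .r_squared(fit, y), n)
}

#' Compare logarithmic and linear fits of the same points
#'
#' Fits y = a ln(z) + b and y = a z + b to identical points and labels the
#' dose-response behaviour by the larger R^2 (\code{"Log"} strictly wins;
#' a tie is labelled \code{"Linear"}).
#'
#' @inheritParams fit_log
#' @return a \code{model_comparison}: \code{log_fit}, \code{linear_fit},
#'   \code{log_r2}, \code{linear_r2}, \code{behavior}
#' @export
compare_fits <- function(z, y) {
  lf <- fit_log(z, y)
  nf <- fit_linear(z, y)
  structure(list(log_fit = lf, linear_fit = nf,
                 log_r2 = lf$r_squared, linear_r2 = nf$r_squared,
                 behavior = if (lf$r_squared > nf$r_squared) "Log"
                            else "Linear"),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("log R^2 = %.4f, linear R^2 = %.4f -> %s\n",
              x$log_r2, x$linear_r2, x$behavior))
  invisible(x)
}

#' Ratio of lesion area to contact area
#'
#' @param area_mm2 ablated lesion area (mm^2)
#' @param contact_area_mm2 catheter contact area (mm^2), > 0
#' @return dimensionless ratio (vectorized)
#' @export
lesion_contact_ratio <- function(area_mm2, contact_area_mm2) {
  stopifnot(is.numeric(area_mm2), is.numeric(contact_area_mm2))
  if (any(contact_area_mm2 <= 0))
    stop("contact area must be positive", call. = FALSE)
  area_mm2 / contact_area_mm2
}

#' Pooled-variance two-sample Student's t-test
#'
#' Classic equal-variance two-sample t-test, two-sided, with significance
#' declared at the 0.05 level.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2
#' @param label_a,label_b optional group labels carried into the result
#' @return a \code{pairwise_comparison}: \code{t_statistic}, \code{df},
#'   \code{p_two_sided}, \code{significant}
#' @export
students_t_test <- function(group_a, group_b,
                            label_a = "A", label_b = "B") {
  stopifnot(is.numeric(group_a), is.numeric(group_b),
            length(group_a) >= 2, length(group_b) >= 2)
  if (stats::var(group_a) + stats::var(group_b) == 0)
    stop("zero pooled variance: t statistic undefined", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  structure(list(group_a = label_a, group_b = label_b,
                 t_statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_two_sided = ht$p.value,
                 significant = ht$p.value < 0.05),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: t = %.3f (df = %g), P = %.4g -> %s\n",
              x$group_a, x$group_b, x$t_statistic, x$df, x$p_two_sided,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
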