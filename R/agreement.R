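# Instrument-comparison statistics: accuracy/precision of paired
# differences, Bland-Altman 95% limits of agreement, RMSE, normality-gated
# correlation (Pearson/Spearman after Shapiro-Wilk on the differences), and
# TOST equivalence inside a +-5%-of-reference-mean zone.

#' Accuracy, precision and RMSE of paired measurements
#'
#' Relative error is signed (test instrument minus reference), absolute
#' error its magnitude; accuracy = mean, precision = standard deviation.
#'
#' @param imu_values,ref_values paired per-stride values (matched strides
#'   only).
#' @return one-row data.frame.
#' @export
error_summary <- function(imu_values, ref_values) {
  if (!length(imu_values) || length(imu_values) != length(ref_values))
    stop("need a non-empty equal-length pairing")
  d <- imu_values - ref_values
  data.frame(n = length(d), rel_mean = mean(d), rel_sd = stats::sd(d),
             abs_mean = mean(abs(d)), abs_sd = stats::sd(abs(d)),
             rmse = sqrt(mean(d^2)))
}

#' Bland-Altman limits of agreement
#'
#' 95% limits: mean difference +- 1.96 standard deviations.
#'
#' @inheritParams error_summary
#' @return list with `mean_diff`, `sd_diff`, `loa` (lower, upper).
#' @export
bland_altman <- function(imu_values, ref_values) {
  if (length(imu_values) < 2L) stop("need at least 2 pairs")
  d <- imu_values - ref_values
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa = c(lower = m - 1.96 * s,
                                           upper = m + 1.96 * s))
}

# Shapiro-Wilk normality gate on the paired differences (alpha = 0.05);
# n > 5000 is subsampled deterministically to the test's supported range
differences_normal <- function(d, alpha = 0.05) {
  d <- d[is.finite(d)]
  if (length(d) < 3L || stats::sd(d) == 0) return(NA)
  if (length(d) > 5000L) d <- d[round(seq(1, length(d), length.out = 5000L))]
  stats::shapiro.test(d)$p.value >= alpha
}

#' Correlation between instruments
#'
#' Pearson when the paired differences pass Shapiro-Wilk normality at
#' alpha = 0.05, Spearman otherwise. The magnitude is classified as
#' very high (> 0.90), high (0.70-0.90), moderate (0.50-0.70), low
#' (0.30-0.50) or negligible (< 0.30).
#'
#' @inheritParams error_summary
#' @param on_differences gate normality on the paired differences (default)
#'   or on the raw series.
#' @return list with `coefficient`, `type`, `p_value`, `classification`.
#' @export
correlation <- function(imu_values, ref_values, on_differences = TRUE) {
  if (length(imu_values) < 3L) stop("need at least 3 pairs")
  if (stats::sd(imu_values) == 0 || stats::sd(ref_values) == 0)
    return(list(coefficient = NA_real_, type = "undefined",
                p_value = NA_real_, classification = "undefined"))
  normal <- if (on_differences) differences_normal(imu_values - ref_values)
    else isTRUE(differences_normal(imu_values)) &&
         isTRUE(differences_normal(ref_values))
  type <- if (isTRUE(normal)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(imu_values, ref_values,
                                         method = type))
  r <- unname(ct$estimate)
  cls <- if (abs(r) > 0.9) "very high" else if (abs(r) > 0.7) "high" else
    if (abs(r) > 0.5) "moderate" else if (abs(r) > 0.3) "low" else
      "negligible"
  list(coefficient = r, type = type, p_value = ct$p.value,
       classification = cls)
}

#' TOST equivalence test
#'
#' Two one-sided tests that the mean (parametric, paired t) or the
#' location (non-parametric, Wilcoxon signed-rank) of the paired
#' differences lies within an equivalence zone of +-5% of the reference
#' series mean. The branch is gated by Shapiro-Wilk on the differences;
#' p is the larger of the two one-sided p-values.
#'
#' @inheritParams error_summary
#' @param zone_fraction half-width of the zone as a fraction of the
#'   reference mean.
#' @param zone explicit zone half-width (overrides `zone_fraction`).
#' @param alpha significance level.
#' @return list with `zone`, `test` ("t" or "wilcoxon"), `p_value`,
#'   `equivalent`.
#' @export
equivalence_test <- function(imu_values, ref_values, zone_fraction = 0.05,
                             zone = NULL, alpha = 0.05) {
  d <- imu_values - ref_values
  if (is.null(zone)) zone <- zone_fraction * abs(mean(ref_values))
  if (zone == 0) stop("equivalence zone is zero (zero-mean reference)")
  normal <- differences_normal(d)
  if (isTRUE(normal)) {
    p1 <- stats::t.test(d, mu = -zone, alternative = "greater")$p.value
    p2 <- stats::t.test(d, mu = zone, alternative = "less")$p.value
    test <- "t"
  } else {
    if (stats::sd(d) == 0) {
      # degenerate: constant differences; decide by location alone
      inside <- abs(d[1]) < zone
      return(list(zone = zone, test = "wilcoxon",
                  p_value = if (inside) 0 else 1, equivalent = inside))
    }
    p1 <- suppressWarnings(stats::wilcox.test(
      d, mu = -zone, alternative = "greater"))$p.value
    p2 <- suppressWarnings(stats::wilcox.test(
      d, mu = zone, alternative = "less"))$p.value
    test <- "wilcoxon"
  }
  p <- max(p1, p2)
  list(zone = zone, test = test, p_value = p, equivalent = p < alpha)
}

#' Filter a per-stride parameter table by turning status
#'
#' @param param_table table with an `is_turning` column.
#' @param mode "include" keeps all strides, "exclude" drops turning
#'   strides.
#' @return filtered table with attribute `turning_mode`.
#' @export
turning_filter <- function(param_table, mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  out <- if (mode == "exclude")
    param_table[!isTRUE_vec(param_table$is_turning), , drop = FALSE]
  else param_table
  attr(out, "turning_mode") <- mode
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

GAIT_PARAMETERS <- c("stride_duration", "swing_duration", "stance_duration",
                     "cadence", "stride_length", "swing_width", "mtc",
                     "speed")

#' Agreement report between two per-stride parameter tables
#'
#' One row per gait parameter: accuracy/precision of relative and absolute
#' errors, Bland-Altman limits, RMSE, normality-gated correlation and TOST
#' equivalence, computed over matched strides.
#'
#' @param imu_table,ref_table matched per-stride tables (equal row counts,
#'   row i paired with row i).
#' @param parameters parameter columns to compare.
#' @param alpha significance level for the equivalence verdict.
#' @return data.frame of class `agreement_report`.
#' @export
agreement_report <- function(imu_table, ref_table,
                             parameters = GAIT_PARAMETERS, alpha = 0.05) {
  stopifnot(nrow(imu_table) == nrow(ref_table))
  rows <- lapply(parameters, function(p) {
    x <- imu_table[[p]]; y <- ref_table[[p]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      return(data.frame(parameter = p, n = length(x), imu_mean = NA,
                        imu_sd = NA, ref_mean = NA, ref_sd = NA,
                        rel_mean = NA, rel_sd = NA, abs_mean = NA,
                        abs_sd = NA, loa_lower = NA, loa_upper = NA,
                        rmse = NA, corr = NA, corr_type = NA, corr_p = NA,
                        zone = NA, equiv_test = NA, equiv_p = NA,
                        equivalent = NA))
    es <- error_summary(x, y)
    ba <- bland_altman(x, y)
    co <- correlation(x, y)
    eq <- equivalence_test(x, y, alpha = alpha)
    data.frame(parameter = p, n = es$n,
               imu_mean = mean(x), imu_sd = stats::sd(x),
               ref_mean = mean(y), ref_sd = stats::sd(y),
               rel_mean = es$rel_mean, rel_sd = es$rel_sd,
               abs_mean = es$abs_mean, abs_sd = es$abs_sd,
               loa_lower = ba$loa[["lower"]], loa_upper = ba$loa[["upper"]],
               rmse = es$rmse, corr = co$coefficient, corr_type = co$type,
               corr_p = co$p_value, zone = eq$zone, equiv_test = eq$test,
               equiv_p = eq$p_value, equivalent = eq$equivalent)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", class(out))
  out
}

#' Root-mean-square deviation between paired runs
#' @inheritParams error_summary
#' @export
rmsd <- function(imu_values, ref_values) {
  if (!length(imu_values) || length(imu_values) != length(ref_values))
    stop("need a non-empty equal-length pairing")
  sqrt(mean((imu_values - ref_values)^2))
}

#' Print an agreement report as a compact text table
#' @param x an `agreement_report`.
#' @param ... unused.
#' @export
print.agreement_report <- function(x, ...) {
  df <- data.frame(
    Parameter = x$parameter, n = x$n,
    `Rel.Error` = sprintf("%.2f(%.2f)", x$rel_mean, x$rel_sd),
    `Abs.Error` = sprintf("%.2f(%.2f)", x$abs_mean, x$abs_sd),
    `Lim.Agr` = sprintf("[%.2f,%.2f]", x$loa_lower, x$loa_upper),
    RMSE = sprintf("%.2f", x$rmse),
    Corr = sprintf("%.2f(%s)", x$corr, substr(x$corr_type, 1, 1)),
    Equiv = sprintf("+-%.2f(%.2g)%s", x$zone, x$equiv_p,
                    ifelse(isTRUE_vec(x$equivalent), "*", "")),
    check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
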