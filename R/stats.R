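#' Descriptive summary
#'
#' Arithmetic mean and sample standard deviation, the form in which cohort
#' parameters are reported.
#'
#' @param values numeric vector, length >= 2, no missing values.
#' @return Named numeric `c(mean, sd)`.
#' @export
describe <- function(values) {
  if (anyNA(values)) stop("missing values are not allowed")
  if (length(values) < 2L) stop("need at least two values")
  c(mean = mean(values), sd = stats::sd(values))
}

fisher_ci <- function(r, n, alpha = 0.05) {
  z <- atanh(r)
  half <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Pearson correlation confidence interval from r and n alone
#'
#' Fisher z-transform interval: `tanh(atanh(r) +/- z_{1-alpha/2} / sqrt(n-3))`,
#' with the two-sided p-value for the null r = 0 from
#' `t = r * sqrt((n-2) / (1-r^2))`. This closed form lets printed
#' correlation tables (r, n) be checked without the raw data.
#'
#' @param r Pearson correlation coefficient.
#' @param n number of pairs (>= 4).
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @return list with `r`, `ci_low`, `ci_high`, `r2`, `p`, `n`.
#' @export
pearson_ci_from_r <- function(r, n, alpha = 0.05) {
  stopifnot(n >= 4, abs(r) <= 1)
  ci <- fisher_ci(r, n, alpha)
  p <- if (abs(r) == 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, ci_low = ci[1], ci_high = ci[2], r2 = r^2, p = p, n = n)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param reference,test paired numeric vectors (equal length >= 4, no
#'   missing values, nonzero variance in both).
#' @param alpha two-sided significance level.
#' @return list as in [pearson_ci_from_r()].
#' @export
pearson_ci <- function(reference, test, alpha = 0.05) {
  check_pairs(reference, test, min_n = 4L)
  if (stats::sd(reference) == 0 || stats::sd(test) == 0) {
    stop("zero variance in one of the lists; correlation undefined")
  }
  r <- stats::cor(reference, test)
  pearson_ci_from_r(r, length(reference), alpha)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `test - reference`. Bias is their mean; the 95% limits of
#' agreement are `bias +/- 1.96 * sd(differences)` (the conventional normal
#' quantile, not a t quantile). The proportional-bias trend is the ordinary
#' least-squares regression of the differences on the pair means, with 95%
#' confidence intervals on slope and intercept.
#'
#' @param reference,test paired numeric vectors (length >= 3).
#' @return list with `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `trend_slope`, `trend_intercept`, `trend_slope_ci`,
#'   `trend_intercept_ci`, `n`.
#' @export
bland_altman <- function(reference, test) {
  check_pairs(reference, test, min_n = 3L)
  d <- test - reference
  m <- (test + reference) / 2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  if (stats::sd(m) == 0) {
    slope <- 0; intercept <- bias
    sci <- c(NA_real_, NA_real_); ici <- c(NA_real_, NA_real_)
  } else {
    fit <- stats::lm(d ~ m)
    co <- stats::coef(fit)
    intercept <- unname(co[1]); slope <- unname(co[2])
    ci <- suppressWarnings(stats::confint(fit, level = 0.95))
    ici <- unname(ci[1, ]); sci <- unname(ci[2, ])
  }
  list(bias = bias, sd_diff = sd_d, loa_low = loa[1], loa_high = loa[2],
       trend_slope = slope, trend_intercept = intercept,
       trend_slope_ci = sci, trend_intercept_ci = ici,
       n = length(d))
}

#' Paired t-test on device differences
#'
#' Two-sided paired t-test on `test - reference` with the confidence
#' interval of the mean difference. Degenerate all-equal differences are
#' handled explicitly: if every difference is zero the devices agree exactly
#' (p = 1 by convention); if the differences are a nonzero constant the
#' statistic is undefined (p = NA) and the CI collapses to the constant.
#'
#' @param reference,test paired numeric vectors (length >= 3).
#' @param alpha two-sided significance level.
#' @return list with `p`, `diff_ci_low`, `diff_ci_high`, `mean_diff`, `n`,
#'   `degenerate`.
#' @export
paired_ttest <- function(reference, test, alpha = 0.05) {
  check_pairs(reference, test, min_n = 3L)
  d <- test - reference
  if (stats::sd(d) == 0) {
    return(list(p = if (all(d == 0)) 1 else NA_real_,
                diff_ci_low = mean(d), diff_ci_high = mean(d),
                mean_diff = mean(d), n = length(d), degenerate = TRUE))
  }
  tt <- stats::t.test(test, reference, paired = TRUE, conf.level = 1 - alpha)
  list(p = unname(tt$p.value),
       diff_ci_low = unname(tt$conf.int[1]),
       diff_ci_high = unname(tt$conf.int[2]),
       mean_diff = unname(tt$estimate), n = length(d), degenerate = FALSE)
}

check_pairs <- function(reference, test, min_n = 3L) {
  if (length(reference) != length(test)) stop("reference and test lengths differ")
  if (anyNA(reference) || anyNA(test)) stop("missing values are not allowed")
  if (length(reference) < min_n) {
    stop(sprintf("need at least %d pairs, got %d", min_n, length(reference)))
  }
  invisible(TRUE)
}

#' Device-comparison tables for paired morphometry results
#'
#' Given per-specimen morphometry tables from a reference and a test device
#' (matched by an `id` column), produces the three standard validation
#' tables: Pearson correlations with 95% CIs, R^2 and p; descriptive
#' mean +/- SD per device; and paired t-tests with CIs of the difference.
#' Bland-Altman summaries per parameter are included for plotting.
#' Parameters with zero variance on either device get NA correlation rows
#' (flagged with a warning).
#'
#' @param reference_df,test_df data frames with an `id` column and the
#'   columns of [morphometry_columns()].
#' @param alpha two-sided significance level.
#' @param parameters which columns to compare; default the nine structure
#'   parameters (CNR is reported in the descriptives only).
#' @return list of data frames: `correlations`, `descriptives`, `ttests`,
#'   `bland_altman` (one row per parameter).
#' @export
compare_morphometry <- function(reference_df, test_df, alpha = 0.05,
                                parameters = setdiff(morphometry_columns(),
                                                     "CNR")) {
  if (!"id" %in% names(reference_df) || !"id" %in% names(test_df)) {
    stop("both tables need an 'id' column for specimen pairing")
  }
  ids <- intersect(reference_df$id, test_df$id)
  if (length(ids) != nrow(reference_df) || length(ids) != nrow(test_df)) {
    stop("specimen IDs do not match between the two tables")
  }
  if (length(ids) < 4L) stop("need at least 4 paired specimens (n < 4)")
  ref <- reference_df[match(ids, reference_df$id), , drop = FALSE]
  tst <- test_df[match(ids, test_df$id), , drop = FALSE]

  corr <- list(); desc <- list(); tt <- list(); ba <- list()
  desc_params <- intersect(morphometry_columns(), names(ref))
  for (p in desc_params) {
    dr <- describe(ref[[p]]); dt <- describe(tst[[p]])
    desc[[p]] <- data.frame(parameter = p,
                            reference_mean = dr["mean"], reference_sd = dr["sd"],
                            test_mean = dt["mean"], test_sd = dt["sd"],
                            row.names = NULL)
  }
  for (p in parameters) {
    x <- ref[[p]]; y <- tst[[p]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero variance for parameter ", p, "; correlation undefined")
      corr[[p]] <- data.frame(parameter = p, r = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, r2 = NA_real_, p = NA_real_,
                              n = length(x), row.names = NULL)
    } else {
      pc <- pearson_ci(x, y, alpha)
      corr[[p]] <- data.frame(parameter = p, r = pc$r, ci_low = pc$ci_low,
                              ci_high = pc$ci_high, r2 = pc$r2, p = pc$p,
                              n = pc$n, row.names = NULL)
    }
    pt <- paired_ttest(x, y, alpha)
    tt[[p]] <- data.frame(parameter = p, p = pt$p, diff_ci_low = pt$diff_ci_low,
                          diff_ci_high = pt$diff_ci_high,
                          mean_diff = pt$mean_diff, row.names = NULL)
    b <- bland_altman(x, y)
    ba[[p]] <- data.frame(parameter = p, bias = b$bias, loa_low = b$loa_low,
                          loa_high = b$loa_high, trend_slope = b$trend_slope,
                          trend_intercept = b$trend_intercept,
                          row.names = NULL)
  }
  list(correlations = do.call(rbind, corr),
       descriptives = do.call(rbind, desc),
       ttests = do.call(rbind, tt),
       bland_altman = do.call(rbind, ba))
}
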