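# Method-agreement statistics for paired saliva/plasma measurements of one
# analyte: Pearson correlation, OLS, ordinary least products (geometric-mean)
# regression with bias classification, and Bland-Altman limits of agreement.
#
# Orientation convention throughout: x = plasmatic level, y = salivary level;
# differences are saliva - plasma, so a positive mean difference means saliva
# reads higher.

#' Construct a paired saliva/plasma dataset
#'
#' One value pair per subject for a single analyte within one cycle-phase x
#' timepoint stratum; the unit of all agreement statistics.
#'
#' @param plasma,saliva Numeric vectors of equal length (>= 3), finite, one
#'   pair per subject.
#' @param subject_id Optional subject identifiers.
#' @param analyte,cycle_phase,timepoint Optional stratum labels (`"DC"`,
#'   `"TC"`, `"SB"`; `"F"`, `"L"`; `"pre"`, `"post"`).
#' @return A list of class `"paired_dataset"`.
#' @export
paired_dataset <- function(plasma, saliva, subject_id = NULL,
                           analyte = NA_character_,
                           cycle_phase = NA_character_,
                           timepoint = NA_character_) {
  plasma <- as.numeric(plasma); saliva <- as.numeric(saliva)
  if (length(plasma) != length(saliva))
    stop("plasma and saliva must have the same length (paired design)",
         call. = FALSE)
  if (length(plasma) < 3)
    stop("insufficient data: at least 3 pairs are required", call. = FALSE)
  if (any(!is.finite(plasma)) || any(!is.finite(saliva)))
    stop("all paired values must be finite (no missing pair members)",
         call. = FALSE)
  if (is.null(subject_id)) subject_id <- seq_along(plasma)
  structure(list(plasma = plasma, saliva = saliva, subject_id = subject_id,
                 analyte = analyte, cycle_phase = cycle_phase,
                 timepoint = timepoint, n = length(plasma)),
            class = "paired_dataset")
}

as_paired <- function(data) {
  if (inherits(data, "paired_dataset")) return(data)
  if (is.data.frame(data) && all(c("plasma", "saliva") %in% names(data)))
    return(paired_dataset(data$plasma, data$saliva))
  stop("expected a paired_dataset or a data frame with plasma/saliva columns",
       call. = FALSE)
}

#' Pearson correlation between salivary and plasmatic levels
#'
#' Product-moment correlation with its two-sided p-value from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom.
#'
#' @param data A [paired_dataset()].
#' @return A list with `r`, `p`, `df`, `n`.
#' @export
pearson_r <- function(data) {
  data <- as_paired(data)
  if (stats::sd(data$plasma) == 0 || stats::sd(data$saliva) == 0)
    stop("degenerate data: zero variance in plasma or saliva values",
         call. = FALSE)
  ct <- stats::cor.test(data$plasma, data$saliva, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = data$n)
}

#' Ordinary least squares line of saliva on plasma
#'
#' The display regression: saliva ~ plasma, with t-based confidence
#' intervals on n - 2 degrees of freedom.
#'
#' @param data A [paired_dataset()].
#' @param alpha Two-sided significance level for the intervals.
#' @return A list with `slope`, `intercept`, `slope_ci`, `intercept_ci`, `n`.
#' @export
ols_fit <- function(data, alpha = 0.05) {
  data <- as_paired(data)
  if (stats::sd(data$plasma) == 0)
    stop("degenerate data: zero variance in plasma (regressor)", call. = FALSE)
  fit <- stats::lm(saliva ~ plasma,
                   data = data.frame(plasma = data$plasma,
                                     saliva = data$saliva))
  ci <- stats::confint(fit, level = 1 - alpha)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci = unname(ci["plasma", ]),
       intercept_ci = unname(ci["(Intercept)", ]),
       n = data$n)
}

#' Ordinary least products (geometric-mean) regression with bias flags
#'
#' Symmetric regression for method comparison, appropriate when neither
#' measurement is error-free. The slope is `b = sign(r) * sd(y) / sd(x)`
#' (y = saliva, x = plasma) and the intercept `a = mean(y) - b * mean(x)`.
#'
#' The analytic 95% confidence interval for the slope is the standard
#' geometric-mean-regression interval: with
#' `B = qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)`,
#' the interval is `b * (sqrt(B + 1) -/+ sqrt(B))` (for positive `b`; the
#' mirrored form for negative `b`). Intercept interval endpoints come from
#' `a = mean(y) - b* mean(x)` evaluated at the opposing slope endpoints.
#' Alternatively a percentile bootstrap over subject resamples is available.
#'
#' Bias classification: differential bias when the intercept interval
#' excludes 0; proportional bias when the slope interval excludes 1.
#'
#' @param data A [paired_dataset()].
#' @param alpha Two-sided significance level (default 0.05).
#' @param ci_method `"analytic"` (F-based, default) or `"bootstrap"`
#'   (percentile over `boot_reps` pair resamples; uses the current RNG
#'   state, so set a seed for reproducibility).
#' @param boot_reps Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return An object of class `"olp_fit"`: list with `r`, `a`, `b`,
#'   `a_ci`, `b_ci`, `n`, `differential_bias`, `proportional_bias`,
#'   `alpha`, `ci_method`.
#' @examples
#' d <- paired_dataset(plasma = c(1, 2, 3, 4, 5),
#'                     saliva = c(1.2, 2.1, 2.9, 4.2, 4.8))
#' olp_fit(d)
#' @export
olp_fit <- function(data, alpha = 0.05,
                    ci_method = c("analytic", "bootstrap"),
                    boot_reps = 20000) {
  data <- as_paired(data)
  ci_method <- match.arg(ci_method)
  x <- data$plasma; y <- data$saliva; n <- data$n
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("degenerate data: zero variance in plasma or saliva values",
         call. = FALSE)
  r <- stats::cor(x, y)
  if (r == 0)
    stop("undefined slope sign: correlation is exactly zero", call. = FALSE)
  b <- sign(r) * sy / sx
  a <- mean(y) - b * mean(x)
  if (ci_method == "analytic") {
    B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r^2) / (n - 2)
    half <- c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))
    b_ci <- sort(b * half)
    a_ci <- sort(mean(y) - rev(b_ci) * mean(x))
  } else {
    est <- function(xx, yy) {
      if (stats::sd(xx) == 0 || stats::sd(yy) == 0) return(c(NA, NA))
      rr <- stats::cor(xx, yy)
      if (is.na(rr) || rr == 0) return(c(NA, NA))
      bb <- sign(rr) * stats::sd(yy) / stats::sd(xx)
      c(bb, mean(yy) - bb * mean(xx))
    }
    idx <- matrix(sample.int(n, n * boot_reps, replace = TRUE), nrow = n)
    bs <- apply(idx, 2, function(i) est(x[i], y[i]))
    b_ci <- unname(stats::quantile(bs[1, ], c(alpha / 2, 1 - alpha / 2),
                                   na.rm = TRUE))
    a_ci <- unname(stats::quantile(bs[2, ], c(alpha / 2, 1 - alpha / 2),
                                   na.rm = TRUE))
  }
  structure(list(r = r, a = a, b = b, a_ci = a_ci, b_ci = b_ci, n = n,
                 differential_bias = !(a_ci[1] <= 0 && 0 <= a_ci[2]),
                 proportional_bias = !(b_ci[1] <= 1 && 1 <= b_ci[2]),
                 alpha = alpha, ci_method = ci_method),
            class = "olp_fit")
}

#' @export
print.olp_fit <- function(x, digits = 3, ...) {
  cat("Ordinary least products regression (saliva on plasma)\n")
  cat(sprintf("  n = %d, r = %.*f\n", x$n, digits, x$r))
  cat(sprintf("  intercept a = %.*f [%.*f, %.*f]%s\n", digits, x$a,
              digits, x$a_ci[1], digits, x$a_ci[2],
              if (x$differential_bias) "  * differential bias" else ""))
  cat(sprintf("  slope     b = %.*f [%.*f, %.*f]%s\n", digits, x$b,
              digits, x$b_ci[1], digits, x$b_ci[2],
              if (x$proportional_bias) "  * proportional bias" else ""))
  invisible(x)
}

#' Bland-Altman method of differences
#'
#' Differences `d = saliva - plasma` are summarised by their mean and SD
#' (n - 1 denominator); limits of agreement are `mean(d) +/- 1.96 sd(d)`
#' (fixed 1.96 multiplier). Confidence intervals use t quantiles on n - 1
#' degrees of freedom: the mean difference gets `+/- t * sd/sqrt(n)`, each
#' limit of agreement gets `+/- t * sd * sqrt(1/n + 1.96^2 / (2(n-1)))`.
#' Proportional bias is assessed by the OLS regression of differences on
#' pair means `(saliva + plasma)/2`: flagged when the slope's interval
#' excludes 0 (equivalently, two-sided p < alpha).
#'
#' @param data A [paired_dataset()].
#' @param alpha Two-sided significance level for the confidence bands.
#' @param loa_multiplier SD multiplier for the limits of agreement
#'   (default 1.96, the 95% normal convention).
#' @return An object of class `"bland_altman"`: list with `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `mean_diff_ci`, `loa_low_ci`,
#'   `loa_high_ci`, `prop_slope`, `prop_slope_ci`, `prop_p`, `n`,
#'   `differential_bias`, `proportional_bias`, `outside_loa_count`,
#'   `degenerate` (TRUE when sd of differences is 0 and the limits collapse).
#' @examples
#' d <- paired_dataset(plasma = c(1, 2, 3, 4, 5),
#'                     saliva = c(1.1, 1.8, 3.0, 4.3, 4.9))
#' bland_altman(d)
#' @export
bland_altman <- function(data, alpha = 0.05, loa_multiplier = 1.96) {
  data <- as_paired(data)
  d <- data$saliva - data$plasma
  m <- (data$saliva + data$plasma) / 2
  n <- data$n
  md <- mean(d)
  sdd <- stats::sd(d)
  loa_low <- md - loa_multiplier * sdd
  loa_high <- md + loa_multiplier * sdd
  tq <- stats::qt(1 - alpha / 2, n - 1)
  degenerate <- sdd == 0
  if (degenerate) {
    warning("sd of differences is 0: limits of agreement collapse to the ",
            "mean difference and their confidence intervals are undefined",
            call. = FALSE)
    md_ci <- c(md, md)
    loa_low_ci <- loa_high_ci <- c(NA_real_, NA_real_)
  } else {
    md_ci <- md + c(-1, 1) * tq * sdd / sqrt(n)
    loa_half <- tq * sdd * sqrt(1 / n + loa_multiplier^2 / (2 * (n - 1)))
    loa_low_ci <- loa_low + c(-1, 1) * loa_half
    loa_high_ci <- loa_high + c(-1, 1) * loa_half
  }
  # differences-on-means OLS for proportional bias
  if (stats::sd(m) == 0 || degenerate) {
    prop_slope <- if (stats::sd(m) == 0) NA_real_ else 0
    prop_ci <- c(NA_real_, NA_real_); prop_p <- NA_real_
    prop_bias <- FALSE
  } else {
    fit <- stats::lm(d ~ m)
    sm <- stats::summary.lm(fit)$coefficients
    prop_slope <- unname(stats::coef(fit)[2])
    prop_ci <- unname(stats::confint(fit, level = 1 - alpha)["m", ])
    prop_p <- unname(sm["m", "Pr(>|t|)"])
    prop_bias <- !(prop_ci[1] <= 0 && 0 <= prop_ci[2])
  }
  structure(list(
    mean_diff = md, sd_diff = sdd, loa_low = loa_low, loa_high = loa_high,
    mean_diff_ci = md_ci, loa_low_ci = loa_low_ci, loa_high_ci = loa_high_ci,
    prop_slope = prop_slope, prop_slope_ci = prop_ci, prop_p = prop_p,
    n = n,
    differential_bias = !(md_ci[1] <= 0 && 0 <= md_ci[2]),
    proportional_bias = prop_bias,
    outside_loa_count = sum(abs(d - md) > loa_multiplier * sdd),
    degenerate = degenerate, alpha = alpha),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat("Bland-Altman method of differences (saliva - plasma)\n")
  cat(sprintf("  n = %d, mean difference = %.*f [%.*f, %.*f]%s\n",
              x$n, digits, x$mean_diff, digits, x$mean_diff_ci[1],
              digits, x$mean_diff_ci[2],
              if (x$differential_bias) "  * differential bias" else ""))
  cat(sprintf("  limits of agreement: [%.*f, %.*f] (sd = %.*f)\n",
              digits, x$loa_low, digits, x$loa_high, digits, x$sd_diff))
  cat(sprintf("  differences-on-means slope = %.*f (p = %.3g)%s\n",
              digits, x$prop_slope, x$prop_p,
              if (x$proportional_bias) "  * proportional bias" else ""))
  cat(sprintf("  points outside limits: %d\n", x$outside_loa_count))
  invisible(x)
}

#' Run the full agreement suite over analyte x phase x timepoint strata
#'
#' Computes Pearson correlation, OLP regression and Bland-Altman statistics
#' for each stratum of a long concentrations table, producing one row per
#' stratum ordered analyte (DC, TC, SB) x cycle phase (F, L) x timepoint
#' (pre, post). Per-stratum failures are caught and marked rather than
#' aborting the remaining rows.
#'
#' @param data Either a list of [paired_dataset()] objects, or a long data
#'   frame with columns `subject_id`, `cycle_phase`, `timepoint`, `analyte`,
#'   `plasma`, `saliva` (see [cohort_pairs()] for conversion from a
#'   quantified cohort).
#' @param alpha Two-sided significance level for all intervals.
#' @param bonferroni_family Family size for Bonferroni adjustment of the
#'   correlation p-values; `1` (default) leaves them unadjusted.
#' @param ci_method Passed to [olp_fit()].
#' @return A list of class `"agreement_suite"` with elements `table` (the
#'   per-stratum summary data frame: `analyte`, `phase`, `timepoint`, `n`,
#'   `r`, `p_r`, `p_r_adj`, `a`, `a_lo`, `a_hi`, `b`, `b_lo`, `b_hi`,
#'   `differential_bias`, `proportional_bias`, `ok`, `error`),
#'   `bland_altman` (the companion Bland-Altman data frame) and `fits`
#'   (per-stratum olp_fit/bland_altman objects).
#' @export
agreement_suite <- function(data, alpha = 0.05, bonferroni_family = 1,
                            ci_method = c("analytic", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  datasets <- if (is.data.frame(data)) split_paired(data) else data
  if (!length(datasets)) stop("no datasets supplied", call. = FALSE)
  datasets <- order_strata(datasets)
  rows <- vector("list", length(datasets))
  ba_rows <- vector("list", length(datasets))
  fits <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    ds <- datasets[[i]]
    lab <- list(analyte = ds$analyte, phase = ds$cycle_phase,
                timepoint = ds$timepoint)
    res <- tryCatch({
      pr <- pearson_r(ds)
      olp <- olp_fit(ds, alpha = alpha, ci_method = ci_method)
      ba <- bland_altman(ds, alpha = alpha)
      list(pr = pr, olp = olp, ba = ba, err = NA_character_)
    }, error = function(e) list(pr = NULL, olp = NULL, ba = NULL,
                                err = conditionMessage(e)))
    fits[[i]] <- res
    ok <- is.na(res$err)
    rows[[i]] <- data.frame(
      analyte = lab$analyte, phase = lab$phase, timepoint = lab$timepoint,
      n = ds$n,
      r = if (ok) res$pr$r else NA_real_,
      p_r = if (ok) res$pr$p else NA_real_,
      p_r_adj = NA_real_,
      a = if (ok) res$olp$a else NA_real_,
      a_lo = if (ok) res$olp$a_ci[1] else NA_real_,
      a_hi = if (ok) res$olp$a_ci[2] else NA_real_,
      b = if (ok) res$olp$b else NA_real_,
      b_lo = if (ok) res$olp$b_ci[1] else NA_real_,
      b_hi = if (ok) res$olp$b_ci[2] else NA_real_,
      differential_bias = if (ok) res$olp$differential_bias else NA,
      proportional_bias = if (ok) res$olp$proportional_bias else NA,
      ok = ok, error = res$err, stringsAsFactors = FALSE)
    ba_rows[[i]] <- if (ok) with(res$ba, data.frame(
      analyte = lab$analyte, phase = lab$phase, timepoint = lab$timepoint,
      n = n, mean_diff = mean_diff, sd_diff = sd_diff,
      loa_low = loa_low, loa_high = loa_high,
      md_lo = mean_diff_ci[1], md_hi = mean_diff_ci[2],
      loal_lo = loa_low_ci[1], loal_hi = loa_low_ci[2],
      loah_lo = loa_high_ci[1], loah_hi = loa_high_ci[2],
      prop_slope = prop_slope, prop_lo = prop_slope_ci[1],
      prop_hi = prop_slope_ci[2], prop_p = prop_p,
      differential_bias = differential_bias,
      proportional_bias = proportional_bias,
      outside_loa_count = outside_loa_count, stringsAsFactors = FALSE))
    else data.frame(analyte = lab$analyte, phase = lab$phase,
                    timepoint = lab$timepoint, n = ds$n,
                    mean_diff = NA_real_, sd_diff = NA_real_,
                    loa_low = NA_real_, loa_high = NA_real_,
                    md_lo = NA_real_, md_hi = NA_real_, loal_lo = NA_real_,
                    loal_hi = NA_real_, loah_lo = NA_real_,
                    loah_hi = NA_real_, prop_slope = NA_real_,
                    prop_lo = NA_real_, prop_hi = NA_real_, prop_p = NA_real_,
                    differential_bias = NA, proportional_bias = NA,
                    outside_loa_count = NA_integer_, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (bonferroni_family > 1)
    tab$p_r_adj <- bonferroni_adjust(tab$p_r, bonferroni_family)
  structure(list(table = tab, bland_altman = do.call(rbind, ba_rows),
                 fits = fits, alpha = alpha,
                 bonferroni_family = bonferroni_family),
            class = "agreement_suite")
}

split_paired <- function(df) {
  need <- c("analyte", "plasma", "saliva")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("long data frame is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"cycle_phase" %in% names(df)) df$cycle_phase <- NA_character_
  if (!"timepoint" %in% names(df)) df$timepoint <- NA_character_
  key <- interaction(df$analyte, df$cycle_phase, df$timepoint, drop = TRUE)
  lapply(split(df, key), function(s)
    paired_dataset(s$plasma, s$saliva,
                   subject_id = if ("subject_id" %in% names(s)) s$subject_id,
                   analyte = s$analyte[1], cycle_phase = s$cycle_phase[1],
                   timepoint = s$timepoint[1]))
}

order_strata <- function(datasets) {
  rank_of <- function(v, lev) {
    i <- match(as.character(v), lev)
    ifelse(is.na(i), length(lev) + 1L, i)
  }
  key <- vapply(datasets, function(d)
    rank_of(d$analyte, c("DC", "TC", "SB")) * 100 +
      rank_of(d$cycle_phase, c("F", "L")) * 10 +
      rank_of(d$timepoint, c("pre", "post")), numeric(1))
  datasets[order(key)]
}
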