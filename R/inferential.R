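# Within-group inference: Shapiro-Wilk normality gating, paired t-tests with
# the paired-design effect size d_z, Bonferroni adjustment, and power /
# minimum-detectable-effect computation for the paired t-test via the
# noncentral t distribution.

#' Shapiro-Wilk normality gate
#'
#' Wraps `stats::shapiro.test()` as a gate: intended to warn (not abort)
#' before paired t-tests and Bland-Altman analysis, whose interval
#' constructions assume normal differences.
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha Level below which normality is flagged as rejected.
#' @param warn Emit a warning when normality is rejected.
#' @return A list with `W`, `p`, `normal` (logical, `p >= alpha`), `n`.
#' @export
shapiro_gate <- function(values, alpha = 0.05, warn = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  n <- length(values)
  if (n < 3)
    stop("insufficient data: Shapiro-Wilk needs at least 3 values",
         call. = FALSE)
  if (n > 5000)
    stop("Shapiro-Wilk is defined for at most 5000 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("degenerate data: constant input has no distribution to test",
         call. = FALSE)
  sw <- stats::shapiro.test(values)
  normal <- sw$p.value >= alpha
  if (warn && !normal)
    warning(sprintf("normality rejected (Shapiro-Wilk W = %.3f, p = %.3g)",
                    sw$statistic, sw$p.value), call. = FALSE)
  list(W = unname(sw$statistic), p = sw$p.value, normal = normal, n = n)
}

#' Paired-sample t-test with effect size
#'
#' Two-sided paired t-test on differences `d = values_b - values_a`
#' (same subjects, same order): `t = mean(d) / (sd(d) / sqrt(n))` on
#' n - 1 degrees of freedom. The effect size is Cohen's
#' `d_z = mean(d) / sd(d)`, the paired-design standardised mean difference.
#'
#' @param values_a,values_b Numeric vectors of equal length (n >= 2);
#'   the difference is b - a (e.g. a = pre-exercise, b = post-exercise).
#' @param label Comparison label used in error messages and output.
#' @return An object of class `"ttest_result"`: list with `t`, `df`, `p`,
#'   `d` (Cohen's d_z), `mean_diff`, `sd_diff`, `n`, `label`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 3, 5))  # t = 4, df = 2, d_z = 2.31
#' @export
paired_t <- function(values_a, values_b, label = "") {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) != length(b))
    stop(sprintf("comparison %s: paired samples must have equal length",
                 label), call. = FALSE)
  if (length(a) < 2)
    stop(sprintf("comparison %s: at least 2 pairs required", label),
         call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop(sprintf("comparison %s: values must be finite", label),
         call. = FALSE)
  d <- b - a
  n <- length(d)
  sdd <- stats::sd(d)
  if (sdd == 0)
    stop(sprintf(
      "comparison %s: zero-variance differences (paired t undefined)",
      label), call. = FALSE)
  tval <- mean(d) / (sdd / sqrt(n))
  structure(list(t = tval, df = n - 1L,
                 p = 2 * stats::pt(-abs(tval), n - 1),
                 d = mean(d) / sdd, mean_diff = mean(d), sd_diff = sdd,
                 n = n, label = label),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("Paired t-test%s: t(%d) = %.3f, p = %.4g, d_z = %.3f, mean diff = %.4g\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$df, x$t, x$p, x$d, x$mean_diff))
  invisible(x)
}

#' Bonferroni adjustment with an explicit family size
#'
#' Multiplies each p-value by the family size and caps at 1. The family is
#' explicit (it may exceed the number of p-values passed, e.g. when rows of
#' a larger table are adjusted in pieces).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param family Integer family size, >= 1; `1` is the identity.
#' @return Adjusted p-values, same length as `p`.
#' @examples
#' bonferroni_adjust(c(0.01, 0.04), family = 3)  # 0.03, 0.12
#' @export
bonferroni_adjust <- function(p, family) {
  if (length(family) != 1 || !is.finite(family) || family < 1)
    stop("family must be a single integer >= 1", call. = FALSE)
  p <- as.numeric(p)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(p * family, 1)
}

#' Power of a paired t-test via the noncentral t distribution
#'
#' For a true standardised effect `d` (Cohen's d_z) with `n` pairs, the test
#' statistic follows a noncentral t distribution with `n - 1` degrees of
#' freedom and noncentrality `d * sqrt(n)`. Two-sided power is
#' `P(|T'| > t_{n-1, 1-alpha/2})`; one-sided power uses the upper critical
#' value only.
#'
#' @param d True effect size (Cohen's d_z).
#' @param n Number of pairs (>= 2).
#' @param alpha Significance level.
#' @param sides `"two"` (default) or `"one"`.
#' @return Power, a probability in `[0, 1]`.
#' @examples
#' power_paired_t(d = 0.89, n = 12)  # about 0.80
#' @export
power_paired_t <- function(d, n, alpha = 0.05, sides = c("two", "one")) {
  sides <- match.arg(sides)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (sides == "two") {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}

#' Minimum detectable effect size for a paired t-test
#'
#' Smallest Cohen's d_z at which a paired t-test with `n` pairs at level
#' `alpha` reaches the requested power, obtained by bisection on
#' d in (0, 10] against [power_paired_t()] to within `tol` in power.
#'
#' @param n Number of pairs (>= 2).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (alpha, 1).
#' @param sides `"two"` (default) or `"one"`.
#' @param tol Bisection tolerance on power.
#' @return The required Cohen's d_z.
#' @examples
#' required_effect_size(n = 12, alpha = 0.05, power = 0.80)  # about 0.89
#' @export
required_effect_size <- function(n, alpha = 0.05, power = 0.80,
                                 sides = c("two", "one"), tol = 1e-6) {
  sides <- match.arg(sides)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (power <= alpha || power >= 1)
    stop("power must lie in (alpha, 1): a test already rejects at rate ",
         "alpha under d = 0", call. = FALSE)
  lo <- 0; hi <- 10
  if (power_paired_t(hi, n, alpha, sides) < power)
    stop("no solution: requested power unattainable for d <= 10 at this n",
         call. = FALSE)
  # power is strictly increasing in d, so plain bisection converges
  while (TRUE) {
    mid <- (lo + hi) / 2
    pw <- power_paired_t(mid, n, alpha, sides)
    if (abs(pw - power) < tol || (hi - lo) < 1e-12) return(mid)
    if (pw < power) lo <- mid else hi <- mid
  }
}

#' Paired pre/post t-tests across analyte x phase strata
#'
#' Runs one paired t-test (post vs pre) per fluid x analyte x cycle-phase
#' stratum of a long concentrations table, with a Shapiro-Wilk gate on the
#' differences and optional Bonferroni adjustment.
#'
#' @param conc Long data frame with columns `subject_id`, `fluid`,
#'   `cycle_phase`, `timepoint` (`"pre"`/`"post"`), `analyte`, `value`.
#' @param bonferroni_family Family size for p-value adjustment (1 = none).
#' @return Data frame with one row per stratum: `fluid`, `analyte`,
#'   `cycle_phase`, `n`, `t`, `df`, `p`, `p_adjusted`, `d`, `mean_diff`,
#'   `normal_diffs`, `shapiro_p`.
#' @export
paired_t_table <- function(conc, bonferroni_family = 1) {
  need <- c("subject_id", "fluid", "cycle_phase", "timepoint", "analyte",
            "value")
  miss <- setdiff(need, names(conc))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  key <- interaction(conc$fluid, conc$analyte, conc$cycle_phase, drop = TRUE)
  rows <- lapply(split(conc, key), function(s) {
    pre <- s[s$timepoint == "pre", ]
    post <- s[s$timepoint == "post", ]
    lab <- sprintf("%s %s (%s)", s$fluid[1], s$analyte[1], s$cycle_phase[1])
    if (!nrow(pre) || !nrow(post)) return(NULL)  # partial stratum: skip
    ord <- match(pre$subject_id, post$subject_id)
    if (any(is.na(ord)))
      stop(sprintf("comparison %s: unmatched subjects between pre and post",
                   lab), call. = FALSE)
    tt <- paired_t(pre$value, post$value[ord], label = lab)
    sw <- tryCatch(shapiro_gate(post$value[ord] - pre$value),
                   error = function(e) list(p = NA_real_, normal = NA))
    data.frame(fluid = s$fluid[1], analyte = s$analyte[1],
               cycle_phase = s$cycle_phase[1], n = tt$n, t = tt$t,
               df = tt$df, p = tt$p, p_adjusted = NA_real_, d = tt$d,
               mean_diff = tt$mean_diff, normal_diffs = sw$normal,
               shapiro_p = sw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out))
    stop("no complete pre/post strata found", call. = FALSE)
  rownames(out) <- NULL
  if (bonferroni_family > 1)
    out$p_adjusted <- bonferroni_adjust(out$p, bonferroni_family)
  out
}
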