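test_that("Pearson correlation matches the product-moment oracle", {
  d <- paired_dataset(1:5, 2 * (1:5) + 1)
  pr <- pearson_r(d)
  expect_equal(pr$r, 1)
  expect_lt(pr$p, 1e-10)
  expect_equal(pearson_r(paired_dataset(1:5, -(1:5)))$r, -1)
  pr2 <- pearson_r(five_pairs())
  expect_equal(pr2$r, 0.995236, tolerance = 1e-6)
  # p from t = r sqrt((n-2)/(1-r^2)) on n-2 df
  tstat <- pr2$r * sqrt(3 / (1 - pr2$r^2))
  expect_equal(pr2$p, 2 * pt(-tstat, 3))
  expect_error(pearson_r(paired_dataset(1:5, rep(2, 5))), "zero variance")
})

test_that("OLS line of saliva on plasma matches the normal equations", {
  d <- paired_dataset(1:5, 1:5)
  f <- suppressWarnings(ols_fit(d))  # perfect fit: summary.lm warns
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  f2 <- suppressWarnings(ols_fit(paired_dataset(1:5, rep(3, 5))))
  expect_equal(f2$slope, 0)
  expect_equal(f2$intercept, 3)
  f3 <- ols_fit(five_pairs())
  expect_equal(f3$slope, 0.93, tolerance = 1e-10)
  expect_equal(f3$intercept, 0.25, tolerance = 1e-10)
  expect_error(ols_fit(paired_dataset(rep(1, 4), 1:4)), "zero variance")
})

test_that("OLP slope is the signed SD ratio with coherent intervals and flags", {
  f <- olp_fit(paired_dataset(1:5, 1:5))
  expect_equal(f$b, 1)
  expect_equal(f$a, 0)
  expect_false(f$differential_bias)
  expect_false(f$proportional_bias)

  f2 <- olp_fit(paired_dataset(c(1, 2, 3), c(2, 4, 6)))
  expect_equal(f2$b, 2)
  expect_equal(f2$a, 0, tolerance = 1e-12)

  f3 <- olp_fit(five_pairs())
  expect_equal(f3$b, 0.9344517, tolerance = 1e-6)
  expect_equal(f3$a, 0.2366449, tolerance = 1e-6)
  expect_true(f3$b_ci[1] <= f3$b && f3$b <= f3$b_ci[2])
  expect_true(f3$a_ci[1] <= f3$a && f3$a <= f3$a_ci[2])

  expect_error(olp_fit(paired_dataset(1:4, c(1, 2, 2, 1))),
               "undefined slope sign")
})

test_that("OLP satisfies its defining identities on random datasets", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    d <- rho_pairs(n, runif(1, -0.95, 0.95), mu = runif(1, -2, 5),
                   sd = runif(1, 0.2, 3))
    r <- cor(d$plasma, d$saliva)
    if (abs(r) < 1e-6) next
    olp <- olp_fit(d)
    ols <- ols_fit(d)
    # |b_OLP| = |b_OLS| / |r| and hence |b_OLP| >= |b_OLS|
    expect_equal(abs(olp$b), abs(ols$slope) / abs(r), tolerance = 1e-10)
    expect_gte(abs(olp$b) + 1e-15, abs(ols$slope))
    # symmetry: reversing the roles gives the reciprocal slope
    rev <- olp_fit(paired_dataset(d$saliva, d$plasma))
    expect_equal(rev$b, 1 / olp$b, tolerance = 1e-10)
    # translation equivariance: shifting both members leaves the slope alone
    sh <- olp_fit(paired_dataset(d$plasma + 3.7, d$saliva + 3.7))
    expect_equal(sh$b, olp$b, tolerance = 1e-9)
  }
})

test_that("analytic OLP slope CI agrees with a percentile bootstrap at n = 12", {
  set.seed(23)
  d <- rho_pairs(12, 0.85)
  fa <- olp_fit(d, ci_method = "analytic")
  fb <- olp_fit(d, ci_method = "bootstrap", boot_reps = 4000)
  width_a <- diff(fa$b_ci)
  width_b <- diff(fb$b_ci)
  expect_lt(abs(width_a - width_b) / width_a, 0.25)
  expect_lt(abs(mean(fa$b_ci) - mean(fb$b_ci)), 0.3 * width_a)
})

test_that("Bland-Altman summaries match hand computation", {
  diffs <- c(0.1, -0.2, 0.0, 0.3, -0.1)
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(paired_dataset(x, x + diffs))
  expect_equal(ba$mean_diff, 0.02)
  expect_equal(ba$sd_diff, sd(diffs))
  expect_equal(ba$sd_diff, 0.1923538, tolerance = 1e-6)
  expect_equal(ba$loa_low, -0.3570135, tolerance = 1e-6)
  expect_equal(ba$loa_high, 0.3970135, tolerance = 1e-6)
  expect_equal(ba$loa_low, ba$mean_diff - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high, ba$mean_diff + 1.96 * ba$sd_diff)
  # mean-difference CI: t on n-1 df
  expect_equal(ba$mean_diff_ci,
               0.02 + c(-1, 1) * qt(0.975, 4) * sd(diffs) / sqrt(5))
  # LoA CI half-width formula
  half <- qt(0.975, 4) * sd(diffs) * sqrt(1 / 5 + 1.96^2 / (2 * 4))
  expect_equal(ba$loa_low_ci, ba$loa_low + c(-1, 1) * half)
  expect_equal(ba$outside_loa_count, 0)
})

test_that("degenerate and constant-offset differences are handled explicitly", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- suppressWarnings(bland_altman(paired_dataset(x, x)))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_true(ba0$degenerate)
  expect_false(ba0$differential_bias)
  expect_false(ba0$proportional_bias)
  expect_equal(ba0$outside_loa_count, 0)

  expect_warning(ba5 <- bland_altman(paired_dataset(x, x + 5)), "collapse")
  expect_equal(ba5$mean_diff, 5)
  expect_true(ba5$differential_bias)   # point CI excludes 0
  expect_false(ba5$proportional_bias)
})

test_that("translation equivariance holds for the difference analysis", {
  set.seed(5)
  d <- rho_pairs(15, 0.8)
  ba <- bland_altman(d)
  sh <- bland_altman(paired_dataset(d$plasma + 10, d$saliva + 10))
  expect_equal(sh$mean_diff, ba$mean_diff, tolerance = 1e-10)
  expect_equal(sh$sd_diff, ba$sd_diff, tolerance = 1e-10)
  expect_equal(diff(c(sh$loa_low, sh$loa_high)),
               diff(c(ba$loa_low, ba$loa_high)), tolerance = 1e-10)
})

test_that("injected differential bias is detected at the noncentral-t rate", {
  # bias of 3 sd/sqrt(n) gives noncentrality 3; the flag is the one-sample
  # t-test on the differences, so its power is the noncentral-t value
  n <- 12
  analytic <- power_paired_t(3 / sqrt(n), n)
  set.seed(31)
  hits <- mean(replicate(600, {
    x <- rnorm(n, 10, 1)
    d <- rnorm(n, 0, 0.5)
    bias <- 3 * 0.5 / sqrt(n)
    bland_altman(paired_dataset(x, x + d + bias))$differential_bias
  }))
  expect_gt(hits, 0.70)
  expect_lt(abs(hits - analytic), 0.05)
})

test_that("agreement_suite orders strata, flags failures and adjusts p-values", {
  set.seed(55)
  x <- c(1, 2, 3, 4, 5, 6)
  grid <- expand.grid(analyte = c("TC", "DC", "SB"),
                      cycle_phase = c("L", "F"),
                      timepoint = c("post", "pre"),
                      stringsAsFactors = FALSE)
  long <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    data.frame(subject_id = seq_along(x), analyte = grid$analyte[i],
               cycle_phase = grid$cycle_phase[i],
               timepoint = grid$timepoint[i],
               plasma = x, saliva = x + rnorm(6, 0, 0.3))))
  suite <- agreement_suite(long, bonferroni_family = 3)
  expect_equal(nrow(suite$table), 12)
  expect_equal(suite$table$analyte,
               rep(c("DC", "TC", "SB"), each = 4))
  expect_equal(suite$table$phase, rep(rep(c("F", "L"), each = 2), 3))
  expect_equal(suite$table$timepoint, rep(c("pre", "post"), 6))
  expect_true(all(suite$table$ok))
  expect_equal(suite$table$p_r_adj, pmin(suite$table$p_r * 3, 1))
  expect_equal(names(suite$bland_altman)[1:8],
               c("analyte", "phase", "timepoint", "n", "mean_diff",
                 "sd_diff", "loa_low", "loa_high"))

  # a degenerate stratum is marked, not fatal
  long2 <- long
  long2$saliva[long2$analyte == "DC" & long2$cycle_phase == "F" &
                 long2$timepoint == "pre"] <- 2
  suite2 <- agreement_suite(long2)
  bad <- suite2$table$analyte == "DC" & suite2$table$phase == "F" &
    suite2$table$timepoint == "pre"
  expect_false(suite2$table$ok[bad])
  expect_true(all(suite2$table$ok[!bad]))
  expect_error(agreement_suite(list()), "no datasets")
})

test_that("exact-equality cohorts give identity fits with no bias flags", {
  x <- seq(0.2, 1.4, length.out = 8)
  long <- do.call(rbind, lapply(c("DC", "TC", "SB"), function(a)
    data.frame(subject_id = 1:8, analyte = a, cycle_phase = "F",
               timepoint = "pre", plasma = x, saliva = x)))
  suite <- suppressWarnings(agreement_suite(long))
  expect_equal(suite$table$b, rep(1, 3))
  expect_equal(suite$table$a, rep(0, 3), tolerance = 1e-12)
  expect_false(any(suite$table$differential_bias))
  expect_false(any(suite$table$proportional_bias))
})
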