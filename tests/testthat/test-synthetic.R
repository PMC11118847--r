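test_that("config validation lists offending fields and requires a seed", {
  expect_error(simulation_config(n_subjects = 12), "seed is mandatory")
  expect_error(simulation_config(n_subjects = 2, seed = 1), "n_subjects")
  expect_error(
    simulation_config(seed = 1, analytes = list(DC = list(mu = 1, sd = -1,
                                                          rho = 0.5))),
    "sd must be > 0")
  expect_error(
    simulation_config(seed = 1, analytes = list(DC = list(mu = 1, sd = 1,
                                                          rho = 1))),
    "rho")
  expect_error(simulation_config(seed = 1, icc = 1), "icc")
})

test_that("the generator is deterministic and leaves the global RNG intact", {
  cfg <- simulation_config(seed = 99)
  set.seed(1); before <- .Random.seed
  c1 <- generate_cohort(cfg)
  expect_identical(.Random.seed, before)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 12 * 2 * 2 * 3)  # subjects x phases x times x analytes
  expect_true(all(c1$plasma > 0 & c1$saliva > 0))
})

test_that("near-degenerate correlation and stratum means are recovered", {
  cfg <- simulation_config(
    n_subjects = 1000, seed = 5,
    analytes = list(DC = list(mu = 0.45, sd = 0.12, rho = 0.999)))
  co <- generate_cohort(cfg)
  for (s in split(co, interaction(co$cycle_phase, co$timepoint)))
    expect_gt(cor(s$plasma, s$saliva), 0.99)
  # exercise and phase effects move the stratum means in the right direction
  mu <- tapply(co$plasma, interaction(co$cycle_phase, co$timepoint), mean)
  expect_gt(mu[["F.post"]], mu[["F.pre"]])
  expect_gt(mu[["L.pre"]], mu[["F.pre"]])
})

test_that("sample correlation at n = 12 is centred on the target rho", {
  # Fisher-z: median of sample r over replicates should sit near rho
  cfg <- simulation_config(
    n_subjects = 12, seed = 17,
    analytes = list(DC = list(mu = 0.45, sd = 0.12, rho = 0.9)))
  rs <- vapply(1:400, function(i) {
    co <- generate_cohort(simulation_config(
      n_subjects = 12, seed = 1000 + i,
      analytes = list(DC = list(mu = 0.45, sd = 0.12, rho = 0.9))))
    s <- co[co$cycle_phase == "F" & co$timepoint == "pre", ]
    cor(s$plasma, s$saliva)
  }, numeric(1))
  expect_lt(abs(median(rs) - 0.9), 0.03)
})

test_that("bias injection transforms saliva only and scales the OLP slope", {
  cfg <- simulation_config(n_subjects = 8, seed = 3)
  co <- generate_cohort(cfg)
  expect_identical(inject_bias(co, 0, 1), co)
  shifted <- inject_bias(co, differential = 5)
  expect_equal(shifted$saliva, co$saliva + 5)
  expect_equal(shifted$plasma, co$plasma)

  # constant shift on exact-equality pairs shows up as the mean difference
  eq <- data.frame(subject_id = 1:6, cycle_phase = "F", timepoint = "pre",
                   analyte = "DC", plasma = 1:6, saliva = 1:6)
  ba <- suppressWarnings(
    bland_altman(paired_dataset(eq$plasma,
                                inject_bias(eq, differential = 5)$saliva)))
  expect_equal(ba$mean_diff, 5)

  # proportional scaling of y multiplies the OLP slope
  big <- generate_cohort(simulation_config(
    n_subjects = 200, seed = 8,
    analytes = list(DC = list(mu = 10, sd = 1, rho = 0.99))))
  s <- big[big$cycle_phase == "F" & big$timepoint == "pre", ]
  b0 <- olp_fit(paired_dataset(s$plasma, s$saliva))$b
  s2 <- inject_bias(s, proportional = 1.5)
  b1 <- olp_fit(paired_dataset(s2$plasma, s2$saliva))$b
  expect_equal(b1, 1.5 * b0, tolerance = 1e-10)
})

test_that("per-analyte bias vectors are honoured", {
  co <- generate_cohort(simulation_config(n_subjects = 5, seed = 21))
  out <- inject_bias(co, differential = c(DC = 1, TC = 0, SB = 10))
  expect_equal(out$saliva[out$analyte == "DC"],
               co$saliva[co$analyte == "DC"] + 1)
  expect_equal(out$saliva[out$analyte == "TC"],
               co$saliva[co$analyte == "TC"])
  expect_equal(out$saliva[out$analyte == "SB"],
               co$saliva[co$analyte == "SB"] + 10)
})

test_that("OD back-generation inverts the quantification exactly", {
  # identity-ratio case: dc 0.28 with split 0.5 and unit od220 gives od232 = 1
  one <- data.frame(subject_id = "S1", cycle_phase = "F", timepoint = "pre",
                    analyte = c("DC", "TC", "SB"), plasma = c(0.28, 0.32, 104),
                    saliva = c(0.28, 0.32, 104))
  od <- cohort_to_od(one, od220_up = 1, od220_lp = 1, split = 0.5, cap = 60)
  expect_equal(od$od232_up, rep(1, 2))
  expect_equal(od$od232_lp, rep(1, 2))

  zero <- one; zero$plasma[1] <- 0; zero$saliva[1] <- 0
  odz <- cohort_to_od(zero, cap = 60)
  expect_equal(odz$od232_up, rep(0, 2))

  co <- generate_cohort(simulation_config(n_subjects = 12, seed = 13))
  od2 <- cohort_to_od(co, od220_up = 0.3, od220_lp = 0.3, split = 0.4)
  conc <- quantify_od_table(od2)
  pairs <- cohort_pairs(conc)
  m <- merge(as.data.frame(co), pairs,
             by = c("subject_id", "cycle_phase", "timepoint", "analyte"))
  expect_equal(nrow(m), nrow(co))
  expect_lt(max(abs(m$plasma.x - m$plasma.y)), 1e-10)
  expect_lt(max(abs(m$saliva.x - m$saliva.y)), 1e-10)
})

test_that("infeasible absorbances and bad splits are rejected", {
  one <- data.frame(subject_id = "S1", cycle_phase = "F", timepoint = "pre",
                    analyte = c("DC", "TC", "SB"), plasma = c(10, 0.3, 200),
                    saliva = c(10, 0.3, 200))
  expect_error(cohort_to_od(one), "infeasible OD")
  expect_error(cohort_to_od(one, split = 0), "split")
  two <- one[1:2, ]  # missing SB
  expect_error(cohort_to_od(two, cap = 60), "all three analytes")
})
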