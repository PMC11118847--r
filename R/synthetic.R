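# Synthetic cohorts with the statistical structure the agreement analysis
# assumes: correlated saliva/plasma pairs per analyte, a crossed cycle-phase
# (F/L) x timepoint (pre/post) repeated design with a subject random
# intercept, and optional injected differential/proportional bias. Also the
# right-inverse of the quantification equations, so the full OD -> agreement
# pipeline can be exercised without external data.

default_analyte_params <- function() {
  # Relative-unit scales; synthetic order-of-magnitude choices, not measured
  # study values. Correlations sit inside the 0.77-0.97 range typical of
  # saliva/plasma LPO agreement data.
  list(
    DC = list(mu = 0.45, sd = 0.12, rho = 0.80),
    TC = list(mu = 0.35, sd = 0.09, rho = 0.85),
    SB = list(mu = 250,  sd = 60,   rho = 0.90))
}

#' Configure a synthetic saliva/plasma cohort
#'
#' Full parameterisation of the generator. Each analyte block holds the
#' plasma mean for the pre-exercise follicular stratum (`mu`), the
#' between-subject SD (`sd`), and the within-stratum saliva/plasma
#' correlation (`rho`). Effects are standardised shifts (in units of `sd`):
#' `exercise_effect_d` moves post above pre, `phase_effect_d` moves the
#' luteal phase above the follicular. Bias knobs act on saliva only:
#' `saliva = differential_bias + proportional_bias * saliva`.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param seed Mandatory integer seed; the generator never falls back to
#'   clock seeding.
#' @param analytes Named list of per-analyte blocks (`mu`, `sd`, `rho`);
#'   defaults cover DC, TC, SB.
#' @param exercise_effect_d Standardised post-minus-pre shift (Cohen's d
#'   scale, applied within subject).
#' @param phase_effect_d Standardised luteal-minus-follicular shift.
#' @param icc Intraclass correlation of repeated measures within a subject
#'   (additive subject random intercept), in `[0, 1)`.
#' @param differential_bias Constant offset added to saliva (analyte units;
#'   scalar, or named per analyte).
#' @param proportional_bias Multiplicative slope applied to saliva (scalar
#'   or named per analyte).
#' @param lognormal Generate on the log scale (exp-transformed Gaussian)
#'   instead of Gaussian marginals; for robustness testing only.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_subjects = 12, seed,
                              analytes = default_analyte_params(),
                              exercise_effect_d = 1.5,
                              phase_effect_d = 0.5,
                              icc = 0.5,
                              differential_bias = 0,
                              proportional_bias = 1,
                              lognormal = FALSE) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory (no silent clock seeding)", call. = FALSE)
  problems <- character()
  if (!is.numeric(n_subjects) || n_subjects < 3)
    problems <- c(problems, "n_subjects must be >= 3")
  if (!is.list(analytes) || is.null(names(analytes)) ||
      !all(nzchar(names(analytes))))
    problems <- c(problems, "analytes must be a named list")
  else for (nm in names(analytes)) {
    blk <- analytes[[nm]]
    if (!all(c("mu", "sd", "rho") %in% names(blk)))
      problems <- c(problems,
                    sprintf("analyte %s: needs mu, sd, rho", nm))
    else {
      if (blk$sd <= 0) problems <- c(problems, sprintf("analyte %s: sd must be > 0", nm))
      if (abs(blk$rho) >= 1) problems <- c(problems, sprintf("analyte %s: |rho| must be < 1", nm))
    }
  }
  if (icc < 0 || icc >= 1) problems <- c(problems, "icc must be in [0, 1)")
  if (length(problems))
    stop("invalid simulation config: ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 analytes = analytes, exercise_effect_d = exercise_effect_d,
                 phase_effect_d = phase_effect_d, icc = icc,
                 differential_bias = differential_bias,
                 proportional_bias = proportional_bias,
                 lognormal = lognormal),
            class = "simulation_config")
}

per_analyte <- function(x, analyte) {
  if (length(x) == 1 && is.null(names(x))) return(unname(x))
  if (!is.null(names(x)) && analyte %in% names(x)) return(unname(x[[analyte]]))
  unname(x[[1]])
}

#' Generate a synthetic cohort
#'
#' Per subject, stratum (cycle phase x timepoint) and analyte, the plasma
#' value is drawn as `mu_stratum + u_subject + e` where `u_subject` is a
#' shared random intercept (variance `icc * sd^2`) and `e` is stratum noise
#' (variance `(1 - icc) * sd^2`). The saliva value follows the conditional
#' law at correlation rho with equal marginal SD,
#' `mu_stratum + rho * (plasma - mu_stratum) + eps`,
#' `eps ~ N(0, sd * sqrt(1 - rho^2))`, so in the bias-free default the true
#' agreement line is identity (OLP slope 1, intercept 0) with correlation
#' rho. Bias knobs then transform saliva only. Negative draws are rejected
#' and redrawn (count recorded in the `redraws` attribute), preserving
#' distributional shape near the positive bulk.
#'
#' @param config A [simulation_config()]. The seed is applied internally;
#'   the same config always yields the identical cohort.
#' @return A data frame of class `"synthetic_cohort"` with columns
#'   `subject_id`, `cycle_phase` (`F`/`L`), `timepoint` (`pre`/`post`),
#'   `analyte`, `plasma`, `saliva`; attributes `config` and `redraws`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop("config must come from simulation_config()", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_subjects
  strata <- expand.grid(cycle_phase = c("F", "L"),
                        timepoint = c("pre", "post"),
                        stringsAsFactors = FALSE)
  redraws <- 0L
  rows <- list()
  for (an in names(config$analytes)) {
    blk <- config$analytes[[an]]
    sd_u <- blk$sd * sqrt(config$icc)
    sd_e <- blk$sd * sqrt(1 - config$icc)
    sd_eps <- blk$sd * sqrt(1 - blk$rho^2)
    u <- stats::rnorm(n, 0, sd_u)
    for (k in seq_len(nrow(strata))) {
      mu_k <- blk$mu +
        (strata$cycle_phase[k] == "L") * config$phase_effect_d * blk$sd +
        (strata$timepoint[k] == "post") * config$exercise_effect_d * blk$sd
      plasma <- saliva <- numeric(n)
      for (i in seq_len(n)) {
        repeat {
          p <- mu_k + u[i] + stats::rnorm(1, 0, sd_e)
          s <- mu_k + blk$rho * (p - mu_k) + stats::rnorm(1, 0, sd_eps)
          if (config$lognormal) { p <- exp(p / blk$mu); s <- exp(s / blk$mu) }
          s <- per_analyte(config$differential_bias, an) +
            per_analyte(config$proportional_bias, an) * s
          if (p > 0 && s > 0) break
          redraws <- redraws + 1L
        }
        plasma[i] <- p; saliva[i] <- s
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("S%02d", seq_len(n)),
        cycle_phase = strata$cycle_phase[k],
        timepoint = strata$timepoint[k],
        analyte = an, plasma = plasma, saliva = saliva,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  attr(out, "redraws") <- redraws
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}

#' Inject differential and/or proportional bias into a cohort
#'
#' Transforms the saliva member of every pair:
#' `saliva' = differential + proportional * saliva`; plasma is untouched.
#' Positive control for the bias-detection rules of [olp_fit()] and
#' [bland_altman()].
#'
#' @param cohort A cohort data frame with `plasma` and `saliva` columns.
#' @param differential Constant offset (analyte units; scalar or named per
#'   analyte).
#' @param proportional Slope multiplier (scalar or named per analyte).
#' @return The cohort with transformed saliva values.
#' @export
inject_bias <- function(cohort, differential = 0, proportional = 1) {
  if (!all(c("plasma", "saliva") %in% names(cohort)))
    stop("cohort must have plasma and saliva columns", call. = FALSE)
  ans <- if ("analyte" %in% names(cohort)) cohort$analyte
         else rep("all", nrow(cohort))
  d <- vapply(ans, function(a) per_analyte(differential, a), numeric(1))
  p <- vapply(ans, function(a) per_analyte(proportional, a), numeric(1))
  cohort$saliva <- d + p * cohort$saliva
  cohort
}

#' Back-generate an optical-density table from a cohort
#'
#' Right-inverse of the quantification equations: for each specimen
#' (subject x fluid x cycle phase x timepoint) the target DC/TC/SB
#' concentrations are converted to absorbances such that
#' [quantify_od_table()] recovers them exactly. Both od220 values are
#' fixed, each analyte's total ratio-sum `conc / coefficient` is split into
#' upper/lower parts by `split`, and the numerator absorbances follow.
#'
#' @param cohort Long cohort data frame (columns `subject_id`,
#'   `cycle_phase`, `timepoint`, `analyte`, `plasma`, `saliva`) containing
#'   all three analytes DC, TC, SB for every specimen.
#' @param od220_up,od220_lp Fixed 220 nm absorbances per phase.
#' @param split Fraction of each ratio-sum assigned to the upper phase,
#'   in (0, 1).
#' @param cap Maximum physically plausible absorbance; implied values above
#'   it raise an infeasible-OD error.
#' @param coefficients Correction coefficients used for the inversion.
#' @return Data frame in the OD schema of [quantify_od_table()].
#' @export
cohort_to_od <- function(cohort, od220_up = 1.0, od220_lp = 1.0, split = 0.5,
                         cap = 3.0, coefficients = lpo_coefficients) {
  if (split <= 0 || split >= 1) stop("split must be in (0, 1)", call. = FALSE)
  need <- c("subject_id", "cycle_phase", "timepoint", "analyte", "plasma",
            "saliva")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  long <- rbind(
    data.frame(cohort[c("subject_id", "cycle_phase", "timepoint", "analyte")],
               fluid = "plasma", value = cohort$plasma,
               stringsAsFactors = FALSE),
    data.frame(cohort[c("subject_id", "cycle_phase", "timepoint", "analyte")],
               fluid = "saliva", value = cohort$saliva,
               stringsAsFactors = FALSE))
  if (any(long$value < 0))
    stop("target concentrations must be >= 0", call. = FALSE)
  key <- interaction(long$subject_id, long$fluid, long$cycle_phase,
                     long$timepoint, drop = TRUE)
  rows <- lapply(split(long, key), function(s) {
    conc <- stats::setNames(s$value, s$analyte)
    if (!all(c("DC", "TC", "SB") %in% names(conc)))
      stop("specimen ", s$subject_id[1], "/", s$fluid[1],
           ": needs all three analytes DC, TC, SB", call. = FALSE)
    ratio <- conc[c("DC", "TC", "SB")] / coefficients[c("DC", "TC", "SB")]
    up <- ratio * split * od220_up
    lp <- ratio * (1 - split) * od220_lp
    if (any(c(up, lp, od220_up, od220_lp) > cap))
      stop(sprintf(
        "infeasible OD for specimen %s/%s: implied absorbance exceeds cap %.2f",
        s$subject_id[1], s$fluid[1], cap), call. = FALSE)
    data.frame(
      specimen_id = paste(s$subject_id[1], s$fluid[1], s$cycle_phase[1],
                          s$timepoint[1], sep = "_"),
      subject_id = s$subject_id[1], fluid = s$fluid[1],
      cycle_phase = s$cycle_phase[1], timepoint = s$timepoint[1],
      od220_up = od220_up, od232_up = unname(up["DC"]),
      od278_up = unname(up["TC"]), od400_up = unname(up["SB"]),
      od220_lp = od220_lp, od232_lp = unname(lp["DC"]),
      od278_lp = unname(lp["TC"]), od400_lp = unname(lp["SB"]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$specimen_id), , drop = FALSE]
}

#' Reshape a long per-fluid concentrations table to saliva/plasma pairs
#'
#' Converts the quantification output (one row per specimen, fluids stacked)
#' or a synthetic cohort into the wide paired layout consumed by
#' [agreement_suite()].
#'
#' @param conc Data frame with `subject_id`, `cycle_phase`, `timepoint`,
#'   and either (`fluid` + analyte value columns `dc`/`tc`/`sb`) or already
#'   (`analyte`, `plasma`, `saliva`).
#' @return Data frame with columns `subject_id`, `cycle_phase`, `timepoint`,
#'   `analyte`, `plasma`, `saliva`.
#' @export
cohort_pairs <- function(conc) {
  if (all(c("plasma", "saliva", "analyte") %in% names(conc)))
    return(conc[c("subject_id", "cycle_phase", "timepoint", "analyte",
                  "plasma", "saliva")])
  need <- c("subject_id", "fluid", "cycle_phase", "timepoint", "dc", "tc",
            "sb")
  miss <- setdiff(need, names(conc))
  if (length(miss))
    stop("concentrations table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  long <- stats::reshape(
    conc[c("subject_id", "fluid", "cycle_phase", "timepoint", "dc", "tc",
           "sb")],
    direction = "long", varying = c("dc", "tc", "sb"), v.names = "value",
    timevar = "analyte", times = c("DC", "TC", "SB"))
  key <- c("subject_id", "cycle_phase", "timepoint", "analyte")
  pl <- long[long$fluid == "plasma", c(key, "value")]
  sa <- long[long$fluid == "saliva", c(key, "value")]
  names(pl)[5] <- "plasma"; names(sa)[5] <- "saliva"
  out <- merge(pl, sa, by = key)
  if (nrow(out) < nrow(pl) || nrow(out) < nrow(sa))
    warning("unpaired specimens dropped (missing saliva or plasma member)",
            call. = FALSE)
  rownames(out) <- NULL
  out
}
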