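# Spectrophotometric quantification of lipid-peroxidation products from
# two-phase (heptane upper / isopropanol lower) lipid-extract absorbances.
#
#   DC = (OD232up/OD220up + OD232lp/OD220lp) * 0.14
#   TC = (OD278up/OD220up + OD278lp/OD220lp) * 0.16
#   SB = (OD400up/OD220up + OD400lp/OD220lp) * 52
#
# OD220 (isolated double bonds) normalises each phase, so results are
# invariant to rescaling all four absorbances of one phase.

#' Default correction coefficients for DC, TC and SB
#'
#' Dimensionless correction coefficients applied to the sum of the upper- and
#' lower-phase absorbance ratios for each analyte. Treated as fixed assay
#' constants; overridable via the `coefficients` argument of the
#' quantification functions.
#'
#' @format Named numeric vector with elements `DC`, `TC`, `SB`.
#' @export
lpo_coefficients <- c(DC = 0.14, TC = 0.16, SB = 52)

#' Construct absorbance readings for one phase of a lipid extract
#'
#' Bundles the four optical densities (absorbances) measured on one phase
#' (heptane upper or isopropanol lower) of a two-phase lipid extract:
#' 220 nm (isolated double bonds, the normalising denominator), 232 nm
#' (diene conjugates), 278 nm (triene conjugates) and 400 nm (Schiff bases).
#' All arguments are recycled to a common length, so a whole batch can be
#' represented by one object.
#'
#' @param od220,od232,od278,od400 Numeric vectors of net absorbances
#'   (blank-subtracted, dimensionless). `od220` must be strictly positive;
#'   the others non-negative and finite.
#' @param phase Label used in error messages, e.g. `"upper"` or `"lower"`.
#' @param clamp_negative If `TRUE`, small negative absorbances (possible
#'   after blank subtraction) are clamped to 0 with a warning instead of
#'   raising an error.
#' @return A list of class `"phase_od"` with components `od220`, `od232`,
#'   `od278`, `od400`.
#' @examples
#' phase_od(od220 = 0.8, od232 = 0.2, od278 = 0.4, od400 = 0.04)
#' @export
phase_od <- function(od220, od232, od278, od400, phase = "phase",
                     clamp_negative = FALSE) {
  vals <- list(od220 = as.numeric(od220), od232 = as.numeric(od232),
               od278 = as.numeric(od278), od400 = as.numeric(od400))
  n <- max(lengths(vals))
  vals <- lapply(vals, rep_len, length.out = n)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (any(!is.finite(v)))
      stop(sprintf("non-finite %s absorbance in %s phase", nm, phase),
           call. = FALSE)
    if (any(v < 0)) {
      if (clamp_negative && nm != "od220") {
        warning(sprintf("clamping %d negative %s value(s) to 0 in %s phase",
                        sum(v < 0), nm, phase), call. = FALSE)
        vals[[nm]] <- pmax(v, 0)
      } else {
        stop(sprintf("negative %s absorbance in %s phase", nm, phase),
             call. = FALSE)
      }
    }
  }
  if (any(vals$od220 <= 0))
    stop(sprintf(
      "invalid denominator: od220 must be > 0 in %s phase (it normalises all ratios)",
      phase), call. = FALSE)
  structure(vals, class = "phase_od")
}

as_phase_od <- function(x, phase) {
  if (inherits(x, "phase_od")) return(x)
  if (is.list(x) && all(c("od220", "od232", "od278", "od400") %in% names(x)))
    return(phase_od(x$od220, x$od232, x$od278, x$od400, phase = phase))
  stop("expected a phase_od object or a list with od220/od232/od278/od400",
       call. = FALSE)
}

ratio_sum <- function(upper, lower, wavelength, coefficient) {
  upper <- as_phase_od(upper, "upper")
  lower <- as_phase_od(lower, "lower")
  (upper[[wavelength]] / upper$od220 + lower[[wavelength]] / lower$od220) *
    coefficient
}

#' Diene-conjugate concentration from two-phase absorbances
#'
#' `DC = (OD232up/OD220up + OD232lp/OD220lp) * coefficient`, in relative
#' units. The correction coefficient multiplies the sum of both phase ratios.
#'
#' @param upper,lower [phase_od()] objects (or lists coercible to them) for
#'   the heptane (upper) and isopropanol (lower) phases.
#' @param coefficient Correction coefficient; default `lpo_coefficients["DC"]`.
#' @return Numeric vector of DC concentrations (relative units, >= 0).
#' @examples
#' up <- phase_od(0.8, 0.2, 0.4, 0.04)
#' lo <- phase_od(0.5, 0.1, 0.2, 0.05)
#' compute_dc(up, lo)  # (0.25 + 0.20) * 0.14 = 0.063
#' @seealso [compute_tc()], [compute_sb()], [quantify_specimen()]
#' @export
compute_dc <- function(upper, lower, coefficient = lpo_coefficients[["DC"]]) {
  ratio_sum(upper, lower, "od232", coefficient)
}

#' Triene-conjugate concentration from two-phase absorbances
#'
#' `TC = (OD278up/OD220up + OD278lp/OD220lp) * coefficient`, relative units.
#'
#' @inheritParams compute_dc
#' @param coefficient Correction coefficient; default `lpo_coefficients["TC"]`.
#' @return Numeric vector of TC concentrations (relative units, >= 0).
#' @export
compute_tc <- function(upper, lower, coefficient = lpo_coefficients[["TC"]]) {
  ratio_sum(upper, lower, "od278", coefficient)
}

#' Schiff-base concentration from two-phase absorbances
#'
#' `SB = (OD400up/OD220up + OD400lp/OD220lp) * coefficient`, relative units.
#'
#' @inheritParams compute_dc
#' @param coefficient Correction coefficient; default `lpo_coefficients["SB"]`.
#' @return Numeric vector of SB concentrations (relative units, >= 0).
#' @export
compute_sb <- function(upper, lower, coefficient = lpo_coefficients[["SB"]]) {
  ratio_sum(upper, lower, "od400", coefficient)
}

#' Quantify all three LPO products for one specimen
#'
#' @param specimen A list with components `specimen_id`, `fluid`
#'   (`"saliva"` or `"plasma"`), `upper` and `lower` (each a [phase_od()]).
#' @param coefficients Named vector of correction coefficients
#'   (`DC`, `TC`, `SB`).
#' @return A list of class `"lpo_concentrations"` with components `dc`,
#'   `tc`, `sb` (relative units) plus the specimen's `specimen_id` and
#'   `fluid`.
#' @examples
#' s <- list(specimen_id = "S1", fluid = "plasma",
#'           upper = phase_od(1, 1, 1, 1), lower = phase_od(1, 1, 1, 1))
#' quantify_specimen(s)  # dc 0.28, tc 0.32, sb 104
#' @export
quantify_specimen <- function(specimen, coefficients = lpo_coefficients) {
  if (!is.list(specimen) || is.null(specimen$upper) || is.null(specimen$lower))
    stop("specimen must be a list with upper and lower phase readings",
         call. = FALSE)
  fluid <- specimen$fluid
  if (!is.null(fluid) && !all(fluid %in% c("saliva", "plasma")))
    stop("fluid must be 'saliva' or 'plasma'", call. = FALSE)
  id <- if (is.null(specimen$specimen_id)) NA_character_ else specimen$specimen_id
  res <- tryCatch(
    list(dc = compute_dc(specimen$upper, specimen$lower, coefficients[["DC"]]),
         tc = compute_tc(specimen$upper, specimen$lower, coefficients[["TC"]]),
         sb = compute_sb(specimen$upper, specimen$lower, coefficients[["SB"]])),
    error = function(e) stop(sprintf("specimen %s: %s",
                                     paste(id, collapse = ","),
                                     conditionMessage(e)), call. = FALSE))
  structure(c(res, list(specimen_id = id, fluid = fluid)),
            class = "lpo_concentrations")
}

#' Quantify a table of optical-density readings
#'
#' Applies the DC/TC/SB equations to a data frame in the assay's long OD
#' schema (one row per specimen): columns `specimen_id`, `subject_id`,
#' `fluid`, `cycle_phase`, `timepoint`, and the eight absorbances
#' `od220_up`, `od232_up`, `od278_up`, `od400_up`, `od220_lp`, `od232_lp`,
#' `od278_lp`, `od400_lp`.
#'
#' @param od A data frame in the OD schema above (see [read_od_csv()]).
#' @param clamp_negative_od Clamp negative numerator absorbances to 0 with a
#'   warning instead of erroring (od220 must always be positive).
#' @param coefficients Named vector of correction coefficients.
#' @return A data frame with columns `specimen_id`, `subject_id`, `fluid`,
#'   `cycle_phase`, `timepoint`, `dc`, `tc`, `sb`.
#' @export
quantify_od_table <- function(od, clamp_negative_od = FALSE,
                              coefficients = lpo_coefficients) {
  need <- c("specimen_id", "fluid", "od220_up", "od232_up", "od278_up",
            "od400_up", "od220_lp", "od232_lp", "od278_lp", "od400_lp")
  miss <- setdiff(need, names(od))
  if (length(miss))
    stop("OD table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(od$fluid %in% c("saliva", "plasma")))
    stop("fluid must be 'saliva' or 'plasma'", call. = FALSE)
  up <- phase_od(od$od220_up, od$od232_up, od$od278_up, od$od400_up,
                 phase = "upper", clamp_negative = clamp_negative_od)
  lo <- phase_od(od$od220_lp, od$od232_lp, od$od278_lp, od$od400_lp,
                 phase = "lower", clamp_negative = clamp_negative_od)
  out <- data.frame(
    specimen_id = od$specimen_id,
    subject_id = if ("subject_id" %in% names(od)) od$subject_id else NA,
    fluid = od$fluid,
    cycle_phase = if ("cycle_phase" %in% names(od)) od$cycle_phase else NA,
    timepoint = if ("timepoint" %in% names(od)) od$timepoint else NA,
    dc = compute_dc(up, lo, coefficients[["DC"]]),
    tc = compute_tc(up, lo, coefficients[["TC"]]),
    sb = compute_sb(up, lo, coefficients[["SB"]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read an optical-density CSV
#'
#' Header required; decimal point; UTF-8.
#'
#' @param path Path to a CSV in the OD schema of [quantify_od_table()].
#' @return A data frame.
#' @export
read_od_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write a concentrations table to CSV
#'
#' Values are written unrounded; presentation rounding is left to report
#' consumers.
#'
#' @param conc Data frame as returned by [quantify_od_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentrations_csv <- function(conc, path) {
  utils::write.csv(conc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
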