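#' Calvert dose
#'
#' `dose = target AUC * (CrCL + offset)` for creatinine-clearance methods;
#' direct-clearance methods store clearance minus the offset in their `crcl`
#' slot, so the same expression returns `target AUC * clearance` exactly.
#'
#' @param target_auc Target AUC in mg*min/mL (the study used 4, 5 or 6;
#'   values outside that set trigger a warning).
#' @param estimate A `renal_estimate`, or a plain CrCL in mL/min.
#' @param constants A [dosing_constants()] bundle.
#' @return Calculated (unrounded) dose in mg.
#' @examples
#' calvert_dose(5, 99)   # 620 mg
#' @export
calvert_dose <- function(target_auc, estimate, constants = dosing_constants()) {
  crcl <- if (inherits(estimate, "renal_estimate")) estimate$crcl else estimate
  if (target_auc < 0) stop("target AUC must be non-negative", call. = FALSE)
  if (target_auc > 0 && !target_auc %in% c(4, 5, 6)) {
    warning("target AUC ", target_auc, " is outside the usual {4, 5, 6}")
  }
  if (crcl <= 0) stop("clearance must be positive", call. = FALSE)
  target_auc * (crcl + constants$calvert_offset)
}

#' Round a dose to the administered increment
#'
#' Nearest multiple of the rounding increment; exact midpoints round down
#' (toxicity-conservative). Idempotent and monotone non-decreasing.
#'
#' @param dose Calculated dose in mg (non-negative).
#' @param increment Rounding increment in mg, default 50.
#' @return Administered dose in mg (an exact multiple of `increment`).
#' @examples
#' round_dose(620) # 600
#' round_dose(625) # 600 (midpoint down)
#' @export
round_dose <- function(dose, increment = 50) {
  if (any(dose < 0)) stop("dose must be non-negative", call. = FALSE)
  if (increment <= 0) stop("increment must be positive", call. = FALSE)
  increment * ceiling(dose / increment - 0.5)
}

#' Flat dose from the mean population clearance
#'
#' `target AUC * mean population clearance`, then rounded to the
#' administered increment.
#'
#' @inheritParams calvert_dose
#' @param increment Rounding increment in mg; `NULL` disables rounding.
#' @return Dose in mg.
#' @examples
#' flat_dose(6, increment = NULL) # 674.4
#' @export
flat_dose <- function(target_auc, constants = dosing_constants(),
                      increment = 50) {
  if (target_auc < 0) stop("target AUC must be non-negative", call. = FALSE)
  dose <- target_auc * constants$flat_population_cl
  if (is.null(increment)) dose else round_dose(dose, increment)
}

#' Dose a cohort by one method
#'
#' Computes the per-patient dose decision grid
#' `id, method, target_auc, crcl_ml_min, calculated_dose_mg,
#' administered_dose_mg` for one registered method. Patients missing a
#' covariate the method needs are dropped with a logged reason (attribute
#' `excluded`).
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param method One of [renal_methods()].
#' @param constants A [dosing_constants()] bundle.
#' @param coefficients A [formula_coefficients()] registry.
#' @param increment Rounding increment in mg; `NULL` disables rounding.
#' @return Data frame of dose decisions, one row per dosed patient.
#' @export
dose_cohort <- function(cohort, method = "aCG",
                        constants = dosing_constants(),
                        coefficients = formula_coefficients(),
                        increment = 50) {
  rows <- list()
  excluded <- character()
  for (i in seq_len(nrow(cohort))) {
    p <- as.list(cohort[i, ])
    est <- tryCatch(estimate_renal(p, method, constants, coefficients),
                    carbopk_missing_covariate = function(e) e)
    if (inherits(est, "condition")) {
      excluded <- c(excluded, stats::setNames(conditionMessage(est), p$id))
      next
    }
    calc <- calvert_dose(p$target_auc, est, constants)
    rows[[length(rows) + 1L]] <- data.frame(
      id = p$id, method = method, target_auc = p$target_auc,
      crcl_ml_min = est$crcl, calculated_dose_mg = calc,
      administered_dose_mg = if (is.null(increment)) calc else round_dose(calc, increment),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), method = character(), target_auc = numeric(),
               crcl_ml_min = numeric(), calculated_dose_mg = numeric(),
               administered_dose_mg = numeric(), stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}
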