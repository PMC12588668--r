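#' Body mass index
#'
#' @param weight Actual body weight in kg.
#' @param height Height in cm.
#' @return BMI in kg/m^2.
#' @examples
#' compute_bmi(99, 170)
#' @export
compute_bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight / (height / 100)^2
}

#' BMI stratum labels
#'
#' The three study strata: normal/underweight, overweight, obese. The lower
#' bound of each band is inclusive, so a BMI of exactly 25.0 is overweight
#' and 30.0 is obese.
#'
#' @param bmi BMI in kg/m^2.
#' @return Character vector in `c("<25.0", "25.0-29.9", ">=30.0")`.
#' @export
bmi_stratum <- function(bmi) {
  ifelse(bmi >= 30, ">=30.0", ifelse(bmi >= 25, "25.0-29.9", "<25.0"))
}

#' @rdname bmi_stratum
#' @export
stratum_levels <- function() c("<25.0", "25.0-29.9", ">=30.0")

#' Ideal and adjusted ideal body weight
#'
#' Devine ideal body weight (sex-specific base plus a per-inch slope above a
#' height anchor; heights below the anchor extrapolate linearly) and the
#' adjusted ideal body weight `IBW + f * (ABW - IBW)`.
#'
#' @param sex "M" or "F".
#' @param height Height in cm.
#' @param weight Actual body weight in kg (for [aibw()]).
#' @param coefficients A [formula_coefficients()] registry.
#' @param factor AIBW adjustment fraction, default from [dosing_constants()].
#' @return Weight in kg.
#' @examples
#' ibw("M", 180)
#' aibw("M", 180, 100)
#' @export
ibw <- function(sex, height, coefficients = formula_coefficients()) {
  if (any(height <= 0)) stop("height must be positive", call. = FALSE)
  cf <- coefficients$devine_ibw
  base <- ifelse(sex == "M", cf$base_male, cf$base_female)
  base + cf$slope_per_inch * (height - cf$height_anchor_cm) / 2.54
}

#' @rdname ibw
#' @export
aibw <- function(sex, height, weight, factor = 0.4,
                 coefficients = formula_coefficients()) {
  w_ideal <- ibw(sex, height, coefficients)
  w_ideal + factor * (weight - w_ideal)
}

#' Du Bois body surface area
#'
#' @param weight Weight in kg.
#' @param height Height in cm.
#' @param coefficients A [formula_coefficients()] registry.
#' @return BSA in m^2.
#' @examples
#' bsa_dubois(72, 180)
#' @export
bsa_dubois <- function(weight, height, coefficients = formula_coefficients()) {
  if (any(weight <= 0) || any(height <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  cf <- coefficients$dubois_bsa
  cf$coef * weight^cf$exp_weight * height^cf$exp_height
}

#' Cockcroft-Gault creatinine clearance
#'
#' The umol/L dialect: `(140 - age) * weight * F_sex / scr` with sex factors
#' 1.23 (male) and 1.04 (female) by default.
#'
#' @param weight_used Weight entering the formula, kg (ABW, AIBW or IBW).
#' @param age Age in years (must be below the age anchor, 140).
#' @param sex "M" or "F".
#' @param scr Serum creatinine in umol/L.
#' @param coefficients A [formula_coefficients()] registry.
#' @return Estimated creatinine clearance in mL/min.
#' @examples
#' cockcroft_gault(72, 40, "M", 80)
#' @export
cockcroft_gault <- function(weight_used, age, sex, scr,
                            coefficients = formula_coefficients()) {
  cf <- coefficients$cockcroft_gault
  if (any(scr <= 0)) stop("serum creatinine must be positive", call. = FALSE)
  if (any(age >= cf$age_anchor)) {
    stop("age must be below ", cf$age_anchor, " years", call. = FALSE)
  }
  f_sex <- ifelse(sex == "M", cf$factor_male, cf$factor_female)
  (cf$age_anchor - age) * weight_used * f_sex / scr
}

# uniform result record for every estimator in the registry.
# For direct-clearance methods `crcl` stores (clearance - calvert_offset) so
# that the downstream Calvert reconstruction crcl + offset returns the
# formula's clearance exactly.
renal_estimate <- function(method, crcl, weight_used = NA_real_,
                           weight_descriptor = "none",
                           scr_floored = FALSE, crcl_capped = FALSE,
                           raw_crcl = crcl, direct_clearance = FALSE) {
  stopifnot(crcl > 0, crcl <= raw_crcl + 1e-12)
  structure(list(method = method, crcl = crcl, weight_used = weight_used,
                 weight_descriptor = weight_descriptor,
                 scr_floored = scr_floored, crcl_capped = crcl_capped,
                 raw_crcl = raw_crcl, direct_clearance = direct_clearance),
            class = "renal_estimate")
}

#' @export
print.renal_estimate <- function(x, ...) {
  cat(sprintf("<renal_estimate> %s: %.2f mL/min", x$method, x$crcl))
  flags <- c(if (x$scr_floored) "scr floored",
             if (x$crcl_capped) sprintf("capped from %.2f", x$raw_crcl),
             if (x$direct_clearance) "direct clearance")
  if (length(flags)) cat(" [", paste(flags, collapse = "; "), "]", sep = "")
  cat("\n")
  invisible(x)
}

missing_covariate <- function(method, covariate) {
  stop(errorCondition(
    paste0("method '", method, "' requires covariate '", covariate, "'"),
    class = c("carbopk_missing_covariate", "error", "condition"),
    method = method, covariate = covariate))
}

#' Adjusted Cockcroft-Gault algorithm
#'
#' The adjusted dosing algorithm: AIBW replaces actual body weight when
#' BMI >= 25 kg/m^2, serum creatinine below 60 umol/L is floored at 60, and
#' the estimated creatinine clearance is capped at 125 mL/min. Flags record
#' which adjustments fired.
#'
#' @param patient A list or one-row data frame with fields `sex`, `age`,
#'   `weight_kg`, `height_cm`, `scr_umol_l` (and optionally `cysc_mg_l`,
#'   `ucr_mmol_24h` for other estimators).
#' @param constants A [dosing_constants()] bundle.
#' @param coefficients A [formula_coefficients()] registry.
#' @return A `renal_estimate`.
#' @examples
#' p <- list(sex = "M", age = 64, weight_kg = 99, height_cm = 170,
#'           scr_umol_l = 77)
#' adjusted_cg(p)
#' @export
adjusted_cg <- function(patient, constants = dosing_constants(),
                        coefficients = formula_coefficients()) {
  bmi <- compute_bmi(patient$weight_kg, patient$height_cm)
  if (bmi >= constants$bmi_threshold) {
    w <- aibw(patient$sex, patient$height_cm, patient$weight_kg,
              constants$aibw_factor, coefficients)
    descriptor <- "AIBW"
  } else {
    w <- patient$weight_kg
    descriptor <- "ABW"
  }
  scr_floored <- patient$scr_umol_l < constants$scr_floor
  scr_eff <- max(patient$scr_umol_l, constants$scr_floor)
  raw <- cockcroft_gault(w, patient$age, patient$sex, scr_eff, coefficients)
  capped <- raw > constants$crcl_cap
  renal_estimate("aCG", min(raw, constants$crcl_cap), weight_used = w,
                 weight_descriptor = descriptor, scr_floored = scr_floored,
                 crcl_capped = capped, raw_crcl = raw)
}

#' Conventional Cockcroft-Gault with a fixed weight descriptor
#'
#' The comparator rows: Cockcroft-Gault evaluated with a fixed descriptor
#' (ABW or AIBW). The capped variant applies both the serum-creatinine floor
#' and the creatinine-clearance cap; the uncapped variant applies neither.
#'
#' @inheritParams adjusted_cg
#' @param descriptor "ABW" or "AIBW".
#' @param capped Apply the scr floor and CrCL cap?
#' @return A `renal_estimate`.
#' @export
conventional_cg <- function(patient, descriptor = c("ABW", "AIBW"),
                            capped = FALSE, constants = dosing_constants(),
                            coefficients = formula_coefficients()) {
  descriptor <- match.arg(descriptor)
  w <- if (descriptor == "AIBW") {
    aibw(patient$sex, patient$height_cm, patient$weight_kg,
         constants$aibw_factor, coefficients)
  } else {
    patient$weight_kg
  }
  scr_floored <- capped && patient$scr_umol_l < constants$scr_floor
  scr_eff <- if (capped) max(patient$scr_umol_l, constants$scr_floor) else patient$scr_umol_l
  raw <- cockcroft_gault(w, patient$age, patient$sex, scr_eff, coefficients)
  do_cap <- capped && raw > constants$crcl_cap
  method <- paste0("CG_", descriptor, if (capped) "_capped" else "")
  renal_estimate(method, if (do_cap) constants$crcl_cap else raw,
                 weight_used = w, weight_descriptor = descriptor,
                 scr_floored = scr_floored, crcl_capped = do_cap,
                 raw_crcl = raw)
}

#' Chatelut-type carboplatin clearance with the Benezet substitution
#'
#' Direct carboplatin-clearance model
#' `CL = a*w + b*w*(1 - c*age)*(1 - d*female)/scr` evaluated at
#' `w = min(ABW, IBW)`, i.e. ideal body weight replaces actual body weight
#' whenever the patient is above ideal weight. Returned as a
#' direct-clearance estimate (`crcl` slot holds clearance minus the Calvert
#' offset).
#'
#' @inheritParams adjusted_cg
#' @return A `renal_estimate` with `direct_clearance = TRUE`.
#' @export
benezet_crcl <- function(patient, constants = dosing_constants(),
                         coefficients = formula_coefficients()) {
  cf <- coefficients$benezet
  if (patient$scr_umol_l <= 0) stop("serum creatinine must be positive", call. = FALSE)
  w_ideal <- ibw(patient$sex, patient$height_cm, coefficients)
  w <- min(patient$weight_kg, w_ideal)
  female <- as.numeric(patient$sex == "F")
  cl <- cf$intercept_per_kg * w +
    cf$slope * w * (1 - cf$age_coef * patient$age) *
      (1 - cf$female_coef * female) / patient$scr_umol_l
  renal_estimate("benezet", cl - constants$calvert_offset,
                 weight_used = w,
                 weight_descriptor = if (w < patient$weight_kg) "IBW" else "ABW",
                 direct_clearance = TRUE)
}

#' Cystatin-C carboplatin clearance (power covariate model)
#'
#' Direct carboplatin-clearance power model on serum creatinine, cystatin C,
#' actual body weight, age and sex; at the reference covariates the model
#' returns its typical clearance exactly. Returned as a direct-clearance
#' estimate (`crcl` slot holds clearance minus the Calvert offset).
#'
#' @inheritParams adjusted_cg
#' @return A `renal_estimate` with `direct_clearance = TRUE`.
#' @export
schmitt_clearance <- function(patient, constants = dosing_constants(),
                              coefficients = formula_coefficients()) {
  if (is.null(patient$cysc_mg_l) || is.na(patient$cysc_mg_l)) {
    missing_covariate("schmitt", "cysc_mg_l")
  }
  cf <- coefficients$schmitt
  cl <- cf$typical_cl *
    (patient$scr_umol_l / cf$scr_ref)^cf$scr_exp *
    (patient$cysc_mg_l / cf$cysc_ref)^cf$cysc_exp *
    (patient$weight_kg / cf$weight_ref)^cf$weight_exp *
    (patient$age / cf$age_ref)^cf$age_exp *
    cf$female_factor^(patient$sex == "F")
  renal_estimate("schmitt", cl - constants$calvert_offset,
                 weight_used = patient$weight_kg, weight_descriptor = "ABW",
                 direct_clearance = TRUE)
}

#' CKD-EPI 2021 race-free eGFR
#'
#' The 2021 creatinine and creatinine-cystatin-C equations. The indexed
#' eGFR (mL/min/1.73 m^2) is de-indexed to absolute mL/min via Du Bois BSA
#' by default, as required for dimensional consistency in the Calvert
#' formula. Serum creatinine in umol/L is converted to mg/dL internally.
#'
#' @inheritParams adjusted_cg
#' @param variant "creatinine" or "creatinine_cystatin".
#' @param deindex Multiply by BSA/1.73 to obtain absolute mL/min?
#' @return A `renal_estimate`.
#' @export
ckdepi <- function(patient, variant = c("creatinine", "creatinine_cystatin"),
                   deindex = TRUE, constants = dosing_constants(),
                   coefficients = formula_coefficients()) {
  variant <- match.arg(variant)
  scr <- patient$scr_umol_l / coefficients$units$scr_umol_per_mgdl
  female <- patient$sex == "F"
  if (variant == "creatinine") {
    cf <- coefficients$ckdepi_2021_cr
    kappa <- if (female) cf$kappa_female else cf$kappa_male
    alpha <- if (female) cf$alpha_female else cf$alpha_male
    egfr <- cf$base * min(scr / kappa, 1)^alpha * max(scr / kappa, 1)^cf$exp_high *
      cf$age_decay^patient$age * (if (female) cf$female_factor else 1)
    method <- "ckdepi_cr"
  } else {
    if (is.null(patient$cysc_mg_l) || is.na(patient$cysc_mg_l)) {
      missing_covariate("ckdepi_crcys", "cysc_mg_l")
    }
    cf <- coefficients$ckdepi_2021_crcys
    kappa <- if (female) cf$kappa_female else cf$kappa_male
    alpha <- if (female) cf$alpha_female else cf$alpha_male
    cys <- patient$cysc_mg_l
    egfr <- cf$base * min(scr / kappa, 1)^alpha * max(scr / kappa, 1)^cf$exp_high *
      min(cys / cf$cysc_knot, 1)^cf$cysc_exp_low *
      max(cys / cf$cysc_knot, 1)^cf$cysc_exp_high *
      cf$age_decay^patient$age * (if (female) cf$female_factor else 1)
    method <- "ckdepi_crcys"
  }
  if (deindex) {
    bsa <- bsa_dubois(patient$weight_kg, patient$height_cm, coefficients)
    egfr <- egfr * bsa / 1.73
  }
  renal_estimate(method, egfr, weight_used = patient$weight_kg,
                 weight_descriptor = "ABW")
}

#' Measured 24-hour creatinine clearance
#'
#' `CrCL (mL/min) = excretion rate / serum concentration` with the 24-hour
#' urinary creatinine in mmol/24 h and serum creatinine in umol/L.
#'
#' @param urine_creatinine_24h Urinary creatinine excretion, mmol per 24 h.
#' @param scr Serum creatinine, umol/L.
#' @return A `renal_estimate`.
#' @examples
#' crcl_24h(9.8, 69)
#' @export
crcl_24h <- function(urine_creatinine_24h, scr) {
  if (is.null(urine_creatinine_24h) || is.na(urine_creatinine_24h)) {
    missing_covariate("crcl_24h", "ucr_mmol_24h")
  }
  if (urine_creatinine_24h <= 0 || scr <= 0) {
    stop("24-h urine creatinine and serum creatinine must be positive",
         call. = FALSE)
  }
  crcl <- urine_creatinine_24h * 1000 / 1440 / scr * 1000
  renal_estimate("crcl_24h", crcl)
}

#' Registered dosing methods
#'
#' The ten methods of the comparison grid: the adjusted Cockcroft-Gault
#' algorithm, conventional Cockcroft-Gault with ABW (uncapped and capped)
#' and AIBW, the Benezet-substituted Chatelut clearance, measured 24-hour
#' creatinine clearance, the cystatin-C clearance model, both 2021 CKD-EPI
#' equations, and flat dosing from the mean population clearance.
#'
#' @return Character vector of method identifiers.
#' @export
renal_methods <- function() {
  c("aCG", "CG_ABW", "CG_ABW_capped", "CG_AIBW", "benezet",
    "crcl_24h", "schmitt", "ckdepi_cr", "ckdepi_crcys", "flat")
}

#' Evaluate one registered method on one patient
#'
#' Dispatches a method identifier from [renal_methods()] to its estimator.
#' Missing covariates raise a condition of class
#' `carbopk_missing_covariate`, mirroring per-method patient exclusion.
#'
#' @inheritParams adjusted_cg
#' @param method One of [renal_methods()].
#' @return A `renal_estimate`.
#' @export
estimate_renal <- function(patient, method, constants = dosing_constants(),
                           coefficients = formula_coefficients()) {
  switch(method,
    aCG = adjusted_cg(patient, constants, coefficients),
    CG_ABW = conventional_cg(patient, "ABW", FALSE, constants, coefficients),
    CG_ABW_capped = conventional_cg(patient, "ABW", TRUE, constants, coefficients),
    CG_AIBW = conventional_cg(patient, "AIBW", FALSE, constants, coefficients),
    benezet = benezet_crcl(patient, constants, coefficients),
    crcl_24h = crcl_24h(patient$ucr_mmol_24h, patient$scr_umol_l),
    schmitt = schmitt_clearance(patient, constants, coefficients),
    ckdepi_cr = ckdepi(patient, "creatinine", TRUE, constants, coefficients),
    ckdepi_crcys = ckdepi(patient, "creatinine_cystatin", TRUE, constants, coefficients),
    flat = renal_estimate("flat",
                          constants$flat_population_cl - constants$calvert_offset,
                          direct_clearance = TRUE),
    stop("unknown method '", method, "'", call. = FALSE))
}
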