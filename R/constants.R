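#' Dosing constants
#'
#' Bundle of the fixed clinical constants used throughout the dosing
#' pipeline: the Calvert non-renal clearance offset, the creatinine-clearance
#' cap, the serum-creatinine floor, the BMI threshold above which adjusted
#' ideal body weight is used, the mean population carboplatin clearance used
#' for flat dosing, and the AIBW adjustment factor.
#'
#' @param calvert_offset Non-renal clearance term of the Calvert formula
#'   (mL/min). Default 25.
#' @param crcl_cap Upper cap on estimated creatinine clearance (mL/min).
#'   Default 125.
#' @param scr_floor Lower floor on serum creatinine (umol/L). Default 60.
#' @param bmi_threshold BMI (kg/m^2) at or above which AIBW replaces actual
#'   body weight in the adjusted algorithm. Default 25.
#' @param flat_population_cl Mean population carboplatin clearance (mL/min)
#'   used for flat dosing. Default 112.4.
#' @param aibw_factor Fraction of the excess over ideal body weight added
#'   back when forming AIBW. Default 0.4.
#' @return A list of class `dosing_constants`.
#' @examples
#' dosing_constants()
#' @export
dosing_constants <- function(calvert_offset = 25, crcl_cap = 125,
                             scr_floor = 60, bmi_threshold = 25,
                             flat_population_cl = 112.4, aibw_factor = 0.4) {
  x <- list(calvert_offset = calvert_offset, crcl_cap = crcl_cap,
            scr_floor = scr_floor, bmi_threshold = bmi_threshold,
            flat_population_cl = flat_population_cl,
            aibw_factor = aibw_factor)
  for (nm in names(x)) {
    v <- x[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("dosing constant '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  structure(x, class = "dosing_constants")
}

# default coefficient sets; every registered estimator draws its numeric
# constants from here so that alternative dialects (e.g. the mg/dL
# Cockcroft-Gault form) are a config change, not a code change.
default_coefficients <- function() {
  list(
    cockcroft_gault = list(
      # umol/L serum-creatinine dialect
      factor_male = 1.23, factor_female = 1.04, age_anchor = 140
    ),
    devine_ibw = list(
      base_male = 50, base_female = 45.5,
      slope_per_inch = 2.3, height_anchor_cm = 152.4
    ),
    dubois_bsa = list(coef = 0.007184, exp_weight = 0.425, exp_height = 0.725),
    benezet = list(
      # Chatelut-type carboplatin clearance evaluated at min(ABW, IBW)
      intercept_per_kg = 0.134, slope = 218,
      age_coef = 0.00457, female_coef = 0.314
    ),
    schmitt = list(
      # cystatin-C carboplatin clearance power model (direct clearance)
      typical_cl = 110,
      scr_ref = 75, scr_exp = -0.512,
      cysc_ref = 1.0, cysc_exp = -0.327,
      weight_ref = 65, weight_exp = 0.474,
      age_ref = 56, age_exp = -0.387,
      female_factor = 0.854
    ),
    ckdepi_2021_cr = list(
      base = 142, kappa_female = 0.7, kappa_male = 0.9,
      alpha_female = -0.241, alpha_male = -0.302,
      exp_high = -1.200, age_decay = 0.9938, female_factor = 1.012
    ),
    ckdepi_2021_crcys = list(
      base = 135, kappa_female = 0.7, kappa_male = 0.9,
      alpha_female = -0.219, alpha_male = -0.144,
      exp_high = -0.544, cysc_knot = 0.8,
      cysc_exp_low = -0.323, cysc_exp_high = -0.778,
      age_decay = 0.9961, female_factor = 0.963
    ),
    units = list(scr_umol_per_mgdl = 88.4)
  )
}

#' Formula coefficient registry
#'
#' Named coefficient sets for every renal-function / carboplatin-clearance
#' estimator in the registry: Cockcroft-Gault sex factors (umol/L dialect),
#' Devine ideal body weight, Du Bois body surface area, the Chatelut-type
#' clearance model with the Benezet ideal-body-weight substitution, the
#' cystatin-C clearance power model, and the 2021 race-free CKD-EPI
#' creatinine and creatinine-cystatin-C equations.
#'
#' @param path Optional path to a YAML file whose top-level tables override
#'   individual coefficients; unknown tables or coefficient names are an
#'   error, and every registered set must remain complete.
#' @return A list of class `formula_coefficients`, one named table per
#'   formula.
#' @examples
#' cf <- formula_coefficients()
#' names(cf)
#' @export
formula_coefficients <- function(path = NULL) {
  cf <- default_coefficients()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("coefficient file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    for (tab in names(user)) {
      if (!tab %in% names(cf)) {
        stop("unknown coefficient table '", tab, "' in ", path, call. = FALSE)
      }
      for (nm in names(user[[tab]])) {
        if (!nm %in% names(cf[[tab]])) {
          stop("unknown coefficient '", tab, "$", nm, "' in ", path, call. = FALSE)
        }
        cf[[tab]][[nm]] <- user[[tab]][[nm]]
      }
    }
  }
  for (tab in names(cf)) {
    ok <- vapply(cf[[tab]], function(v) {
      is.numeric(v) && length(v) == 1L && is.finite(v)
    }, logical(1))
    if (!all(ok)) {
      stop("incomplete coefficient set '", tab, "': ",
           paste(names(cf[[tab]])[!ok], collapse = ", "), call. = FALSE)
    }
  }
  structure(cf, class = "formula_coefficients")
}
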