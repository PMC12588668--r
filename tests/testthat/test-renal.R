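test_that("BMI computation and stratum bands behave at interior points and the 25.0 boundary", {
  expect_equal(compute_bmi(99, 170), 99 / 1.70^2, tolerance = 1e-12)
  expect_equal(round(compute_bmi(99, 170), 2), 34.26)
  # lower band edges are inclusive
  expect_equal(bmi_stratum(compute_bmi(72.25, 170)), "25.0-29.9")
  expect_equal(bmi_stratum(c(24.999, 25, 29.999, 30, 41)),
               c("<25.0", "25.0-29.9", "25.0-29.9", ">=30.0", ">=30.0"))
  # algebraic identity: weight chosen so BMI is exactly 25
  for (h in c(155, 170.3, 192)) {
    expect_equal(compute_bmi(25 * (h / 100)^2, h), 25, tolerance = 1e-12)
  }
  expect_error(compute_bmi(-1, 170), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("Devine ideal weight and the AIBW adjustment compose correctly", {
  # 50 kg + 2.3 kg per inch over 152.4 cm: 180 cm male
  expect_equal(ibw("M", 180), 50 + 2.3 * (180 - 152.4) / 2.54, tolerance = 1e-12)
  expect_equal(ibw("M", 180), 74.99213, tolerance = 1e-6)
  expect_equal(ibw("F", 180) - ibw("M", 180), 45.5 - 50, tolerance = 1e-12)
  # fixed point: at ideal weight the adjustment changes nothing
  w_id <- ibw("F", 165)
  expect_equal(aibw("F", 165, w_id), w_id, tolerance = 1e-12)
  # composition with the configured factor
  expect_equal(aibw("M", 180, 100, factor = 0.4),
               74.99213 + 0.4 * (100 - 74.99213), tolerance = 1e-5)
})

test_that("Cockcroft-Gault matches hand arithmetic and its scaling laws", {
  expect_equal(cockcroft_gault(72, 40, "M", 80), 110.7, tolerance = 1e-10)
  p <- make_patient()
  m <- cockcroft_gault(70, 55, "M", 90)
  f <- cockcroft_gault(70, 55, "F", 90)
  expect_equal(f / m, 1.04 / 1.23, tolerance = 1e-12)
  expect_equal(cockcroft_gault(70, 55, "M", 180),
               cockcroft_gault(70, 55, "M", 90) / 2, tolerance = 1e-12)
  expect_error(cockcroft_gault(70, 150, "M", 90), "age")
  expect_error(cockcroft_gault(70, 55, "M", 0), "creatinine")
})

test_that("adjusted algorithm applies the AIBW switch, creatinine floor and clearance cap", {
  # scr below the floor is replaced by 60 and flagged
  p_low <- make_patient(scr_umol_l = 49, weight_kg = 60, height_cm = 180)
  est <- adjusted_cg(p_low)
  expect_true(est$scr_floored)
  expect_equal(est$raw_crcl, cockcroft_gault(60, 60, "M", 60), tolerance = 1e-12)
  # overweight patient uses AIBW
  p_ob <- make_patient(weight_kg = 99, height_cm = 170)
  est_ob <- adjusted_cg(p_ob)
  expect_equal(est_ob$weight_descriptor, "AIBW")
  expect_equal(est_ob$weight_used, aibw("M", 170, 99), tolerance = 1e-12)
  # cap: construct scr (above the floor) so the raw estimate is exactly 139.54
  w_used <- aibw("M", 170, 99)
  scr <- (140 - 40) * w_used * 1.23 / 139.54
  stopifnot(scr >= 60)
  p_cap <- make_patient(age = 40, weight_kg = 99, height_cm = 170,
                        scr_umol_l = scr)
  est_cap <- adjusted_cg(p_cap)
  expect_equal(est_cap$raw_crcl, 139.54, tolerance = 1e-9)
  expect_equal(est_cap$crcl, 125)
  expect_true(est_cap$crcl_capped)
  # identity branch: BMI < 25, scr >= 60, raw below cap -> no flags
  p_id <- make_patient(weight_kg = 70, height_cm = 180, scr_umol_l = 95)
  est_id <- adjusted_cg(p_id)
  expect_false(est_id$scr_floored || est_id$crcl_capped)
  expect_equal(est_id$crcl, cockcroft_gault(70, 60, "M", 95), tolerance = 1e-12)
})

test_that("conventional CG variants: descriptor choice, cap rule and AIBW monotonicity", {
  p <- make_patient(weight_kg = 99, height_cm = 170, scr_umol_l = 70)
  abw <- conventional_cg(p, "ABW")
  aib <- conventional_cg(p, "AIBW")
  expect_equal(abw$weight_used, 99)
  # AIBW <= ABW whenever weight exceeds ideal, so the estimate is lower
  expect_lt(aib$crcl, abw$crcl)
  # capped variant applies floor and cap; 139.54 -> 125
  w <- 99
  scr <- (140 - 60) * w * 1.23 / 139.54
  stopifnot(scr >= 60)
  p_cap <- make_patient(weight_kg = w, height_cm = 170, scr_umol_l = scr)
  est <- conventional_cg(p_cap, "ABW", capped = TRUE)
  expect_equal(est$crcl, 125)
  expect_true(est$crcl_capped)
  # uncapped variant applies neither adjustment
  p_low <- make_patient(scr_umol_l = 45)
  expect_false(conventional_cg(p_low, "ABW")$scr_floored)
  expect_true(conventional_cg(p_low, "ABW", capped = TRUE)$scr_floored)
})

test_that("Chatelut-type clearance with the ideal-weight substitution", {
  # golden value: male, 60 y, 70 kg (below ideal weight at 175 cm), scr 80
  p <- make_patient()
  est <- benezet_crcl(p)
  expect_true(est$direct_clearance)
  expect_equal(est$crcl + 25, 147.8263, tolerance = 1e-4)
  # below ideal weight the substitution is inert
  expect_equal(est$weight_used, 70)
  # above ideal weight the model evaluates at IBW
  p_ob <- make_patient(weight_kg = 110)
  est_ob <- benezet_crcl(p_ob)
  expect_equal(est_ob$weight_used, ibw("M", 175), tolerance = 1e-12)
  # strictly decreasing in serum creatinine
  cls <- vapply(c(60, 80, 100, 130), function(s) {
    benezet_crcl(make_patient(scr_umol_l = s))$crcl
  }, 0)
  expect_true(all(diff(cls) < 0))
})

test_that("cystatin-C clearance model: reference identity, golden value, monotonicity, exclusion", {
  # at the reference covariates the power model returns its typical value
  ref <- make_patient(sex = "M", age = 56, weight_kg = 65, scr_umol_l = 75,
                      cysc_mg_l = 1.0)
  expect_equal(schmitt_clearance(ref)$crcl + 25, 110, tolerance = 1e-10)
  # golden value from independent hand evaluation
  expect_equal(schmitt_clearance(make_patient())$crcl + 25, 101.1136,
               tolerance = 1e-4)
  # clearance strictly decreases as cystatin C rises
  cls <- vapply(c(0.8, 1.0, 1.5, 2.0), function(cc) {
    schmitt_clearance(make_patient(cysc_mg_l = cc))$crcl
  }, 0)
  expect_true(all(diff(cls) < 0))
  expect_error(schmitt_clearance(make_patient(cysc_mg_l = NA)),
               class = "carbopk_missing_covariate")
})

test_that("CKD-EPI 2021: knot identity, golden values, BSA de-indexing", {
  # female with scr exactly at the female knot: both spline terms are 1
  p_knot <- make_patient(sex = "F", age = 40, scr_umol_l = 0.7 * 88.4)
  est <- ckdepi(p_knot, "creatinine", deindex = FALSE)
  expect_equal(est$crcl, 142 * 0.9938^40 * 1.012, tolerance = 1e-10)
  # golden values (indexed): male, 60 y, scr 80 umol/L (0.90498 mg/dL)
  p <- make_patient()
  expect_equal(ckdepi(p, "creatinine", deindex = FALSE)$crcl, 97.13005,
               tolerance = 1e-5)
  expect_equal(ckdepi(p, "creatinine_cystatin", deindex = FALSE)$crcl,
               77.66193, tolerance = 1e-5)
  # neutral BSA: de-indexing with BSA = 1.73 m^2 changes nothing
  # (find a height/weight pair with Du Bois BSA 1.73 by 1-D search)
  h <- 170
  f <- function(w) bsa_dubois(w, h) - 1.73
  w <- uniroot(f, c(40, 120), tol = 1e-12)$root
  p_neutral <- make_patient(weight_kg = w, height_cm = h)
  expect_equal(ckdepi(p_neutral, "creatinine", deindex = TRUE)$crcl,
               ckdepi(p_neutral, "creatinine", deindex = FALSE)$crcl,
               tolerance = 1e-9)
  expect_error(ckdepi(make_patient(cysc_mg_l = NA), "creatinine_cystatin"),
               class = "carbopk_missing_covariate")
})

test_that("24-hour creatinine clearance arithmetic", {
  expect_equal(crcl_24h(9.8, 69)$crcl, 98.63124, tolerance = 1e-5)
  # ratio is invariant to scaling both inputs
  expect_equal(crcl_24h(19.6, 138)$crcl, crcl_24h(9.8, 69)$crcl,
               tolerance = 1e-12)
  # constructed so the output is exactly 100 mL/min
  scr <- 85
  ucr <- 100 * scr * 1440 / 1e6
  expect_equal(crcl_24h(ucr, scr)$crcl, 100, tolerance = 1e-12)
  expect_error(crcl_24h(NA, 80), class = "carbopk_missing_covariate")
  expect_error(crcl_24h(-1, 80), "positive")
})

test_that("Du Bois body surface area", {
  expect_equal(bsa_dubois(72, 180), 1.909, tolerance = 1e-3)
  # monotone increasing in each argument
  expect_true(bsa_dubois(80, 180) > bsa_dubois(72, 180))
  expect_true(bsa_dubois(72, 190) > bsa_dubois(72, 180))
  # degenerate coefficients give the constant 1
  cf <- formula_coefficients()
  cf$dubois_bsa <- list(coef = 1, exp_weight = 0, exp_height = 0)
  expect_equal(bsa_dubois(72, 180, cf), 1)
})

test_that("registry: full method list evaluates to the 10-row grid with cap dominance", {
  p <- make_patient(weight_kg = 99, height_cm = 170, scr_umol_l = 77,
                    cysc_mg_l = 1.3, ucr_mmol_24h = 14.5)
  ests <- lapply(renal_methods(), estimate_renal, patient = p)
  expect_length(ests, 10)
  expect_equal(vapply(ests, `[[`, "", "method"), renal_methods())
  for (e in ests) {
    expect_gt(e$crcl, 0)
    expect_lte(e$crcl, e$raw_crcl + 1e-12)
  }
  # cap dominance for the capping methods
  consts <- dosing_constants()
  p_hot <- make_patient(weight_kg = 120, height_cm = 165, scr_umol_l = 50)
  expect_lte(adjusted_cg(p_hot)$crcl, consts$crcl_cap)
  expect_lte(conventional_cg(p_hot, "ABW", capped = TRUE)$crcl, consts$crcl_cap)
  # flat is covariate-free direct clearance reconstructing 112.4
  flat <- estimate_renal(p, "flat")
  expect_true(flat$direct_clearance)
  expect_equal(flat$crcl + consts$calvert_offset, consts$flat_population_cl)
})

test_that("coefficient registry loads, overrides and fails loudly", {
  cf <- formula_coefficients()
  expect_s3_class(cf, "formula_coefficients")
  path <- system.file("extdata", "formula_coefficients.yaml", package = "carbopk")
  cf2 <- formula_coefficients(path)
  expect_equal(unclass(cf2), unclass(cf))
  bad <- tempfile(fileext = ".yaml")
  writeLines("schmitt:\n  not_a_coef: 1", bad)
  expect_error(formula_coefficients(bad), "unknown coefficient")
  bad2 <- tempfile(fileext = ".yaml")
  writeLines("nonsense:\n  a: 1", bad2)
  expect_error(formula_coefficients(bad2), "unknown coefficient table")
})
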