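#' Cohort generation specification
#'
#' Per-stratum sample sizes and covariate distributions for the synthetic
#' cohort generator, the inter-individual variability of the latent true
#' carboplatin clearance, the urinary-creatinine measurement noise, and the
#' truth formula that defines the reference clearance. The shipped defaults
#' mirror the study's per-stratum covariate ranges and counts (7/5/6
#' patients; covariates uniform within the printed ranges; sex probabilities
#' from the printed counts; target AUC drawn from \{5, 6\} with P(6) = 0.8).
#'
#' @param strata A list of per-stratum specifications; each element has
#'   `n`, `bmi_min`, `bmi_max`, `age` (range), `weight` (range, kg),
#'   `height` (range, cm), `scr` (range, umol/L), `cysc` (range, mg/L) and
#'   `p_male`.
#' @param omega_cl Standard deviation of the log-scale clearance deviation
#'   eta (default 0.2, about 20% CV).
#' @param ucr_cv Multiplicative coefficient of variation of the back-computed
#'   24-h urinary creatinine (default 0.1).
#' @param truth_method Method from [renal_methods()] whose estimate defines
#'   the latent reference clearance (default "aCG", so dosing by the
#'   adjusted algorithm is unbiased by construction).
#' @param p_auc6 Probability that a patient's target AUC is 6 rather than 5.
#' @param seed Root seed; per-patient substreams are derived from
#'   `(seed, patient index)` so cohorts are extensible without reshuffling.
#' @return A list of class `cohort_spec`.
#' @examples
#' sp <- cohort_spec(seed = 1)
#' vapply(sp$strata, `[[`, 0, "n")
#' @export
cohort_spec <- function(strata = default_strata(), omega_cl = 0.2,
                        ucr_cv = 0.1, truth_method = "aCG", p_auc6 = 0.8,
                        seed = 1L) {
  stopifnot(is.list(strata), length(strata) >= 1,
            omega_cl >= 0, ucr_cv >= 0,
            truth_method %in% renal_methods(),
            p_auc6 >= 0, p_auc6 <= 1)
  for (s in strata) {
    stopifnot(s$n >= 0, s$bmi_min < s$bmi_max, s$p_male >= 0, s$p_male <= 1)
    for (rng in c("age", "weight", "height", "scr", "cysc")) {
      r <- s[[rng]]
      if (length(r) != 2 || r[1] > r[2] || r[1] <= 0) {
        stop("stratum range '", rng, "' must be an ordered positive pair",
             call. = FALSE)
      }
    }
  }
  structure(list(strata = strata, omega_cl = omega_cl, ucr_cv = ucr_cv,
                 truth_method = truth_method, p_auc6 = p_auc6,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_strata <- function() {
  list(
    `<25.0` = list(n = 7, bmi_min = 15, bmi_max = 25,
                   age = c(50, 78), weight = c(48, 80), height = c(171, 185),
                   scr = c(49, 95), cysc = c(0.8, 1.6), p_male = 6 / 7),
    `25.0-29.9` = list(n = 5, bmi_min = 25, bmi_max = 30,
                       age = c(54, 77), weight = c(72, 81), height = c(166, 173),
                       scr = c(67, 130), cysc = c(0.8, 1.9), p_male = 1 / 5),
    `>=30.0` = list(n = 6, bmi_min = 30, bmi_max = 45,
                    age = c(56, 78), weight = c(87, 115), height = c(160, 180),
                    scr = c(57, 114), cysc = c(0.8, 1.5), p_male = 3 / 6)
  )
}

# deterministic per-patient substream: a fixed affine hash of the root seed
# and the 1-based global patient index, kept inside 32-bit integer range.
patient_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

#' Generate a synthetic cohort with latent truth
#'
#' Draws covariates uniformly within each stratum's configured ranges
#' (resampling internally until the implied BMI falls in the stratum band),
#' derives the latent reference clearance from the configured truth formula,
#' sets the true carboplatin clearance to
#' `(reference CrCL + Calvert offset) * exp(eta)` with
#' `eta ~ N(0, omega_cl^2)`, and back-computes the 24-h urinary creatinine
#' from the latent creatinine clearance and serum creatinine with
#' multiplicative noise. Generation is reproducible to the byte for a fixed
#' spec.
#'
#' @param spec A [cohort_spec()].
#' @param constants A [dosing_constants()] bundle.
#' @param coefficients A [formula_coefficients()] registry.
#' @return A list with `cohort` (data frame: `id, sex, age, weight_kg,
#'   height_cm, scr_umol_l, cysc_mg_l, ucr_mmol_24h, target_auc, stratum`)
#'   and `truth` (data frame: `id, true_cl_ml_min, eta_cl, true_crcl_ml_min`).
#' @examples
#' cg <- generate_cohort(cohort_spec(seed = 1))
#' table(cg$cohort$stratum)
#' @export
generate_cohort <- function(spec, constants = dosing_constants(),
                            coefficients = formula_coefficients()) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  truths <- list()
  idx <- 0L
  for (sname in names(spec$strata)) {
    s <- spec$strata[[sname]]
    if (s$n == 0) next
    for (k in seq_len(s$n)) {
      idx <- idx + 1L
      set.seed(patient_seed(spec$seed, idx))
      sex <- if (stats::runif(1) < s$p_male) "M" else "F"
      age <- sample(seq(s$age[1], s$age[2]), 1L)
      for (tries in 1:10000) {
        weight <- round(stats::runif(1, s$weight[1], s$weight[2]), 1)
        height <- round(stats::runif(1, s$height[1], s$height[2]), 1)
        bmi <- compute_bmi(weight, height)
        if (bmi >= s$bmi_min && bmi < s$bmi_max) break
        if (tries == 10000) {
          stop("stratum '", sname, "': could not sample a BMI inside [",
               s$bmi_min, ", ", s$bmi_max, ") from the configured weight ",
               "and height ranges", call. = FALSE)
        }
      }
      scr <- round(stats::runif(1, s$scr[1], s$scr[2]))
      cysc <- round(stats::runif(1, s$cysc[1], s$cysc[2]), 2)
      target <- if (stats::runif(1) < spec$p_auc6) 6 else 5
      eta <- if (spec$omega_cl > 0) stats::rnorm(1, 0, spec$omega_cl) else 0
      patient <- list(id = sprintf("P%03d", idx), sex = sex, age = age,
                      weight_kg = weight, height_cm = height,
                      scr_umol_l = scr, cysc_mg_l = cysc,
                      target_auc = target)
      est <- estimate_renal(patient, spec$truth_method, constants, coefficients)
      true_crcl <- est$crcl
      true_cl <- (true_crcl + constants$calvert_offset) * exp(eta)
      # 24-h urinary creatinine (mmol) consistent with the latent CrCL:
      # excretion (umol/24h) = CrCL (mL/min) * Scr (umol/L) * 1440 / 1000
      ucr <- true_crcl * scr * 1440 / 1e6
      if (spec$ucr_cv > 0) {
        repeat {
          noisy <- ucr * (1 + stats::rnorm(1, 0, spec$ucr_cv))
          if (noisy > 0) break
        }
        ucr <- noisy
      }
      rows[[idx]] <- data.frame(id = patient$id, sex = sex, age = as.numeric(age),
                                weight_kg = weight, height_cm = height,
                                scr_umol_l = scr, cysc_mg_l = cysc,
                                ucr_mmol_24h = ucr, target_auc = target,
                                stratum = sname, stringsAsFactors = FALSE)
      truths[[idx]] <- data.frame(id = patient$id, true_cl_ml_min = true_cl,
                                  eta_cl = eta, true_crcl_ml_min = true_crcl,
                                  stringsAsFactors = FALSE)
    }
  }
  list(cohort = do.call(rbind, rows), truth = do.call(rbind, truths))
}

# shortest decimal representation that parses back to the identical double
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

cohort_columns <- c("id", "sex", "age", "weight_kg", "height_cm",
                    "scr_umol_l", "cysc_mg_l", "ucr_mmol_24h",
                    "target_auc", "stratum")

#' Read and write cohort tables
#'
#' Cohort CSV: comma-separated, UTF-8, dot decimal separator, header
#' `id,sex,age,weight_kg,height_cm,scr_umol_l,cysc_mg_l,ucr_mmol_24h,target_auc,stratum`.
#' Sex is coded M/F; a blank field is missing. Numbers are written with
#' enough digits that a write/read round trip reproduces every stored value
#' exactly.
#'
#' @param cohort A cohort data frame as returned by [generate_cohort()].
#' @param path File path.
#' @param strict For [read_cohort()]: reject files with unknown columns
#'   (default); if `FALSE`, extra columns are preserved.
#' @return `read_cohort()` returns the cohort data frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(cohort_columns %in% names(cohort)))
  out <- cohort[cohort_columns]
  num_cols <- setdiff(cohort_columns, c("id", "sex", "stratum"))
  lines <- paste(cohort_columns, collapse = ",")
  for (i in seq_len(nrow(out))) {
    fields <- vapply(cohort_columns, function(cn) {
      v <- out[[cn]][i]
      if (cn %in% num_cols) format_full(as.numeric(v)) else as.character(v)
    }, character(1))
    lines <- c(lines, paste(fields, collapse = ","))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cohort_columns, names(df))
  if (length(missing)) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), cohort_columns)
  if (strict && length(extra)) {
    stop("cohort file has unknown column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  num_cols <- setdiff(cohort_columns, c("id", "sex", "stratum"))
  for (cn in num_cols) {
    raw <- df[[cn]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & nzchar(raw) & is.na(v)
    if (any(bad)) {
      stop("unparseable number in column '", cn, "': ",
           raw[bad][1], call. = FALSE)
    }
    v[!nzchar(raw)] <- NA_real_
    df[[cn]] <- v
  }
  if (!all(df$sex %in% c("M", "F"))) {
    stop("sex must be coded M or F", call. = FALSE)
  }
  df
}

#' Read and write the simulation truth sidecar
#'
#' Truth CSV (simulation only): `id,true_cl_ml_min,eta_cl,true_crcl_ml_min`.
#'
#' @param truth Truth data frame as returned by [generate_cohort()].
#' @param path File path.
#' @return `read_truth()` returns the truth data frame.
#' @export
write_truth <- function(truth, path) {
  cols <- c("id", "true_cl_ml_min", "eta_cl", "true_crcl_ml_min")
  stopifnot(all(cols %in% names(truth)))
  lines <- paste(cols, collapse = ",")
  for (i in seq_len(nrow(truth))) {
    lines <- c(lines, paste(c(truth$id[i],
                              format_full(truth$true_cl_ml_min[i]),
                              format_full(truth$eta_cl[i]),
                              format_full(truth$true_crcl_ml_min[i])),
                            collapse = ","))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("id", "true_cl_ml_min", "eta_cl", "true_crcl_ml_min")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("truth file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}
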