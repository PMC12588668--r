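#' Estimated AUC from an administered dose
#'
#' Converts an administered dose into a method's estimated AUC by dividing
#' by that method's Calvert clearance (`CrCL + offset`, or the direct
#' clearance for direct-clearance methods).
#'
#' @param administered_dose Administered dose in mg.
#' @param estimate A `renal_estimate`.
#' @param constants A [dosing_constants()] bundle.
#' @return Estimated AUC in mg*min/mL.
#' @examples
#' p <- list(sex = "M", age = 64, weight_kg = 70, height_cm = 175,
#'           scr_umol_l = 95)
#' predicted_auc(600, adjusted_cg(p))
#' @export
predicted_auc <- function(administered_dose, estimate,
                          constants = dosing_constants()) {
  crcl <- if (inherits(estimate, "renal_estimate")) estimate$crcl else estimate
  if (administered_dose < 0) stop("dose must be non-negative", call. = FALSE)
  administered_dose / (crcl + constants$calvert_offset)
}

#' Counterfactual AUC of a dosing method
#'
#' The exposure that would have resulted had this method dosed the patient:
#' the method's (rounded) Calvert dose divided by the patient's measured
#' carboplatin clearance.
#'
#' @param target_auc Target AUC in mg*min/mL.
#' @param estimate A `renal_estimate`.
#' @param cl_measured Measured individual carboplatin clearance in mL/min
#'   (MAP estimate or simulation truth).
#' @param constants A [dosing_constants()] bundle.
#' @param increment Dose-rounding increment in mg; `NULL` disables rounding.
#' @return AUC in mg*min/mL.
#' @export
counterfactual_auc <- function(target_auc, estimate, cl_measured,
                               constants = dosing_constants(),
                               increment = 50) {
  if (cl_measured <= 0) stop("measured clearance must be positive", call. = FALSE)
  dose <- calvert_dose(target_auc, estimate, constants)
  if (!is.null(increment)) dose <- round_dose(dose, increment)
  dose / cl_measured
}

#' Mean and mean absolute percentage prediction error
#'
#' `MPE = mean(pe)`, `MAPE = mean(|pe|)`, with 95% Student-t confidence
#' intervals on each series (NA when n < 2).
#'
#' @param pe_values Percentage errors, `(estimate - reference)/reference * 100`.
#' @param conf Confidence level, default 0.95.
#' @return List with `n`, `mpe`, `mpe_ci`, `mape`, `mape_ci`.
#' @examples
#' mpe_mape(c(10, -10))
#' @export
mpe_mape <- function(pe_values, conf = 0.95) {
  n <- length(pe_values)
  if (n < 1) stop("at least one prediction error is required", call. = FALSE)
  ci <- function(x) {
    if (n < 2) return(c(NA_real_, NA_real_))
    half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(x) / sqrt(n)
    mean(x) + c(-half, half)
  }
  list(n = n, mpe = mean(pe_values), mpe_ci = ci(pe_values),
       mape = mean(abs(pe_values)), mape_ci = ci(abs(pe_values)))
}

#' Required sample size for a mean-difference test
#'
#' Normal-approximation sample size
#' `n = c (z_{1-alpha/2} + z_power)^2 (sd/delta)^2`, rounded up, with
#' `c = 1` for a one-sample and `c = 2` for a two-sample design.
#'
#' @param delta Difference to detect, in AUC units (mg*min/mL).
#' @param sd Standard deviation of the outcome, same units.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param design "one_sample" or "two_sample".
#' @return Integer sample size per group.
#' @examples
#' required_sample_size(1.8, 1.2, design = "two_sample") # 7 per group
#' @export
required_sample_size <- function(delta, sd, alpha = 0.05, power = 0.80,
                                 design = c("two_sample", "one_sample")) {
  design <- match.arg(design)
  if (delta <= 0 || sd <= 0) stop("delta and sd must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (power <= alpha || power >= 1) {
    stop("power must exceed alpha and be below 1", call. = FALSE)
  }
  cc <- if (design == "two_sample") 2 else 1
  n <- cc * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 * (sd / delta)^2
  max(1L, as.integer(ceiling(n)))
}

#' Evaluate every dosing method on a cohort
#'
#' Builds the method-by-stratum performance grid. Every patient is assumed
#' dosed by the adjusted Cockcroft-Gault algorithm (the study design); the
#' measured clearance per patient comes from MAP fits or from the
#' simulation truth. For the adjusted algorithm the evaluated exposure is
#' the actual AUC (administered dose / measured clearance). For comparator
#' methods it is, by default, the counterfactual AUC (the method's rounded
#' Calvert dose / measured clearance); `auc_mode = "predicted"` instead
#' divides the administered dose by the method's Calvert clearance.
#' Prediction errors are taken against the per-patient target AUC.
#' Patients missing a covariate are excluded per method; patients without a
#' usable measured clearance are excluded from all methods, with reasons
#' recorded.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param cl_measured Named numeric vector of measured carboplatin
#'   clearances (mL/min) by patient id -- `fits$cl_hat` from
#'   [fit_cohort()] (use NA for non-converged fits) or
#'   `truth$true_cl_ml_min`.
#' @param methods Character vector of methods, default [renal_methods()].
#' @param constants A [dosing_constants()] bundle.
#' @param coefficients A [formula_coefficients()] registry.
#' @param auc_mode "counterfactual" (default) or "predicted".
#' @param increment Dose-rounding increment in mg; `NULL` disables rounding.
#' @param band Acceptance band on MPE% as a fraction of target
#'   (default 0.15, i.e. mean exposure within 85%--115% of target).
#' @return Data frame of class `stratum_summary`, one row per method and
#'   stratum: `method, stratum, n, mean_auc, auc_lo, auc_hi, mpe, mpe_lo,
#'   mpe_hi, mape, mape_lo, mape_hi, n_excluded, within_band`, with an
#'   `exclusions` attribute listing per-method reasons.
#' @export
evaluate_cohort <- function(cohort, cl_measured, methods = renal_methods(),
                            constants = dosing_constants(),
                            coefficients = formula_coefficients(),
                            auc_mode = c("counterfactual", "predicted"),
                            increment = 50, band = 0.15) {
  auc_mode <- match.arg(auc_mode)
  if (is.null(names(cl_measured))) {
    stop("cl_measured must be a named vector keyed by patient id", call. = FALSE)
  }
  per_patient <- list()
  exclusions <- list()
  for (i in seq_len(nrow(cohort))) {
    p <- as.list(cohort[i, ])
    clm <- if (p$id %in% names(cl_measured)) cl_measured[[p$id]] else NA_real_
    if (is.na(clm)) {
      exclusions[[length(exclusions) + 1L]] <- data.frame(
        id = p$id, method = "all", reason = "no usable measured clearance",
        stringsAsFactors = FALSE)
      next
    }
    acg <- adjusted_cg(p, constants, coefficients)
    dose_acg <- calvert_dose(p$target_auc, acg, constants)
    if (!is.null(increment)) dose_acg <- round_dose(dose_acg, increment)
    auc_actual <- dose_acg / clm
    for (m in methods) {
      if (m == "aCG") {
        auc_est <- auc_actual
      } else {
        est <- tryCatch(estimate_renal(p, m, constants, coefficients),
                        carbopk_missing_covariate = function(e) e)
        if (inherits(est, "condition")) {
          exclusions[[length(exclusions) + 1L]] <- data.frame(
            id = p$id, method = m, reason = conditionMessage(est),
            stringsAsFactors = FALSE)
          next
        }
        auc_est <- if (auc_mode == "counterfactual") {
          counterfactual_auc(p$target_auc, est, clm, constants, increment)
        } else {
          predicted_auc(dose_acg, est, constants)
        }
      }
      per_patient[[length(per_patient) + 1L]] <- data.frame(
        id = p$id, method = m, stratum = p$stratum,
        auc_estimate = auc_est, target_auc = p$target_auc,
        pe_pct = (auc_est - p$target_auc) / p$target_auc * 100,
        stringsAsFactors = FALSE)
    }
  }
  pp <- if (length(per_patient)) do.call(rbind, per_patient) else
    data.frame(id = character(), method = character(), stratum = character(),
               auc_estimate = numeric(), target_auc = numeric(),
               pe_pct = numeric(), stringsAsFactors = FALSE)
  excl <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(id = character(), method = character(), reason = character())
  strata <- unique(cohort$stratum)
  rows <- list()
  for (m in methods) {
    for (st in strata) {
      sub <- pp[pp$method == m & pp$stratum == st, , drop = FALSE]
      n_all <- sum(cohort$stratum == st)
      if (nrow(sub) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, stratum = st, n = 0L, mean_auc = NA_real_,
          auc_lo = NA_real_, auc_hi = NA_real_, mpe = NA_real_,
          mpe_lo = NA_real_, mpe_hi = NA_real_, mape = NA_real_,
          mape_lo = NA_real_, mape_hi = NA_real_, n_excluded = n_all,
          within_band = NA, stringsAsFactors = FALSE)
        next
      }
      stats_pe <- mpe_mape(sub$pe_pct)
      auc_stats <- mpe_mape(sub$auc_estimate) # reuse mean/CI machinery
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, stratum = st, n = nrow(sub),
        mean_auc = auc_stats$mpe, auc_lo = auc_stats$mpe_ci[1],
        auc_hi = auc_stats$mpe_ci[2],
        mpe = stats_pe$mpe, mpe_lo = stats_pe$mpe_ci[1],
        mpe_hi = stats_pe$mpe_ci[2],
        mape = stats_pe$mape, mape_lo = stats_pe$mape_ci[1],
        mape_hi = stats_pe$mape_ci[2],
        n_excluded = n_all - nrow(sub),
        within_band = abs(stats_pe$mpe) <= band * 100,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_patient") <- pp
  attr(out, "exclusions") <- excl
  class(out) <- c("stratum_summary", "data.frame")
  out
}

#' Run the full simulated study
#'
#' Orchestrates the pipeline: generate a synthetic cohort with latent true
#' clearance, dose every patient by the adjusted Cockcroft-Gault algorithm,
#' simulate the sparse sampling design under each patient's true clearance,
#' MAP-fit individual clearance, and evaluate every registered method per
#' BMI stratum. With `use_map = FALSE` the evaluation uses the latent true
#' clearance directly (no sampling or fitting), which isolates the dosing
#' arithmetic from estimation error.
#'
#' @param spec A [cohort_spec()].
#' @param pop_params Population [pk_parameters()] used for simulation and
#'   as the MAP prior centre (each patient's clearance is their latent true
#'   clearance).
#' @param variance A [variance_model()]; its residual sigmas drive the
#'   simulated assay noise and the MAP weighting, its omega the MAP prior.
#' @param constants A [dosing_constants()] bundle.
#' @param coefficients A [formula_coefficients()] registry.
#' @param tinf Infusion duration in min.
#' @param increment Dose-rounding increment in mg; `NULL` disables rounding.
#' @param auc_mode Passed to [evaluate_cohort()].
#' @param use_map MAP-fit the simulated concentrations (default) or use the
#'   latent truth as the measured clearance.
#' @return List with `cohort`, `truth`, `doses`, `fits` (NULL when
#'   `use_map = FALSE`) and `summary`.
#' @examples
#' \donttest{
#' res <- simulate_study(cohort_spec(seed = 7), use_map = FALSE)
#' head(res$summary)
#' }
#' @export
simulate_study <- function(spec, pop_params = pk_parameters(),
                           variance = variance_model(),
                           constants = dosing_constants(),
                           coefficients = formula_coefficients(),
                           tinf = 30, increment = 50,
                           auc_mode = "counterfactual", use_map = TRUE) {
  gen <- generate_cohort(spec, constants, coefficients)
  doses <- dose_cohort(gen$cohort, "aCG", constants, coefficients, increment)
  fits <- NULL
  if (use_map) {
    schedule <- default_schedule(tinf)
    obs_list <- list()
    dvec <- stats::setNames(doses$administered_dose_mg, doses$id)
    for (i in seq_len(nrow(gen$cohort))) {
      id <- gen$cohort$id[i]
      ind <- pop_params
      ind$cl <- gen$truth$true_cl_ml_min[i]
      obs_list[[id]] <- simulate_observations(
        ind, dvec[[id]], schedule, variance, tinf,
        seed = patient_seed(spec$seed + 1L, i), patient_id = id)
    }
    # the MAP prior is centred on the population clearance
    fits <- fit_cohort(obs_list, dvec, pop_params, variance, tinf)
    clm <- stats::setNames(ifelse(fits$converged, fits$cl_hat_ml_min, NA_real_),
                           fits$patient_id)
  } else {
    clm <- stats::setNames(gen$truth$true_cl_ml_min, gen$truth$id)
  }
  summary <- evaluate_cohort(gen$cohort, clm, renal_methods(), constants,
                             coefficients, auc_mode, increment)
  list(cohort = gen$cohort, truth = gen$truth, doses = doses,
       fits = fits, summary = summary)
}

#' Write the method-by-stratum report
#'
#' CSV layout `method,stratum,n,mean_auc,auc_lo,auc_hi,mpe,mpe_lo,mpe_hi,
#' mape,mape_lo,mape_hi,flags`, or a markdown table.
#'
#' @param summary A `stratum_summary` from [evaluate_cohort()].
#' @param path File path.
#' @param format "csv" or "markdown".
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  df <- as.data.frame(summary)
  df$flags <- ifelse(is.na(df$within_band), "",
                     ifelse(df$within_band, "within_band", "outside_band"))
  df$within_band <- NULL
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 4))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, body), path)
  }
  invisible(path)
}
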