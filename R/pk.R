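#' Two-compartment PK parameters
#'
#' Micro-constant parameterisation of the two-compartment model for
#' ultrafilterable carboplatin: clearance `cl` (mL/min), central volume `v1`
#' (mL), inter-compartmental clearance `q` (mL/min) and peripheral volume
#' `v2` (mL). Internal canonical units are mg, mL, min throughout.
#'
#' Defaults: the population clearance 112.4 mL/min; `v1`, `q`, `v2`
#' (20 L, 0.5 L/min, 20 L) are plausible-shape placeholders and explicitly
#' configuration.
#'
#' @param cl,v1,q,v2 Positive parameters as above.
#' @return A list of class `pk_parameters`.
#' @examples
#' pk_parameters()
#' @export
pk_parameters <- function(cl = 112.4, v1 = 20000, q = 500, v2 = 20000) {
  stopifnot(cl > 0, v1 > 0, q > 0, v2 > 0)
  structure(list(cl = cl, v1 = v1, q = q, v2 = v2), class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  mc <- macro_constants(x)
  cat(sprintf("<pk_parameters> CL %.1f mL/min, V1 %.0f mL, Q %.0f mL/min, V2 %.0f mL\n",
              x$cl, x$v1, x$q, x$v2))
  cat(sprintf("  alpha %.3e /min, beta %.3e /min\n", mc$alpha, mc$beta))
  invisible(x)
}

#' Macro disposition constants
#'
#' Hybrid rate constants `alpha > beta > 0` and the central-compartment
#' biexponential coefficients of the unit-bolus response, from
#' `k10 = cl/v1`, `k12 = q/v1`, `k21 = q/v2`.
#'
#' @param params A [pk_parameters()] object.
#' @return List with `alpha`, `beta`, `A`, `B`, `k10`, `k12`, `k21`.
#' @export
macro_constants <- function(params) {
  k10 <- params$cl / params$v1
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  disc <- max(disc, 0)
  alpha <- (s + sqrt(disc)) / 2
  beta <- (s - sqrt(disc)) / 2
  if (alpha - beta < 1e-12 * s) {
    # repeated-root limit: split the double eigenvalue symmetrically by a
    # relative epsilon; the biexponential form then approximates the
    # t*exp(-lambda*t) limit to well below solver tolerance
    eps <- 1e-7 * s
    alpha <- s / 2 + eps
    beta <- s / 2 - eps
  }
  A <- (alpha - k21) / (alpha - beta)
  B <- (k21 - beta) / (alpha - beta)
  list(alpha = alpha, beta = beta, A = A, B = B,
       k10 = k10, k12 = k12, k21 = k21)
}

# (1 - exp(-k t)) / k, stable for small k and defined as t at k = 0
safe_h <- function(k, t) {
  if (k <= 0) return(t)
  -expm1(-k * t) / k
}

#' Concentration under a zero-order infusion
#'
#' Closed-form central-compartment concentration of the two-compartment
#' model under a zero-order infusion of `dose` mg over `tinf` minutes,
#' obtained by superposing the infusion-start response and a negated copy
#' shifted to the infusion end (continuous at `t = tinf` by construction).
#'
#' @param t Time since infusion start, min (vectorised).
#' @param params A [pk_parameters()] object.
#' @param dose Dose in mg.
#' @param tinf Infusion duration in min (default 30).
#' @return Concentration in mg/mL.
#' @examples
#' concentration_2cmt(c(0, 30, 90), pk_parameters(), dose = 600)
#' @export
concentration_2cmt <- function(t, params, dose, tinf = 30) {
  stopifnot(dose > 0, tinf > 0)
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  mc <- macro_constants(params)
  rate <- dose / tinf
  g <- function(tt) {
    mc$A * vapply(tt, function(u) safe_h(mc$alpha, u), 0) +
      mc$B * vapply(tt, function(u) safe_h(mc$beta, u), 0)
  }
  conc <- rate / params$v1 * g(t)
  post <- t > tinf
  if (any(post)) {
    conc[post] <- conc[post] - rate / params$v1 * g(t[post] - tinf)
  }
  conc
}

#' Infinite-time AUC
#'
#' For a linear model the total exposure is `dose / cl` exactly,
#' independent of `v1`, `q`, `v2` and the infusion duration.
#'
#' @param dose Dose in mg.
#' @param params A [pk_parameters()] object.
#' @return AUC in mg*min/mL.
#' @examples
#' auc_inf(600, pk_parameters(cl = 105))
#' @export
auc_inf <- function(dose, params) {
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  dose / params$cl
}

#' Residual and between-subject variance model
#'
#' Log-normal inter-individual variability on clearance (and optionally the
#' central volume) plus a combined proportional/additive residual model.
#'
#' @param omega_cl SD of the log-scale clearance deviation (default 0.2).
#' @param omega_v1 SD of the log-scale central-volume deviation, or `NULL`
#'   to estimate clearance only.
#' @param sigma_prop Proportional residual SD as a fraction (default 0.1).
#' @param sigma_add Additive residual SD in mg/mL (default 0).
#' @return A list of class `variance_model` with the random-effect
#'   covariance matrix `omega`.
#' @export
variance_model <- function(omega_cl = 0.2, omega_v1 = NULL,
                           sigma_prop = 0.1, sigma_add = 0) {
  stopifnot(omega_cl >= 0, sigma_prop >= 0, sigma_add >= 0)
  sds <- c(cl = omega_cl, if (!is.null(omega_v1)) c(v1 = omega_v1))
  omega <- diag(sds^2, nrow = length(sds))
  dimnames(omega) <- list(names(sds), names(sds))
  structure(list(omega = omega, sigma_prop = sigma_prop,
                 sigma_add = sigma_add),
            class = "variance_model")
}

#' Default sparse sampling schedule
#'
#' The study design: one sample before the infusion starts, one at the end
#' of the infusion, and one at 1, 2.5 and 5 hours after the end of the
#' infusion.
#'
#' @param tinf Infusion duration in min.
#' @return Data frame with `time` (min since infusion start) and
#'   `is_predose`.
#' @export
default_schedule <- function(tinf = 30) {
  data.frame(time = c(0, tinf, tinf + 60, tinf + 150, tinf + 300),
             is_predose = c(TRUE, FALSE, FALSE, FALSE, FALSE))
}

#' Simulate sparse concentration observations
#'
#' Model predictions at the scheduled times with combined
#' proportional/additive residual noise; the pre-dose sample of the first
#' cycle has true concentration zero. Negative noisy draws are truncated at
#' zero and counted in the `n_truncated` attribute.
#'
#' @param params Individual [pk_parameters()].
#' @param dose Dose in mg.
#' @param schedule Data frame with `time` and `is_predose`
#'   (see [default_schedule()]).
#' @param variance A [variance_model()] (only the residual sigmas are used).
#' @param tinf Infusion duration in min.
#' @param seed Optional seed for the residual draws.
#' @param patient_id Identifier copied onto the observations.
#' @return Data frame of class `conc_observations` with `patient_id`,
#'   `time`, `conc` (mg/mL) and `is_predose`.
#' @export
simulate_observations <- function(params, dose, schedule = default_schedule(tinf),
                                  variance = variance_model(), tinf = 30,
                                  seed = NULL, patient_id = "P001") {
  stopifnot(nrow(schedule) >= 1)
  if (!is.null(seed)) set.seed(seed)
  truth <- ifelse(schedule$is_predose, 0,
                  concentration_2cmt(schedule$time, params, dose, tinf))
  n <- length(truth)
  eps_p <- if (variance$sigma_prop > 0) stats::rnorm(n, 0, variance$sigma_prop) else numeric(n)
  eps_a <- if (variance$sigma_add > 0) stats::rnorm(n, 0, variance$sigma_add) else numeric(n)
  conc <- truth * (1 + eps_p) + eps_a
  n_trunc <- sum(conc < 0)
  conc[conc < 0] <- 0
  out <- data.frame(patient_id = patient_id, time = schedule$time,
                    conc = conc, is_predose = schedule$is_predose,
                    stringsAsFactors = FALSE)
  attr(out, "n_truncated") <- n_trunc
  class(out) <- c("conc_observations", "data.frame")
  out
}

#' Read a concentration table
#'
#' Concentration CSV `patient_id,time_min,conc,unit` with unit one of
#' mg/mL, ug/mL or mg/L; concentrations are normalised to the internal
#' mg/mL.
#'
#' @param path File path.
#' @return Data frame with `patient_id`, `time`, `conc` (mg/mL),
#'   `is_predose` (time 0 heuristically pre-dose only if conc is 0).
#' @export
read_concentrations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_min", "conc", "unit")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("concentration file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scale <- c("mg/mL" = 1, "ug/mL" = 1e-3, "µg/mL" = 1e-3, "mg/L" = 1e-3)
  if (!all(df$unit %in% names(scale))) {
    stop("unknown concentration unit: ",
         paste(setdiff(df$unit, names(scale)), collapse = ", "), call. = FALSE)
  }
  data.frame(patient_id = df$patient_id, time = df$time_min,
             conc = df$conc * unname(scale[df$unit]),
             is_predose = df$time_min <= 0 & df$conc == 0,
             stringsAsFactors = FALSE)
}
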