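test_that("infusion profile starts at zero and is continuous at the end of infusion", {
  p <- pk_parameters()
  expect_equal(concentration_2cmt(0, p, 600, 30), 0)
  for (tinf in c(15, 30, 60)) {
    c_end <- concentration_2cmt(tinf, p, 600, tinf)
    c_just_after <- concentration_2cmt(tinf + 1e-7, p, 600, tinf)
    expect_equal(c_just_after / c_end, 1, tolerance = 1e-8)
  }
})

test_that("closed form matches an independent stiff-ODE integration", {
  skip_if_not_installed("deSolve")
  p <- pk_parameters(cl = 112.4, v1 = 20000, q = 500, v2 = 20000)
  dose <- 600; tinf <- 30
  rhs <- function(t, y, parms) {
    r0 <- if (t <= tinf) dose / tinf else 0
    list(c(r0 - (p$cl / p$v1) * y[1] - (p$q / p$v1) * y[1] + (p$q / p$v2) * y[2],
           (p$q / p$v1) * y[1] - (p$q / p$v2) * y[2]))
  }
  tt <- c(30, 90, 180, 330)
  sol <- deSolve::ode(c(0, 0), c(0, tt), rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  ode_conc <- sol[-1, 2] / p$v1
  expect_equal(concentration_2cmt(tt, p, dose, tinf), as.numeric(ode_conc),
               tolerance = 1e-6)
})

test_that("mass balance holds against the ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- pk_parameters()
  dose <- 600; tinf <- 30
  for (T_end in c(20, 100, 500)) {
    auc_T <- integrate(function(t) concentration_2cmt(t, p, dose, tinf),
                       0, T_end, rel.tol = 1e-10)$value
    rhs <- function(t, y, parms) {
      r0 <- if (t <= tinf) dose / tinf else 0
      list(c(r0 - (p$cl / p$v1) * y[1] - (p$q / p$v1) * y[1] + (p$q / p$v2) * y[2],
             (p$q / p$v1) * y[1] - (p$q / p$v2) * y[2]))
    }
    sol <- deSolve::ode(c(0, 0), c(0, T_end), rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
    remaining <- sum(sol[2, 2:3])
    infused <- dose * min(T_end, tinf) / tinf
    expect_equal(p$cl * auc_T + remaining, infused, tolerance = 1e-5 * dose)
  }
})

test_that("total AUC equals dose over clearance, independent of distribution parameters", {
  p <- pk_parameters(cl = 105)
  expect_equal(auc_inf(600, p), 5.714286, tolerance = 1e-6)
  expect_equal(auc_inf(0, p), 0)
  # quadrature of the profile agrees to 0.1%
  q <- integrate(function(t) concentration_2cmt(t, p, 600, 30), 0, Inf,
                 rel.tol = 1e-9)$value
  expect_equal(q, auc_inf(600, p), tolerance = 1e-3)
  # invariance in v1, q, v2
  for (i in 1:5) {
    alt <- pk_parameters(cl = 105, v1 = runif(1, 5e3, 5e4),
                         q = runif(1, 50, 2000), v2 = runif(1, 5e3, 5e4))
    expect_equal(auc_inf(600, alt), auc_inf(600, p), tolerance = 1e-12)
  }
})

test_that("concentration is linear in dose (superposition)", {
  p <- pk_parameters()
  tt <- c(10, 30, 120, 400)
  expect_equal(concentration_2cmt(tt, p, 1200, 30),
               2 * concentration_2cmt(tt, p, 600, 30), tolerance = 1e-12)
})

test_that("with vanishing inter-compartmental clearance the profile is one-compartmental", {
  cl <- 112.4; v1 <- 20000
  p <- pk_parameters(cl = cl, v1 = v1, q = 1e-9, v2 = 20000)
  k <- cl / v1; tinf <- 30; rate <- 600 / tinf
  one_cmt <- function(t) {
    ifelse(t <= tinf,
           rate / (k * v1) * (1 - exp(-k * t)),
           rate / (k * v1) * (1 - exp(-k * tinf)) * exp(-k * (t - tinf)))
  }
  tt <- c(5, 30, 90, 300)
  expect_equal(concentration_2cmt(tt, p, 600, tinf), one_cmt(tt),
               tolerance = 1e-6)
})

test_that("repeated-root parameterisations evaluate finitely and continuously", {
  # choose parameters with (k10+k12+k21)^2 == 4 k10 k21 (double eigenvalue)
  v1 <- 10000; v2 <- 10000
  # k10 = k12 = k21 = k gives s = 3k, disc = 9k^2 - 4k^2 > 0; force equality:
  # with k12 -> 0 and k10 = k21 the discriminant vanishes
  p <- pk_parameters(cl = 100, v1 = v1, q = 100 * v2 / v1, v2 = v2)
  mc <- macro_constants(p)
  tt <- seq(0, 300, by = 10)
  conc <- concentration_2cmt(tt, p, 600, 30)
  expect_true(all(is.finite(conc)))
  expect_true(all(conc >= 0))
})

test_that("the default schedule encodes the study's sparse sampling design", {
  sch <- default_schedule(30)
  expect_equal(sch$time, c(0, 30, 90, 180, 330))
  expect_equal(sch$is_predose, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("simulated observations: noise-free limit, predose zero, determinism", {
  p <- pk_parameters()
  obs <- simulate_observations(p, 600, variance = variance_model(sigma_prop = 0),
                               seed = 1)
  expect_equal(obs$conc[1], 0)
  expect_equal(obs$conc[-1],
               concentration_2cmt(obs$time[-1], p, 600, 30), tolerance = 1e-12)
  a <- simulate_observations(p, 600, seed = 42)
  b <- simulate_observations(p, 600, seed = 42)
  expect_identical(a, b)
})

test_that("residual noise reproduces the configured proportional CV", {
  p <- pk_parameters()
  sch <- data.frame(time = rep(90, 1e4), is_predose = FALSE)
  obs <- simulate_observations(p, 600, sch, variance_model(sigma_prop = 0.1),
                               seed = 7)
  cv <- sd(obs$conc) / mean(obs$conc)
  expect_equal(cv, 0.1, tolerance = 0.02)
  expect_equal(attr(obs, "n_truncated"), 0)
})

test_that("concentration files are normalised to mg/mL", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,time_min,conc,unit",
               "P001,0,0,mg/mL",
               "P001,30,21.5,ug/mL",
               "P001,90,13.0,mg/L"), path)
  df <- read_concentrations(path)
  expect_equal(df$conc, c(0, 0.0215, 0.0130), tolerance = 1e-12)
  expect_true(df$is_predose[1])
  writeLines(c("patient_id,time_min,conc,unit", "P001,0,1,furlongs"), path)
  expect_error(read_concentrations(path), "unit")
})
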