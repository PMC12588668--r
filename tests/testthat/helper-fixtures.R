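# shared fixtures built in code

make_patient <- function(id = "P001", sex = "M", age = 60, weight_kg = 70,
                         height_cm = 175, scr_umol_l = 80, cysc_mg_l = 1.2,
                         ucr_mmol_24h = 9.8, target_auc = 6) {
  list(id = id, sex = sex, age = age, weight_kg = weight_kg,
       height_cm = height_cm, scr_umol_l = scr_umol_l,
       cysc_mg_l = cysc_mg_l, ucr_mmol_24h = ucr_mmol_24h,
       target_auc = target_auc)
}

make_cohort_df <- function(patients) {
  do.call(rbind, lapply(patients, function(p) {
    data.frame(id = p$id, sex = p$sex, age = p$age, weight_kg = p$weight_kg,
               height_cm = p$height_cm, scr_umol_l = p$scr_umol_l,
               cysc_mg_l = p$cysc_mg_l, ucr_mmol_24h = p$ucr_mmol_24h,
               target_auc = p$target_auc,
               stratum = bmi_stratum(compute_bmi(p$weight_kg, p$height_cm)),
               stringsAsFactors = FALSE)
  }))
}

# random but valid patients, one seeded stream
random_patients <- function(n, seed, bmi_max = NULL, scr_min = 20) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      h <- round(runif(1, 150, 200), 1)
      w <- round(runif(1, 45, 130), 1)
      bmi <- w / (h / 100)^2
      if (bmi < 15) next
      if (!is.null(bmi_max) && bmi >= bmi_max) next
      break
    }
    out[[i]] <- make_patient(id = sprintf("R%04d", i),
                             sex = sample(c("M", "F"), 1),
                             age = sample(20:90, 1),
                             weight_kg = w, height_cm = h,
                             scr_umol_l = round(runif(1, scr_min, 200)),
                             cysc_mg_l = round(runif(1, 0.6, 2.5), 2),
                             target_auc = sample(c(4, 5, 6), 1))
  }
  out
}
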