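test_that("age bins cover 65-85 without gap or overlap", {
  expect_equal(assign_age_bin(65), "65-69")
  expect_equal(assign_age_bin(69.999), "65-69")
  expect_equal(assign_age_bin(70), "70-74")
  expect_equal(assign_age_bin(72), "70-74")
  expect_equal(assign_age_bin(80), "80-85")
  expect_equal(assign_age_bin(85), "80-85")   # final bin is closed
  expect_error(assign_age_bin(64.9), "outside")
  expect_error(assign_age_bin(85.1), "outside")
  # every age maps to exactly one bin
  ages <- seq(65, 85, by = 0.25)
  expect_false(anyNA(assign_age_bin(ages)))
})

test_that("build_norms summarizes each stratum on both scales", {
  df <- hand_cohort_df(20)
  df$age <- rep(c(66, 72, 77, 83), 5)
  df$sex <- "female"; df$ethnicity <- "korean"
  coh <- cohort_table(df)
  norms <- build_norms(coh, min_n = 3)
  expect_setequal(unique(norms$age_bin),
                  c("65-69", "70-74", "75-79", "80-85"))
  expect_true(all(norms$n == 5))
  expect_false(any(norms$low_n))
  # percentile monotonicity
  expect_true(all(norms$p5 <= norms$p25 & norms$p25 <= norms$p50 &
                    norms$p50 <= norms$p75 & norms$p75 <= norms$p95))

  # stratum means equal independently computed averages
  bin <- assign_age_bin(coh$age)
  for (b in c("65-69", "80-85")) {
    sel <- bin == b
    expected_abs <- mean(coh$vol_hippocampus_mm3[sel])
    expected_rel <- mean(100 * coh$vol_hippocampus_mm3[sel] /
                           coh$icv_mm3[sel])
    row_abs <- norms[norms$age_bin == b & norms$region == "hippocampus" &
                       norms$scale == "absolute", ]
    row_rel <- norms[norms$age_bin == b & norms$region == "hippocampus" &
                       norms$scale == "relative", ]
    expect_equal(row_abs$mean, expected_abs)
    expect_equal(row_rel$mean, expected_rel)
  }

  # a stratum sharing one value has sd 0 and all percentiles equal
  df2 <- df
  df2$icv_mm3 <- 1.5e6
  df2$vol_brain_mm3 <- 0.7 * 1.5e6
  norms2 <- build_norms(cohort_table(df2), min_n = 3)
  row <- norms2[norms2$region == "brain" & norms2$scale == "relative" &
                  norms2$age_bin == "65-69", ]
  expect_equal(row$sd, 0)
  expect_equal(c(row$p5, row$p25, row$p50, row$p75, row$p95),
               rep(70, 5))

  expect_error(build_norms(coh[0, ]), "empty")
})

test_that("every record contributes to exactly one stratum", {
  coh <- generate_cohort(default_specs(), seed = 13)
  norms <- build_norms(coh)
  one <- norms[norms$region == "brain" & norms$scale == "relative", ]
  expect_equal(sum(one$n), nrow(coh))
  # and the same partition holds for every region/scale slice
  counts <- tapply(norms$n, paste(norms$region, norms$scale), sum)
  expect_true(all(counts == nrow(coh)))
})

test_that("norm scale behavior under global volume rescaling", {
  coh <- generate_cohort(default_specs()["korean_male"], seed = 14)
  norms <- build_norms(coh)
  df <- as.data.frame(coh)
  df$icv_mm3 <- df$icv_mm3 * 2
  for (col in region_columns(cohort_regions(coh)))
    df[[col]] <- df[[col]] * 2
  norms2 <- build_norms(cohort_table(df))
  rel1 <- norms[norms$scale == "relative", ]
  rel2 <- norms2[norms2$scale == "relative", ]
  expect_equal(rel2$mean, rel1$mean, tolerance = 1e-12)
  abs1 <- norms[norms$scale == "absolute", ]
  abs2 <- norms2[norms2$scale == "absolute", ]
  expect_equal(abs2$mean, 2 * abs1$mean, tolerance = 1e-12)
})

test_that("default-spec norms match the generator's expectation", {
  specs <- default_specs()
  coh <- generate_cohort(specs, seed = 15)
  norms <- build_norms(coh)
  row <- norms[norms$ethnicity == "korean" & norms$sex == "female" &
                 norms$age_bin == "70-74" & norms$region == "hippocampus" &
                 norms$scale == "relative", ]
  sel <- coh$ethnicity == "korean" & coh$sex == "female" &
    assign_age_bin(coh$age) == "70-74"
  # model-implied mean relative volume at the stratum's mean age
  sp <- specs$korean_female
  rrow <- sp$regions[sp$regions$region == "hippocampus", ]
  f <- sp$apoe_e4_freq
  slope_of <- function(apc, m) apc / 100 * rrow$intercept /
    (1 - apc / 100 * m)
  m_grp <- mean(coh$age[coh$ethnicity == "korean" & coh$sex == "female"]) - 65
  b_mix <- (1 - f) * slope_of(rrow$true_apc, m_grp) +
    f * slope_of(rrow$carrier_apc, m_grp)
  expected <- rrow$intercept + b_mix * (mean(coh$age[sel]) - 65)
  expect_lt(abs(row$mean - expected), 3 * rrow$noise_sd / sqrt(row$n))
})

test_that("zscore_subject standardizes against the matching stratum", {
  df <- hand_cohort_df(20)
  df$age <- rep(c(66, 72, 77, 83), 5)
  df$sex <- "female"; df$ethnicity <- "korean"
  coh <- cohort_table(df)
  norms <- build_norms(coh, min_n = 3)

  rec <- coh[3, , drop = FALSE]   # age 77 -> 75-79
  zs <- zscore_subject(rec, norms)
  expect_setequal(zs$region, cohort_regions(coh))
  # hand computation for one region
  strat <- norms[norms$age_bin == "75-79" & norms$region == "brain" &
                   norms$scale == "relative", ]
  rel <- 100 * rec$vol_brain_mm3 / rec$icv_mm3
  expect_equal(zs$z[zs$region == "brain"], (rel - strat$mean) / strat$sd)

  # subject exactly at the stratum mean scores 0; one sd below scores -1
  rec0 <- rec
  for (reg in cohort_regions(coh)) {
    s <- norms[norms$age_bin == "75-79" & norms$region == reg &
                 norms$scale == "relative", ]
    rec0[[paste0("vol_", reg, "_mm3")]] <- s$mean / 100 * rec0$icv_mm3
  }
  expect_true(all(abs(zscore_subject(rec0, norms)$z) < 1e-12))
  rec1 <- rec0
  s <- norms[norms$age_bin == "75-79" & norms$region == "brain" &
               norms$scale == "relative", ]
  rec1$vol_brain_mm3 <- (s$mean - s$sd) / 100 * rec1$icv_mm3
  expect_equal(zscore_subject(rec1, norms)$z[1], -1, tolerance = 1e-12)

  # degenerate stratum flags undefined; unmatched stratum errors
  rec_m <- rec; rec_m$sex <- "male"
  expect_error(zscore_subject(rec_m, norms), "no matching norm stratum")
  norms0 <- norms
  norms0$sd[norms0$region == "brain" & norms0$age_bin == "75-79" &
              norms0$scale == "relative"] <- 0
  z0 <- zscore_subject(rec, norms0)
  expect_true(z0$undefined[z0$region == "brain"])
  expect_true(is.na(z0$z[z0$region == "brain"]))
})
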