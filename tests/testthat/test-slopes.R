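test_that("relative_volume is the ICV percentage", {
  expect_equal(relative_volume(150000, 1500000), 10)
  expect_equal(relative_volume(0, 1.2e6), 0)
  expect_equal(relative_volume(1.3 * 150000, 1.3 * 1500000), 10)
  expect_error(relative_volume(1000, 0), "positive")
  expect_error(relative_volume(1000, -5), "positive")
})

test_that("fit_group_slope computes APC against the group mean volume", {
  n <- 41
  df <- hand_cohort_df(n)
  df$age <- seq(65, 85, length.out = n)       # uniform ages, mean 75
  df$icv_mm3 <- rep(1.5e6, n)
  rel <- 80 - 0.32 * (df$age - 65)            # mean relative volume 76.8
  df$vol_brain_mm3 <- rel / 100 * df$icv_mm3
  coh <- cohort_table(df, validate = FALSE)
  fit <- fit_group_slope(coh, "brain")
  expect_equal(fit$raw_slope, -0.32, tolerance = 1e-12)
  expect_equal(fit$mean_rel, 76.8, tolerance = 1e-12)
  expect_equal(fit$apc, 100 * (-0.32) / 76.8, tolerance = 1e-12)

  df$vol_brain_mm3 <- 0.10 * df$icv_mm3       # constant relative volume
  expect_equal(fit_group_slope(cohort_table(df, validate = FALSE),
                               "brain")$apc, 0)

  df$age <- rep(70, n)
  expect_error(fit_group_slope(cohort_table(df, validate = FALSE), "brain"),
               "distinct ages")
  expect_error(fit_group_slope(coh[1:2, ], "brain"), "at least 3")
})

test_that("APC is invariant to global rescaling of volumes and ICV", {
  coh <- generate_cohort(one_region_spec(n = 80), seed = 12)
  base <- fit_group_slope(coh, "brain")$apc
  df <- as.data.frame(coh)
  df$icv_mm3 <- df$icv_mm3 * 1.3
  df$vol_brain_mm3 <- df$vol_brain_mm3 * 1.3
  scaled <- cohort_table(df, regions = "brain", validate = FALSE)
  expect_equal(fit_group_slope(scaled, "brain")$apc, base,
               tolerance = 1e-12)
})

test_that("bootstrap CI is deterministic, degenerate-safe and anchored to the plain fit", {
  coh <- generate_cohort(one_region_spec(n = 120), seed = 9)
  a <- bootstrap_slope_ci(coh, "brain", B = 500, seed = 77, group = "g")
  b <- bootstrap_slope_ci(coh, "brain", B = 500, seed = 77, group = "g")
  expect_identical(a[c("slope", "ci_low", "ci_high")],
                   b[c("slope", "ci_low", "ci_high")])
  expect_equal(a$slope, fit_group_slope(coh, "brain")$apc)
  expect_lte(a$ci_low, a$ci_high)
  expect_false(identical(
    a$ci_low,
    bootstrap_slope_ci(coh, "brain", B = 500, seed = 78, group = "g")$ci_low))

  # zero noise: every resampled APC equals the truth, CI width 0
  coh0 <- generate_cohort(one_region_spec(n = 50, apc = -0.7,
                                          noise_sd = 0, apoe_e4_freq = 0),
                          seed = 2)
  est0 <- bootstrap_slope_ci(coh0, "brain", B = 200, seed = 1, group = "g")
  expect_equal(est0$ci_low, -0.7, tolerance = 1e-9)
  expect_equal(est0$ci_high, -0.7, tolerance = 1e-9)
  expect_true(est0$significant)

  expect_warning(bootstrap_slope_ci(coh0, "brain", B = 50, seed = 1),
                 "B < 100")

  # tiny group: degenerate resamples must be redrawn, never kept
  tiny <- coh[1:4, ]
  est_t <- bootstrap_slope_ci(tiny, "brain", B = 300, seed = 5, group = "g")
  expect_gt(est_t$redraws, 0)
  expect_true(is.finite(est_t$ci_low) && is.finite(est_t$ci_high))
})

test_that("CI-overlap comparison reproduces the published decisions", {
  ps <- published_slopes()
  get <- function(eth, sex, region) {
    row <- ps[ps$ethnicity == eth & ps$sex == sex & ps$region == region, ]
    list(group = paste(eth, sex, sep = "_"), region = region, level = 0.95,
         ci_low = row$ci_low, ci_high = row$ci_high)
  }
  brain <- compare_cis(get("caucasian", "female", "brain"),
                       get("korean", "female", "brain"))
  expect_true(brain$significant)
  cing <- compare_cis(get("caucasian", "female", "cingulate"),
                      get("korean", "female", "cingulate"))
  expect_false(cing$significant)

  mk <- function(lo, hi, region = "r", group = "g")
    list(group = group, region = region, level = 0.95,
         ci_low = lo, ci_high = hi)
  expect_false(compare_cis(mk(-1, 0), mk(-1, 0))$significant)
  expect_false(compare_cis(mk(-1, -0.5), mk(-0.5, 0))$significant) # touch
  expect_true(compare_cis(mk(-1, -0.6), mk(-0.5, 0))$significant)
  # symmetry
  expect_equal(compare_cis(mk(-1, -0.6), mk(-0.5, 0))$significant,
               compare_cis(mk(-0.5, 0), mk(-1, -0.6))$significant)
  expect_error(compare_cis(mk(-1, 0, region = "a"), mk(-1, 0, region = "b")),
               "regions")
  bad <- mk(-1, 0); bad$level <- 0.9
  expect_error(compare_cis(mk(-1, 0), bad), "levels")
})

test_that("apoe_effect measures the carrier minus non-carrier slope difference", {
  sp <- one_region_spec(n = 600, apc = -0.624, noise_sd = 0,
                        apoe_e4_freq = 0.3, carrier_apc = -1.234)
  coh <- generate_cohort(sp, seed = 21)
  coh$apoe_carrier[is.na(coh$apoe_carrier)] <- FALSE
  eff <- apoe_effect(coh, "brain", B = 200, seed = 1, group = "g")
  expect_equal(eff$effect, -1.234 - (-0.624), tolerance = 1e-9)
  expect_true(eff$significant)

  # null case: identical true APCs give an effect CI containing 0
  sp0 <- one_region_spec(n = 400, apc = -0.5, noise_sd = 2,
                         apoe_e4_freq = 0.3, carrier_apc = -0.5)
  coh0 <- generate_cohort(sp0, seed = 22)
  eff0 <- apoe_effect(coh0, "brain", B = 500, seed = 2, group = "g")
  expect_false(eff0$significant)

  # records without APOE status are dropped with a message
  sp1 <- one_region_spec(n = 100, apoe_e4_freq = 0.3)
  sp1$apoe_missing_rate <- 0.2
  coh1 <- generate_cohort(sp1, seed = 23)
  expect_message(apoe_effect(coh1, "brain", B = 150, seed = 1, group = "g"),
                 "without APOE status")

  allnc <- coh0[coh0$apoe_carrier == FALSE, ]
  expect_error(apoe_effect(allnc, "brain", B = 100, seed = 1, group = "g"),
               "empty APOE stratum")
})

test_that("CI width shrinks roughly like 1/sqrt(n)", {
  widths <- function(n) {
    vapply(1:25, function(s) {
      coh <- generate_cohort(one_region_spec(n = n), seed = 3000 + s)
      est <- bootstrap_slope_ci(coh, "brain", B = 400, seed = s,
                                group = "g")
      est$ci_high - est$ci_low
    }, 0)
  }
  ratio <- median(widths(300)) / median(widths(150))
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 0.8)
})

test_that("CI non-overlap is more conservative than the difference CI", {
  # whenever the two group CIs are disjoint, the bootstrap CI of the slope
  # difference must also exclude 0
  set.seed(99)
  hits <- 0
  for (s in 1:12) {
    apc_b <- -0.5 - runif(1, 0, 1.5)
    coh_a <- generate_cohort(one_region_spec(n = 150, apc = -0.5,
                                             noise_sd = 2,
                                             apoe_e4_freq = 0),
                             seed = 5000 + s)
    coh_b <- generate_cohort(one_region_spec(n = 150, apc = apc_b,
                                             noise_sd = 2,
                                             apoe_e4_freq = 0,
                                             ethnicity = "caucasian"),
                             seed = 6000 + s)
    ea <- bootstrap_slope_ci(coh_a, "brain", B = 400, seed = s, group = "a")
    eb <- bootstrap_slope_ci(coh_b, "brain", B = 400, seed = s, group = "b")
    cmp <- compare_cis(ea, eb)
    if (cmp$significant) {
      hits <- hits + 1
      # difference CI via independent within-stratum resampling: tag the
      # two groups as carrier strata of one pooled group
      pooled <- rbind(as.data.frame(coh_a), as.data.frame(coh_b))
      pooled$apoe_genotype <- NULL   # would override the synthetic tags
      pooled$apoe_rs429358 <- NULL
      pooled$apoe_rs7412 <- NULL
      pooled$apoe_carrier <- rep(c(FALSE, TRUE), each = 150)
      pooled$subject_id <- paste0("s", seq_len(nrow(pooled)))
      pooled <- cohort_table(pooled, regions = "brain", validate = FALSE)
      eff <- apoe_effect(pooled, "brain", B = 400, seed = s, group = "p")
      expect_true(eff$significant)
    }
  }
  expect_gt(hits, 0)   # the premise must actually occur
})

test_that("cohort-level wrappers tabulate every group and region", {
  coh <- generate_cohort(default_specs(), seed = 30)
  sl <- aging_slopes(coh, B = 150, seed = 1, regions = c("brain", "caudate"))
  expect_equal(nrow(sl), 8)
  expect_setequal(unique(sl$group),
                  c("korean_female", "korean_male", "caucasian_female",
                    "caucasian_male"))
  cmp <- compare_group_slopes(sl)
  expect_equal(nrow(cmp), 12)   # 6 pairs x 2 regions
  ae <- suppressMessages(apoe_effects(coh, B = 150, seed = 1,
                                      regions = "brain"))
  expect_equal(nrow(ae), 4)
  expect_equal(ae$effect, ae$carrier_apc - ae$noncarrier_apc)
})
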