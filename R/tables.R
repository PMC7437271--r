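# Published summary tables used as generator parameters and as printed
# inputs for the CI-overlap logic. Values are data, shipped in code so the
# package has no runtime dependency on external files.

REGION_ORDER <- c("brain", "frontal", "temporal", "parietal", "occipital",
                  "cingulate", "insular", "ventricle", "thalamus", "putamen",
                  "hippocampus", "caudate", "amygdala", "pallidus",
                  "accumbens")

#' Published per-group aging slopes and 95% bootstrap CIs
#'
#' Annual-percent-change aging slopes of the 15 composite regions for the
#' four ethnicity-by-sex groups, with their printed 95% bootstrap
#' confidence intervals. These drive the default synthetic-cohort
#' parameters and the confidence-interval overlap checks.
#'
#' @return data.frame with columns `ethnicity`, `sex`, `region`, `slope`,
#'   `ci_low`, `ci_high` (all slopes in %/yr).
#' @export
published_slopes <- function() {
  g <- function(ethnicity, sex, slope, lo, hi) {
    data.frame(ethnicity = ethnicity, sex = sex, region = REGION_ORDER,
               slope = slope, ci_low = lo, ci_high = hi,
               stringsAsFactors = FALSE)
  }
  rbind(
    g("caucasian", "female",
      c(-0.791, -0.664, -0.941, -0.828, -1.114, -0.649, -0.478, 2.187,
        -0.832, -0.550, -1.588, -0.010, -1.697, -0.243, -1.635),
      c(-1.152, -1.018, -1.268, -1.141, -1.541, -1.069, -0.835, 0.549,
        -1.286, -1.058, -2.074, -0.520, -2.375, -0.664, -2.409),
      c(-0.574, -0.342, -0.632, -0.517, -0.722, -0.275, -0.145, 3.741,
        -0.534, 0.008, -1.122, 0.571, -1.078, 0.187, -0.759)),
    g("korean", "female",
      c(-0.408, -0.155, -0.439, -0.207, -0.344, -0.218, 0.025, 4.176,
        -0.210, -0.734, -0.886, -0.144, -0.652, 0.383, -1.465),
      c(-0.486, -0.257, -0.544, -0.315, -0.480, -0.364, -0.105, 3.527,
        -0.381, -0.960, -1.057, -0.322, -0.835, 0.140, -1.784),
      c(-0.329, -0.050, -0.338, -0.098, -0.205, -0.074, 0.162, 4.815,
        -0.023, -0.500, -0.723, 0.036, -0.468, 0.613, -1.147)),
    g("caucasian", "male",
      c(-0.612, -0.491, -0.684, -0.584, -0.615, -0.196, -0.130, 2.869,
        -0.490, -0.496, -1.220, -0.058, -1.046, -0.183, -1.602),
      c(-0.760, -0.741, -0.955, -0.848, -0.903, -0.460, -0.448, 1.935,
        -0.774, -0.835, -1.605, -0.433, -1.558, -0.493, -2.345),
      c(-0.457, -0.245, -0.433, -0.315, -0.309, 0.059, 0.177, 3.904,
        -0.207, -0.136, -0.825, 0.351, -0.531, 0.149, -0.932)),
    g("korean", "male",
      c(-0.513, -0.323, -0.570, -0.349, -0.659, -0.347, -0.048, 2.796,
        -0.406, -0.714, -0.977, -0.236, -0.918, 0.236, -1.137),
      c(-0.598, -0.422, -0.691, -0.473, -0.820, -0.515, -0.203, 2.181,
        -0.605, -0.976, -1.193, -0.476, -1.159, -0.089, -1.502),
      c(-0.428, -0.221, -0.456, -0.222, -0.496, -0.182, 0.110, 3.427,
        -0.205, -0.441, -0.761, 0.003, -0.683, 0.575, -0.772)))
}

#' Published APOE e4 carrier / non-carrier aging slopes (women)
#'
#' Aging slopes of the two female groups stratified by APOE epsilon-4
#' carrier status, with printed 95% bootstrap CIs. Carrier slopes provide
#' the default carrier-specific annual percent changes for the female
#' synthetic groups.
#'
#' @return data.frame with columns `ethnicity`, `sex`, `carrier` (logical),
#'   `region`, `slope`, `ci_low`, `ci_high`.
#' @export
published_apoe_slopes <- function() {
  g <- function(ethnicity, carrier, slope, lo, hi) {
    data.frame(ethnicity = ethnicity, sex = "female", carrier = carrier,
               region = REGION_ORDER, slope = slope, ci_low = lo,
               ci_high = hi, stringsAsFactors = FALSE)
  }
  rbind(
    g("caucasian", FALSE,
      c(-0.624, -0.495, -0.713, -0.635, -0.862, -0.528, -0.225, 1.694,
        -0.665, -0.277, -1.383, 0.235, -1.394, 0.041, -1.092),
      c(-0.876, -0.859, -1.043, -0.994, -1.347, -0.963, -0.563, -0.152,
        -0.994, -0.859, -1.906, -0.327, -2.098, -0.458, -2.029),
      c(-0.405, -0.163, -0.385, -0.281, -0.420, -0.124, 0.116, 3.487,
        -0.359, 0.371, -0.880, 0.954, -0.700, 0.512, -0.053)),
    g("caucasian", TRUE,
      c(-1.234, -1.078, -1.446, -1.370, -1.830, -0.960, -1.135, 3.116,
        -1.261, -1.693, -2.104, -0.942, -2.419, -1.263, -2.899),
      c(-2.390, -2.008, -2.199, -2.029, -2.599, -1.964, -2.111, 0.103,
        -2.637, -2.473, -3.304, -2.032, -4.208, -1.965, -4.242),
      c(-0.739, -0.296, -0.708, -0.704, -0.965, -0.153, -0.325, 5.803,
        -0.487, -0.730, -1.037, -0.111, -0.973, -0.599, -1.525)),
    g("korean", FALSE,
      c(-0.387, -0.104, -0.451, -0.203, -0.310, -0.146, 0.005, 4.183,
        -0.213, -0.741, -0.967, -0.055, -0.561, 0.379, -1.515),
      c(-0.481, -0.230, -0.582, -0.334, -0.474, -0.317, -0.161, 3.472,
        -0.416, -0.995, -1.163, -0.271, -0.754, 0.094, -1.906),
      c(-0.290, 0.034, -0.326, -0.064, -0.136, 0.028, 0.176, 4.929,
        0.000, -0.483, -0.753, 0.169, -0.367, 0.662, -1.111)),
    g("korean", TRUE,
      c(-0.573, -0.264, -0.381, -0.270, -0.512, -0.261, 0.277, 4.360,
        -0.465, -0.602, -0.636, -0.288, -0.700, 0.343, -1.364),
      c(-0.771, -0.555, -0.632, -0.598, -0.870, -0.637, -0.054, 2.144,
        -0.959, -1.248, -1.055, -0.777, -1.110, -0.381, -2.178),
      c(-0.376, -0.006, -0.101, 0.057, -0.129, 0.094, 0.594, 6.486,
        0.076, 0.052, -0.227, 0.140, -0.145, 0.998, -0.576)))
}

#' Published cohort demographics
#'
#' Group sizes, age, MMSE and education means/SDs, APOE-genotyped counts
#' and epsilon-4 carrier percentages of the four ethnicity-by-sex groups.
#'
#' @return data.frame, one row per group.
#' @export
published_demographics <- function() {
  data.frame(
    ethnicity = c("korean", "korean", "caucasian", "caucasian"),
    sex = c("female", "male", "female", "male"),
    n = c(638L, 370L, 163L, 179L),
    age_mean = c(72.1, 74.3, 74.5, 75.6),
    age_sd = c(4.3, 5.0, 4.8, 5.2),
    mmse_mean = c(27.1, 27.8, 29.2, 29.0),
    mmse_sd = c(2.2, 1.6, 1.1, 1.1),
    education_mean = c(8.4, 12.2, 15.5, 17.0),
    education_sd = c(4.1, 4.0, 2.6, 2.6),
    apoe_n = c(534L, 296L, 161L, 179L),
    apoe_e4_freq = c(0.170, 0.176, 0.292, 0.246),
    stringsAsFactors = FALSE)
}

# Baseline relative volumes (% of ICV at age 65) for the Korean groups,
# chosen once from typical FreeSurfer values in healthy elderly; not
# printed in the source tables. Caucasian baselines apply a modest ethnic
# scaling consistent with the reported direction of group differences
# (smaller cortex, larger ventricle/caudate, equal putamen).
baseline_intercepts <- function() {
  c(brain = 70, frontal = 10.5, temporal = 7.5, parietal = 6.5,
    occipital = 3.0, cingulate = 1.6, insular = 0.85, ventricle = 2.0,
    thalamus = 0.85, putamen = 0.55, hippocampus = 0.50, caudate = 0.45,
    amygdala = 0.20, pallidus = 0.20, accumbens = 0.06)
}

caucasian_intercept_scale <- function() {
  s <- rep(0.95, length(REGION_ORDER))
  names(s) <- REGION_ORDER
  s["ventricle"] <- 1.10
  s["caudate"] <- 1.05
  s["putamen"] <- 1.00
  s
}
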