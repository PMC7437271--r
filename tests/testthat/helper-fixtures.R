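# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# aseg.stats text with the given structures, eTIV and header measures.
aseg_fixture <- function(structures = c("Left-Hippocampus" = 4000,
                                        "Right-Hippocampus" = 4100),
                         etiv = 1500000,
                         measures = c(BrainSegVolNotVent = 1050000)) {
  path <- tempfile(fileext = ".stats")
  write_aseg_stats(structures, etiv, measures, path)
  readLines(path)
}

aparc_fixture <- function(volumes, hemisphere = "lh") {
  path <- tempfile(fileext = ".stats")
  write_aparc_stats(volumes, hemisphere, path)
  readLines(path)
}

# Full synthetic subject: every mapped structure gets a deterministic
# volume; returns the parsed pieces plus the per-structure values.
fs_subject_fixture <- function(scale = 1) {
  rs <- default_region_set()
  map <- rs$mapping
  aparc_names <- unique(map$name[map$source == "aparc"])
  lh <- setNames(100 * seq_along(aparc_names) * scale, aparc_names)
  rh <- lh + 7 * scale
  aseg_names <- map$name[map$source == "aseg"]
  aseg_vols <- setNames(500 * seq_along(aseg_names) * scale, aseg_names)
  measures <- c(BrainSegVolNotVent = 1050000 * scale)
  list(
    aseg = parse_aseg_stats(aseg_fixture(aseg_vols, 1500000 * scale,
                                         measures)),
    lh = parse_aparc_stats(aparc_fixture(lh, "lh"), "lh"),
    rh = parse_aparc_stats(aparc_fixture(rh, "rh"), "rh"),
    lh_vols = lh, rh_vols = rh, aseg_vols = aseg_vols,
    regions = rs)
}

# Minimal hand-built cohort data.frame over the full 15-region set;
# relative volumes are a fixed profile scaled slightly per subject.
hand_cohort_df <- function(n = 6, seed = 99) {
  set.seed(seed)
  regions <- default_region_set()$regions
  base_rel <- c(70, 10.5, 7.5, 6.5, 3, 1.6, 0.85, 2, 0.85, 0.55, 0.5,
                0.45, 0.2, 0.2, 0.06) / 100
  icv <- 1.4e6 + 2e5 * runif(n)   # not collinear with the age sequence
  df <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                   age = seq(66, 84, length.out = n),
                   sex = rep(c("female", "male"), length.out = n),
                   ethnicity = rep(c("korean", "caucasian"),
                                   each = ceiling(n / 2))[seq_len(n)],
                   education = round(runif(n, 6, 18)),
                   icv_mm3 = icv,
                   stringsAsFactors = FALSE)
  for (k in seq_along(regions))
    df[[paste0("vol_", regions[k], "_mm3")]] <-
      base_rel[k] * icv * (1 + 0.02 * seq_len(n) / n)
  df
}

# Add the neuropsychological columns needed by the screen.
with_neuropsych <- function(df, mmse = 27, z = 0) {
  df$mmse <- rep_len(mmse, nrow(df))
  for (d in c("attention", "language", "visuospatial", "memory",
              "executive"))
    df[[paste0("z_", d)]] <- rep_len(z, nrow(df))
  df
}

# Exact-moment sample: n values with the requested mean and sd (sd with
# the n-1 denominator), for expanding cell summaries into subject rows.
expand_cell <- function(n, mean, sd) {
  z <- seq_len(n)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}

# One-region spec for fast simulation-heavy tests.
one_region_spec <- function(n = 200, apc = -0.5, noise_sd = 3,
                            intercept = 70, apoe_e4_freq = 0.2,
                            carrier_apc = NA_real_,
                            ethnicity = "korean", sex = "female") {
  group_spec(ethnicity = ethnicity, sex = sex, n = n,
             age_mean = 72, age_sd = 4.5,
             education_mean = 10, education_sd = 4,
             apoe_e4_freq = apoe_e4_freq, icv_mean = 1.4e6, icv_sd = 1.2e5,
             regions = data.frame(region = "brain", intercept = intercept,
                                  true_apc = apc, noise_sd = noise_sd,
                                  carrier_apc = carrier_apc))
}
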