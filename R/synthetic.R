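# Synthetic cohorts with the statistical structure the analysis assumes:
# truncated-normal ages, lognormal ICV, Bernoulli APOE-e4 carriage, and
# relative volumes linear in age with Gaussian noise.

#' Construct a synthetic-group specification
#'
#' A `group_spec` states the world one ethnicity-by-sex group is drawn
#' from: demographics, APOE epsilon-4 carrier frequency, ICV distribution,
#' and for every region a baseline relative volume (% of ICV at age 65), a
#' true aging slope (annual percent change, %/yr), a Gaussian noise SD on
#' the relative-volume scale (% of ICV) and, optionally, a separate
#' carrier-specific aging slope.
#'
#' @param ethnicity,sex Group labels.
#' @param n Number of subjects.
#' @param age_mean,age_sd Age distribution in years (truncated to
#'   `age_bounds`).
#' @param education_mean,education_sd Education in years (truncated at 0).
#' @param mmse_mean,mmse_sd MMSE distribution (integerized, truncated to
#'   `[mmse_floor, 30]`).
#' @param apoe_e4_freq P(at least one e4 allele).
#' @param apoe_missing_rate Fraction of subjects whose APOE genotype is
#'   unobserved (masked, as in real genotyping shortfall).
#' @param icv_mean,icv_sd ICV distribution in mm^3 (lognormal).
#' @param regions data.frame with columns `region`, `intercept`,
#'   `true_apc`, `noise_sd` and optionally `carrier_apc` (NA = carriers
#'   share `true_apc`).
#' @param age_bounds Age truncation bounds (default `c(65, 85)`).
#' @param mmse_floor Lower MMSE truncation for a screened cohort
#'   (default 19; use 0 to generate unscreened subjects).
#' @return A `group_spec` object.
#' @export
group_spec <- function(ethnicity, sex, n, age_mean, age_sd,
                       education_mean, education_sd,
                       mmse_mean = 28, mmse_sd = 1.5,
                       apoe_e4_freq, apoe_missing_rate = 0,
                       icv_mean, icv_sd, regions,
                       age_bounds = c(65, 85), mmse_floor = 19) {
  stopifnot(n >= 0, age_sd >= 0, education_sd >= 0, icv_sd >= 0,
            apoe_e4_freq >= 0, apoe_e4_freq <= 1,
            apoe_missing_rate >= 0, apoe_missing_rate <= 1)
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  need <- c("region", "intercept", "true_apc", "noise_sd")
  stopifnot(all(need %in% names(regions)))
  if (!("carrier_apc" %in% names(regions))) regions$carrier_apc <- NA_real_
  vals <- unlist(regions[c("intercept", "true_apc", "noise_sd")])
  if (any(!is.finite(vals)))
    stop("non-finite region parameter in group_spec")
  if (any(regions$intercept < 0) || any(regions$noise_sd < 0))
    stop("intercepts and noise_sd must be non-negative")
  structure(list(ethnicity = ethnicity, sex = sex, n = as.integer(n),
                 age_mean = age_mean, age_sd = age_sd,
                 education_mean = education_mean,
                 education_sd = education_sd,
                 mmse_mean = mmse_mean, mmse_sd = mmse_sd,
                 apoe_e4_freq = apoe_e4_freq,
                 apoe_missing_rate = apoe_missing_rate,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 regions = regions, age_bounds = age_bounds,
                 mmse_floor = mmse_floor),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec> %s %s: n=%d, age %.1f±%.1f, e4 freq %.3f\n",
              x$ethnicity, x$sex, x$n, x$age_mean, x$age_sd,
              x$apoe_e4_freq))
  invisible(x)
}

# Moments of a normal truncated to [lo, hi].
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Deterministic 31-bit substream seed from a master seed and a string key,
# so per-group / per-(group, region) streams are order-independent.
substream_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 48271) %% 2147483647)
}

#' Default synthetic-group specifications
#'
#' The four ethnicity-by-sex groups parameterized from the published
#' summary tables: group sizes, age/education/MMSE means and SDs, APOE
#' epsilon-4 carrier frequencies and genotyped fractions from the
#' demographics table; per-region true aging slopes from the published
#' slope table (with carrier-specific slopes for the female groups from the
#' APOE-stratified table); per-region noise SDs calibrated so that
#' bootstrap CI widths at the published group sizes roughly match the
#' printed CI widths (delta-method inversion of the printed half-width).
#'
#' @param regions Region names (default: the 15 shipped regions).
#' @return List of four `group_spec` objects, named
#'   `<ethnicity>_<sex>`.
#' @export
#' @examples
#' specs <- default_specs()
#' specs$korean_female$n
default_specs <- function(regions = REGION_ORDER) {
  demo <- published_demographics()
  slopes <- published_slopes()
  apoe <- published_apoe_slopes()
  base <- baseline_intercepts()[regions]
  cauc_scale <- caucasian_intercept_scale()[regions]

  specs <- list()
  for (i in seq_len(nrow(demo))) {
    eth <- demo$ethnicity[i]; sx <- demo$sex[i]
    sl <- slopes[slopes$ethnicity == eth & slopes$sex == sx, ]
    sl <- sl[match(regions, sl$region), ]
    icpt <- if (eth == "caucasian") base * cauc_scale else base

    # Invert the printed CI half-width into a residual SD:
    # halfwidth ~ 1.96 * SE(APC); SE(APC) = 100 * SE(b) / mean_rel;
    # SE(b) = sigma / (sd_age * sqrt(n)).
    tm <- truncnorm_moments(demo$age_mean[i], demo$age_sd[i], 65, 85)
    mean_rel <- icpt / (1 - sl$slope / 100 * (tm$mean - 65))
    halfwidth <- (sl$ci_high - sl$ci_low) / 2
    noise_sd <- halfwidth / 1.96 / 100 * mean_rel * tm$sd * sqrt(demo$n[i])

    carrier_apc <- rep(NA_real_, length(regions))
    if (sx == "female") {
      ca <- apoe[apoe$ethnicity == eth & apoe$carrier, ]
      carrier_apc <- ca$slope[match(regions, ca$region)]
    }

    specs[[paste(eth, sx, sep = "_")]] <- group_spec(
      ethnicity = eth, sex = sx, n = demo$n[i],
      age_mean = demo$age_mean[i], age_sd = demo$age_sd[i],
      education_mean = demo$education_mean[i],
      education_sd = demo$education_sd[i],
      mmse_mean = demo$mmse_mean[i], mmse_sd = demo$mmse_sd[i],
      apoe_e4_freq = demo$apoe_e4_freq[i],
      apoe_missing_rate = 1 - demo$apoe_n[i] / demo$n[i],
      icv_mean = if (eth == "korean") {
        if (sx == "female") 1.40e6 else 1.55e6
      } else {
        if (sx == "female") 1.45e6 else 1.65e6
      },
      icv_sd = if (sx == "female") 1.2e5 else 1.4e5,
      regions = data.frame(region = regions, intercept = unname(icpt),
                           true_apc = sl$slope,
                           noise_sd = unname(noise_sd),
                           carrier_apc = carrier_apc,
                           stringsAsFactors = FALSE))
  }
  specs
}

#' Generate a synthetic cohort
#'
#' Draws one cohort table from a list of [group_spec()]s. Ages are
#' truncated-normal, ICV lognormal, carrier status Bernoulli, and each
#' region's relative volume follows a line in age with Gaussian noise. The
#' slope of the generating line is anchored so that `true_apc` is exactly
#' the annual percent change measured by [fit_group_slope()] (raw slope
#' divided by the group-mean relative volume): within each carrier stratum
#' with annual percent change `a` and empirical mean age `m`, the raw slope
#' is `a/100 * intercept / (1 - a/100 * (m - 65))` % of ICV per year.
#'
#' Relative volumes are floored at 0.001 (% of ICV) so absolute volumes
#' respect the non-negativity invariant; with the default noise this
#' touches only extreme ventricle draws.
#'
#' @param specs A `group_spec` or list of them.
#' @param seed Master integer seed; each group draws from a deterministic
#'   substream keyed by its labels, so results do not depend on list order.
#' @return A `cohort` table with demographics, APOE columns (SNP genotypes
#'   and derived genotype/carrier; masked to NA for the unobserved
#'   fraction), MMSE, the five domain z-scores, ICV and absolute regional
#'   volumes.
#' @export
#' @examples
#' coh <- generate_cohort(default_specs(), seed = 42)
#' nrow(coh)
generate_cohort <- function(specs, seed) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1, is.numeric(seed))
  rows <- lapply(specs, function(sp) generate_group(sp, seed))
  df <- do.call(rbind, c(rows, list(stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  cohort_table(df, regions = specs[[1]]$regions$region,
               provenance = sprintf("synthetic (seed %d)", as.integer(seed)))
}

generate_group <- function(sp, seed) {
  set.seed(substream_seed(seed, paste("group", sp$ethnicity, sp$sex)))
  n <- sp$n
  lo <- sp$age_bounds[1]; hi <- sp$age_bounds[2]
  age <- rtrunc_norm(n, sp$age_mean, sp$age_sd, lo, hi)
  education <- rtrunc_norm(n, sp$education_mean, sp$education_sd, 0, Inf)
  mmse <- as.integer(round(rtrunc_norm(n, sp$mmse_mean, sp$mmse_sd,
                                       sp$mmse_floor, 30)))

  # domain z-scores of a screened cohort: truncated below the -1.5 cut
  zs <- matrix(rtrunc_norm(5 * n, 0, 1, -1.5, Inf), ncol = 5)
  colnames(zs) <- paste0("z_", COGNITIVE_DOMAINS)

  sdlog <- sqrt(log(1 + (sp$icv_sd / sp$icv_mean)^2))
  icv <- stats::rlnorm(n, log(sp$icv_mean) - sdlog^2 / 2, sdlog)

  carrier <- runif(n) < sp$apoe_e4_freq
  observed <- runif(n) >= sp$apoe_missing_rate
  genotype <- ifelse(carrier,
                     ifelse(runif(n) < sp$apoe_e4_freq / 2, "e4/e4", "e3/e4"),
                     ifelse(runif(n) < 0.1, "e2/e3", "e3/e3"))
  snps <- list("e3/e3" = c("TT", "CC"), "e3/e4" = c("CT", "CC"),
               "e4/e4" = c("CC", "CC"), "e2/e3" = c("TT", "CT"))
  rs429358 <- vapply(genotype, function(g) snps[[g]][1], "")
  rs7412 <- vapply(genotype, function(g) snps[[g]][2], "")
  genotype[!observed] <- NA
  rs429358[!observed] <- NA
  rs7412[!observed] <- NA

  vols <- matrix(NA_real_, nrow = n, ncol = nrow(sp$regions))
  colnames(vols) <- region_columns(sp$regions$region)
  for (k in seq_len(nrow(sp$regions))) {
    r <- relative_line(sp$regions[k, ], age, carrier, lo) +
      rnorm(n, 0, sp$regions$noise_sd[k])
    r <- pmax(r, 0.001)
    vols[, k] <- r / 100 * icv
  }

  id <- sprintf("%s_%s_%04d", substr(sp$ethnicity, 1, 3),
                substr(sp$sex, 1, 1), seq_len(n))
  cbind(data.frame(subject_id = id, age = age, sex = sp$sex,
                   ethnicity = sp$ethnicity, education = education,
                   mmse = mmse, stringsAsFactors = FALSE),
        as.data.frame(zs),
        data.frame(apoe_rs429358 = rs429358, apoe_rs7412 = rs7412,
                   apoe_genotype = genotype,
                   apoe_carrier = ifelse(observed, carrier, NA),
                   icv_mm3 = icv, stringsAsFactors = FALSE),
        as.data.frame(vols))
}

# Noise-free relative volume for one region row, anchoring each carrier
# stratum's slope so the measured APC equals the specified one exactly.
relative_line <- function(rrow, age, carrier, base_age) {
  if (is.na(rrow$carrier_apc)) {
    # no carrier effect: one line anchored at the whole-group mean age
    strata <- list(list(sel = rep(TRUE, length(age)), apc = rrow$true_apc))
  } else {
    strata <- list(list(sel = !carrier, apc = rrow$true_apc),
                   list(sel = carrier, apc = rrow$carrier_apc))
  }
  out <- numeric(length(age))
  for (stratum in strata) {
    sel <- stratum$sel
    if (!any(sel)) next
    m <- mean(age[sel])
    b <- stratum$apc / 100 * rrow$intercept /
      (1 - stratum$apc / 100 * (m - base_age))
    out[sel] <- rrow$intercept + b * (age[sel] - base_age)
  }
  out
}

#' Model-implied group-level annual percent change
#'
#' The value [fit_group_slope()] estimates, in expectation, on cohorts
#' drawn from a spec: for a spec without a carrier-specific slope this is
#' exactly `true_apc`; with one, it is the carrier-frequency-weighted
#' mixture slope divided by the implied group-mean relative volume.
#'
#' @param spec A `group_spec`.
#' @param region Region name.
#' @return Annual percent change (%/yr).
#' @export
expected_group_apc <- function(spec, region) {
  rrow <- spec$regions[spec$regions$region == region, ]
  if (nrow(rrow) != 1) stop("unknown region ", region)
  tm <- truncnorm_moments(spec$age_mean, spec$age_sd,
                          spec$age_bounds[1], spec$age_bounds[2])
  m <- tm$mean - spec$age_bounds[1]
  slope_of <- function(apc) apc / 100 * rrow$intercept / (1 - apc / 100 * m)
  f <- spec$apoe_e4_freq
  apc_c <- if (is.na(rrow$carrier_apc)) rrow$true_apc else rrow$carrier_apc
  b <- (1 - f) * slope_of(rrow$true_apc) + f * slope_of(apc_c)
  mean_rel <- rrow$intercept + b * m
  100 * b / mean_rel
}
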