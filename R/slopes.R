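# Group-stratified aging slopes as annual percent change (APC), percentile
# bootstrap CIs, CI-overlap group comparison, and APOE-e4 slope-difference
# effects.

#' Relative volume as a percentage of intracranial volume
#'
#' @param volume Volume in mm^3.
#' @param icv Intracranial volume in mm^3 (> 0).
#' @return `100 * volume / icv`.
#' @export
relative_volume <- function(volume, icv) {
  if (any(!is.finite(icv)) || any(icv <= 0)) stop("icv must be positive")
  100 * volume / icv
}

group_relative <- function(records, region) {
  col <- paste0("vol_", region, "_mm3")
  if (!(col %in% names(records))) stop("unknown region ", region)
  relative_volume(records[[col]], records$icv_mm3)
}

#' Within-group aging slope as annual percent change
#'
#' Ordinary least squares of relative volume (% of ICV) on age within one
#' group. The annual percent change is the raw slope divided by the group
#' mean relative volume, times 100 — percent change per year relative to
#' the structure's own typical size in the group.
#'
#' @param records A `cohort` subset holding one group.
#' @param region Region name.
#' @return List with `apc` (%/yr), `raw_slope` (% of ICV per yr),
#'   `mean_rel` (% of ICV) and `n`.
#' @export
#' @examples
#' coh <- generate_cohort(default_specs()["korean_female"], seed = 7)
#' fit_group_slope(coh, "hippocampus")$apc
fit_group_slope <- function(records, region) {
  age <- records$age
  if (length(age) < 3 || length(unique(age)) < 2)
    stop("need at least 3 records with distinct ages")
  rel <- group_relative(records, region)
  b <- stats::cov(age, rel) / stats::var(age)
  list(apc = 100 * b / mean(rel), raw_slope = b, mean_rel = mean(rel),
       n = length(age))
}

#' Percentile-bootstrap confidence interval for an aging slope
#'
#' Resamples subjects with replacement (resample size = group size),
#' refits the within-group slope, and takes the percentile interval of the
#' bootstrap APC distribution. Each bootstrap APC divides the resampled raw
#' slope by the full-sample mean relative volume — the normalizing constant
#' is a fixed property of the group, so the interval reflects slope
#' uncertainty only (and a zero-noise group yields a zero-width CI). The
#' point estimate is always the full-sample fit. Resamples with fewer than
#' two distinct ages are redrawn (and counted) so exactly `B` estimates
#' enter the interval.
#'
#' @inheritParams fit_group_slope
#' @param B Bootstrap iterations (default 10,000).
#' @param level Confidence level (default 0.95).
#' @param seed Master seed; the actual stream is keyed by
#'   (`group`, `region`) so results are independent of evaluation order.
#' @param group Group label carried into the result (also keys the seed
#'   substream).
#' @return A `slope_estimate`: list with `group`, `region`, `slope` (APC,
#'   %/yr), `ci_low`, `ci_high`, `level`, `n`, `B`, `seed`, `significant`
#'   (CI excludes 0) and `redraws`.
#' @export
bootstrap_slope_ci <- function(records, region, B = 10000, level = 0.95,
                               seed = 1, group = "group") {
  if (B < 100) warning("B < 100 gives unstable percentile intervals")
  full <- fit_group_slope(records, region)
  age <- records$age
  rel <- group_relative(records, region)
  set.seed(substream_seed(seed, paste("boot", group, region)))
  bs <- bootstrap_apcs(age, rel, B)
  ci <- unname(quantile(bs$apc, c((1 - level) / 2, 1 - (1 - level) / 2)))
  structure(list(group = group, region = region, slope = full$apc,
                 raw_slope = full$raw_slope, ci_low = ci[1], ci_high = ci[2],
                 level = level, n = full$n, B = as.integer(B),
                 seed = as.integer(seed),
                 significant = ci[1] > 0 || ci[2] < 0,
                 redraws = bs$redraws),
            class = "slope_estimate")
}

#' @export
print.slope_estimate <- function(x, ...) {
  cat(sprintf("%s / %s: APC %.3f %%/yr, %d%% CI [%.3f, %.3f], n=%d, B=%d%s\n",
              x$group, x$region, x$slope, round(100 * x$level), x$ci_low,
              x$ci_high, x$n, x$B, if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
as.data.frame.slope_estimate <- function(x, ...) {
  data.frame(group = x$group, region = x$region, slope = x$slope,
             ci_low = x$ci_low, ci_high = x$ci_high, level = x$level,
             n = x$n, B = x$B, significant = x$significant,
             stringsAsFactors = FALSE)
}

# Vectorized bootstrap of the APC statistic; chunked to bound memory.
# The denominator is the full-sample mean relative volume: the APC's
# normalizing constant is a property of the group, so only the slope is
# treated as a resampled statistic (this also makes the zero-noise
# degenerate case exact: every resample returns the true APC).
bootstrap_apcs <- function(age, rel, B, chunk = 2000L) {
  n <- length(age)
  denom <- mean(rel)
  apcs <- numeric(B)
  redraws <- 0L
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    idx <- matrix(sample.int(n, n * b, replace = TRUE), nrow = n)
    A <- matrix(age[idx], nrow = n)
    R <- matrix(rel[idx], nrow = n)
    mA <- colMeans(A); mR <- colMeans(R)
    vA <- colMeans(A * A) - mA^2
    bad <- vA <= 0
    while (any(bad)) {           # degenerate resample: redraw
      redraws <- redraws + sum(bad)
      k <- sum(bad)
      idx2 <- matrix(sample.int(n, n * k, replace = TRUE), nrow = n)
      A[, bad] <- age[idx2]
      R[, bad] <- rel[idx2]
      mA <- colMeans(A); mR <- colMeans(R)
      vA <- colMeans(A * A) - mA^2
      bad <- vA <= 0
    }
    slope <- (colMeans(A * R) - mA * mR) / vA
    apcs[done + seq_len(b)] <- 100 * slope / denom
    done <- done + b
  }
  list(apc = apcs, redraws = redraws)
}

#' Compare two slope estimates by confidence-interval overlap
#'
#' Declares a group difference significant if and only if the two
#' confidence intervals are disjoint; touching endpoints count as overlap.
#' Symmetric in its arguments.
#'
#' @param a,b `slope_estimate` objects (or lists with `region`, `level`,
#'   `ci_low`, `ci_high`) for the same region at the same level.
#' @return A `slope_comparison`: list with the two group labels, `region`,
#'   `significant` and the two intervals.
#' @export
#' @examples
#' ps <- published_slopes()
#' fc <- ps[ps$ethnicity == "caucasian" & ps$sex == "female" &
#'          ps$region == "brain", ]
#' fk <- ps[ps$ethnicity == "korean" & ps$sex == "female" &
#'          ps$region == "brain", ]
#' ci <- function(x, g) list(group = g, region = "brain", level = 0.95,
#'                           ci_low = x$ci_low, ci_high = x$ci_high)
#' compare_cis(ci(fc, "caucasian_f"), ci(fk, "korean_f"))$significant
compare_cis <- function(a, b) {
  if (!identical(a$region, b$region))
    stop("cannot compare CIs across regions (", a$region, " vs ", b$region, ")")
  if (!isTRUE(all.equal(a$level, b$level)))
    stop("cannot compare CIs at different levels")
  sig <- max(a$ci_low, b$ci_low) > min(a$ci_high, b$ci_high)
  structure(list(group_a = a$group, group_b = b$group, region = a$region,
                 significant = sig,
                 ci_a = c(a$ci_low, a$ci_high),
                 ci_b = c(b$ci_low, b$ci_high)),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s / %s: [%.3f, %.3f] vs [%.3f, %.3f] -> %s\n",
              x$group_a, x$group_b, x$region, x$ci_a[1], x$ci_a[2],
              x$ci_b[1], x$ci_b[2],
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' APOE epsilon-4 effect on the aging slope
#'
#' The effect is the carrier-stratum APC minus the non-carrier-stratum APC
#' within one group (full sample), with a percentile bootstrap CI in which
#' each iteration resamples carriers and non-carriers independently.
#' Records with unknown carrier status are dropped (count reported via
#' message and in the result).
#'
#' @inheritParams bootstrap_slope_ci
#' @return An `apoe_effect`: list with `group`, `region`, `effect` (%/yr),
#'   `ci_low`, `ci_high`, `level`, `carrier_apc`, `noncarrier_apc`,
#'   `n_carrier`, `n_noncarrier`, `n_dropped`, `B`, `significant`.
#' @export
apoe_effect <- function(records, region, B = 10000, level = 0.95,
                        seed = 1, group = "group") {
  known <- !is.na(records$apoe_carrier)
  n_dropped <- sum(!known)
  if (n_dropped > 0)
    message(n_dropped, " record(s) without APOE status dropped from ",
            group, "/", region)
  records <- records[known, , drop = FALSE]
  carr <- records[records$apoe_carrier == TRUE, , drop = FALSE]
  nonc <- records[records$apoe_carrier == FALSE, , drop = FALSE]
  for (s in list(carr, nonc)) {
    if (nrow(s) == 0) stop("empty APOE stratum in ", group)
    if (length(unique(s$age)) < 3)
      stop("APOE stratum needs >= 3 distinct ages in ", group)
  }

  fit_c <- fit_group_slope(carr, region)
  fit_n <- fit_group_slope(nonc, region)

  set.seed(substream_seed(seed, paste("apoe", group, region)))
  bs_c <- bootstrap_apcs(carr$age, group_relative(carr, region), B)
  bs_n <- bootstrap_apcs(nonc$age, group_relative(nonc, region), B)
  diff <- bs_c$apc - bs_n$apc
  ci <- unname(quantile(diff, c((1 - level) / 2, 1 - (1 - level) / 2)))

  structure(list(group = group, region = region,
                 effect = fit_c$apc - fit_n$apc,
                 ci_low = ci[1], ci_high = ci[2], level = level,
                 carrier_apc = fit_c$apc, noncarrier_apc = fit_n$apc,
                 n_carrier = nrow(carr), n_noncarrier = nrow(nonc),
                 n_dropped = n_dropped, B = as.integer(B),
                 seed = as.integer(seed),
                 significant = ci[1] > 0 || ci[2] < 0),
            class = "apoe_effect")
}

#' @export
print.apoe_effect <- function(x, ...) {
  cat(sprintf("%s / %s: e4 effect %.3f %%/yr, %d%% CI [%.3f, %.3f] (nc=%d, c=%d)%s\n",
              x$group, x$region, x$effect, round(100 * x$level), x$ci_low,
              x$ci_high, x$n_noncarrier, x$n_carrier,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' @export
as.data.frame.apoe_effect <- function(x, ...) {
  data.frame(group = x$group, region = x$region, effect = x$effect,
             ci_low = x$ci_low, ci_high = x$ci_high, level = x$level,
             carrier_apc = x$carrier_apc, noncarrier_apc = x$noncarrier_apc,
             n_carrier = x$n_carrier, n_noncarrier = x$n_noncarrier,
             B = x$B, significant = x$significant, stringsAsFactors = FALSE)
}

cohort_groups <- function(cohort) {
  split(seq_len(nrow(cohort)),
        paste(cohort$ethnicity, cohort$sex, sep = "_"))
}

#' Aging slopes for every group and region of a cohort
#'
#' @param cohort A `cohort` table.
#' @param B,level,seed Passed to [bootstrap_slope_ci()].
#' @param regions Regions to fit (default: all in the cohort).
#' @return data.frame, one row per group-by-region slope estimate.
#' @export
aging_slopes <- function(cohort, B = 10000, level = 0.95, seed = 1,
                         regions = cohort_regions(cohort)) {
  out <- list()
  for (g in names(groups <- cohort_groups(cohort))) {
    sub <- cohort[groups[[g]], , drop = FALSE]
    for (reg in regions)
      out[[paste(g, reg)]] <- as.data.frame(
        bootstrap_slope_ci(sub, reg, B = B, level = level, seed = seed,
                           group = g))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Pairwise CI-overlap comparisons from a slope table
#'
#' @param slopes data.frame as returned by [aging_slopes()].
#' @return data.frame with one row per unordered group pair per region and
#'   the overlap decision.
#' @export
compare_group_slopes <- function(slopes) {
  out <- list()
  for (reg in unique(slopes$region)) {
    sl <- slopes[slopes$region == reg, , drop = FALSE]
    gs <- sl$group
    if (length(gs) < 2) next
    for (i in seq_len(length(gs) - 1)) for (j in seq(i + 1, length(gs))) {
      cmp <- compare_cis(as.list(sl[i, ]), as.list(sl[j, ]))
      out[[paste(reg, i, j)]] <- data.frame(
        group_a = cmp$group_a, group_b = cmp$group_b, region = reg,
        significant = cmp$significant,
        ci_a_low = cmp$ci_a[1], ci_a_high = cmp$ci_a[2],
        ci_b_low = cmp$ci_b[1], ci_b_high = cmp$ci_b[2],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' APOE epsilon-4 effects for every group and region of a cohort
#'
#' @inheritParams aging_slopes
#' @return data.frame, one row per group-by-region effect.
#' @export
apoe_effects <- function(cohort, B = 10000, level = 0.95, seed = 1,
                         regions = cohort_regions(cohort)) {
  out <- list()
  for (g in names(groups <- cohort_groups(cohort))) {
    sub <- cohort[groups[[g]], , drop = FALSE]
    for (reg in regions)
      out[[paste(g, reg)]] <- as.data.frame(
        apoe_effect(sub, reg, B = B, level = level, seed = seed, group = g))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
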