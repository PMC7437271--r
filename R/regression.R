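# Pooled multi-predictor regression per region, Bonferroni correction, and
# the two-way ANOVA reconstructed from cell summaries.

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Family-wise error rate (0 < alpha < 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 15)   # 0.00333... -> reported as 0.003
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Pooled volume regression for one region
#'
#' Ordinary least squares of one region's absolute volume on age, sex,
#' ethnicity, education and ICV across the pooled cohort. Binary
#' predictors are coded female=0/male=1 and korean=0/caucasian=1 (so a
#' negative ethnicity coefficient means smaller in Caucasians). All
#' variables — outcome, continuous and coded binary predictors alike — are
#' z-scored by default, yielding standardized coefficients; raw
#' coefficients (mm^3 per unit) are reported alongside. With
#' `standardize = FALSE` binary predictors stay dummy-coded 0/1 and the
#' reported `b_std` comes from z-scoring only the continuous variables.
#'
#' @param cohort A `cohort` table.
#' @param region Region name.
#' @param alpha,m Family-wise error rate and number of regions for the
#'   Bonferroni significance flag (defaults 0.05 and 15).
#' @param standardize Z-score binary predictors too (default TRUE).
#' @return A `regression_result`: list with `region`, `coefficients`
#'   (data.frame: predictor, b_std, b_raw, p, significant), `r2` and `n`.
#' @export
fit_volume_model <- function(cohort, region, alpha = 0.05, m = 15,
                             standardize = TRUE) {
  col <- paste0("vol_", region, "_mm3")
  if (!(col %in% names(cohort))) stop("unknown region ", region)
  sex_code <- ifelse(cohort$sex == "male", 1, 0)
  eth_code <- ifelse(cohort$ethnicity == "caucasian", 1, 0)
  d <- data.frame(y = cohort[[col]], age = cohort$age, sex = sex_code,
                  ethnicity = eth_code, education = cohort$education,
                  icv = cohort$icv_mm3)
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10) stop("need at least 10 complete records")
  sds <- vapply(d, sd, 0)
  if (any(sds == 0))
    stop("degenerate design: constant ",
         paste(names(sds)[sds == 0], collapse = ", "))

  zscore <- function(x) (x - mean(x)) / sd(x)
  dz <- d
  cols <- if (standardize) names(d) else c("y", "age", "education", "icv")
  for (cc in cols) dz[[cc]] <- zscore(d[[cc]])

  fit_z <- lm(y ~ age + sex + ethnicity + education + icv, data = dz)
  fit_raw <- lm(y ~ age + sex + ethnicity + education + icv, data = d)
  if (anyNA(stats::coef(fit_z)))
    stop("degenerate design: aliased predictor(s) ",
         paste(names(stats::coef(fit_z))[is.na(stats::coef(fit_z))],
               collapse = ", "))
  sm <- summary(fit_z)
  co <- sm$coefficients[-1, , drop = FALSE]   # drop intercept
  thresh <- bonferroni_threshold(alpha, m)
  structure(list(
    region = region,
    coefficients = data.frame(
      predictor = rownames(co),
      b_std = unname(co[, "Estimate"]),
      b_raw = unname(stats::coef(fit_raw)[-1]),
      p = unname(co[, "Pr(>|t|)"]),
      significant = unname(co[, "Pr(>|t|)"]) < thresh,
      stringsAsFactors = FALSE),
    r2 = sm$r.squared, n = nrow(d), p_threshold = thresh),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %s (n=%d, R2=%.3f, p threshold %.4g)\n",
              x$region, x$n, x$r2, x$p_threshold))
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Pooled regressions for every region
#'
#' @inheritParams fit_volume_model
#' @param regions Regions to fit (default: all in the cohort; also sets
#'   the Bonferroni `m`).
#' @return Tidy data.frame: region, predictor, b_std, b_raw, p,
#'   significant_bonferroni, r2, n.
#' @export
volume_regressions <- function(cohort, regions = cohort_regions(cohort),
                               alpha = 0.05, m = length(regions),
                               standardize = TRUE) {
  out <- lapply(regions, function(reg) {
    r <- fit_volume_model(cohort, reg, alpha = alpha, m = m,
                          standardize = standardize)
    cbind(data.frame(region = reg, stringsAsFactors = FALSE),
          setNames(r$coefficients,
                   c("predictor", "b_std", "b_raw", "p",
                     "significant_bonferroni")),
          data.frame(r2 = r$r2, n = r$n))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-way ANOVA from cell summaries
#'
#' Reconstructs the 2x2 (ethnicity x sex) analysis of variance from
#' per-cell n, mean and SD alone: the within-cell sum of squares is
#' `sum((n_i - 1) * sd_i^2)` and the effect sums of squares are sequential
#' (Type I) in the listed order — ethnicity, then sex, then interaction —
#' computed from weighted fits to the cell means. With unbalanced cells the
#' main-effect F values depend on this order; the interaction F does not.
#'
#' @param cells data.frame with columns `ethnicity`, `sex`, `n`, `mean`,
#'   `sd`; exactly one row per cell of the 2x2 design, each `n >= 2`.
#' @return data.frame with rows ethnicity, sex, ethnicity:sex and
#'   residuals; columns `effect`, `df`, `ss`, `F`, `p`.
#' @export
#' @examples
#' demo <- published_demographics()
#' cells <- data.frame(ethnicity = demo$ethnicity, sex = demo$sex,
#'                     n = demo$n, mean = demo$age_mean, sd = demo$age_sd)
#' twoway_anova_from_summaries(cells)
twoway_anova_from_summaries <- function(cells) {
  cells <- as.data.frame(cells)
  stopifnot(all(c("ethnicity", "sex", "n", "mean", "sd") %in% names(cells)))
  if (nrow(cells) != 4 ||
      nrow(unique(cells[c("ethnicity", "sex")])) != 4 ||
      length(unique(cells$ethnicity)) != 2 ||
      length(unique(cells$sex)) != 2)
    stop("need exactly the four cells of a 2x2 design")
  if (any(cells$n < 2)) stop("each cell needs n >= 2")
  if (any(cells$sd < 0)) stop("cell sd must be >= 0")

  ss_within <- sum((cells$n - 1) * cells$sd^2)
  df_within <- sum(cells$n) - 4
  cells$eth <- factor(cells$ethnicity)
  cells$sx <- factor(cells$sex)
  wrss <- function(formula) {
    fit <- lm(formula, data = cells, weights = cells$n)
    sum(cells$n * stats::resid(fit)^2)
  }
  r0 <- wrss(mean ~ 1)
  r1 <- wrss(mean ~ eth)
  r2 <- wrss(mean ~ eth + sx)
  ss <- c(r0 - r1, r1 - r2, r2)   # saturated model has zero residual
  mse <- ss_within / df_within
  data.frame(effect = c("ethnicity", "sex", "ethnicity:sex", "residuals"),
             df = c(1, 1, 1, df_within),
             ss = c(ss, ss_within),
             F = c(ss / mse, NA),
             p = c(pf(ss / mse, 1, df_within, lower.tail = FALSE), NA),
             stringsAsFactors = FALSE)
}
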