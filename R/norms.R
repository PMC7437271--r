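# Normative tables by ethnicity x sex x 5-year age bin, and per-subject
# z-scoring against them.

AGE_BIN_LABELS <- c("65-69", "70-74", "75-79", "80-85")

#' Assign a 5-year age bin
#'
#' Bins are `[65,70)`, `[70,75)`, `[75,80)` and `[80,85]` — half-open
#' except the last, which closes at 85 so the full 65-85 range is covered
#' without gap or overlap.
#'
#' @param age Age(s) in years, within `[65, 85]`.
#' @return Character bin label(s): `"65-69"`, `"70-74"`, `"75-79"`,
#'   `"80-85"`.
#' @export
#' @examples
#' assign_age_bin(c(65, 72, 85))
assign_age_bin <- function(age) {
  if (any(!is.finite(age)) || any(age < 65 | age > 85))
    stop("age outside [65, 85]")
  idx <- pmin(findInterval(age, c(65, 70, 75, 80)), 4L)
  AGE_BIN_LABELS[idx]
}

#' Build normative tables
#'
#' Per stratum (ethnicity x sex x 5-year age bin) and region, summary
#' statistics on the relative (% of ICV) and absolute (mm^3) scales:
#' n, mean, SD and the 5th/25th/50th/75th/95th percentiles
#' (median-unbiased estimator, `quantile type = 8`). Strata with fewer
#' contributors than `min_n` are kept but flagged `low_n`.
#'
#' @param cohort A screened `cohort` table.
#' @param min_n Low-n flag floor (default 10).
#' @return A `norm_table` data.frame: `ethnicity`, `sex`, `age_bin`,
#'   `region`, `scale`, `n`, `mean`, `sd`, `p5`, `p25`, `p50`, `p75`,
#'   `p95`, `low_n`.
#' @export
build_norms <- function(cohort, min_n = 10) {
  if (nrow(cohort) == 0) stop("empty cohort")
  regions <- cohort_regions(cohort)
  bin <- assign_age_bin(cohort$age)
  key <- paste(cohort$ethnicity, cohort$sex, bin, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    sub <- cohort[sel, , drop = FALSE]
    for (reg in regions) {
      abs_v <- sub[[paste0("vol_", reg, "_mm3")]]
      for (scale_name in c("relative", "absolute")) {
        v <- if (scale_name == "relative")
          relative_volume(abs_v, sub$icv_mm3) else abs_v
        qs <- quantile(v, c(0.05, 0.25, 0.50, 0.75, 0.95), type = 8,
                       names = FALSE)
        out[[paste(k, reg, scale_name)]] <- data.frame(
          ethnicity = parts[1], sex = parts[2], age_bin = parts[3],
          region = reg, scale = scale_name, n = length(v),
          mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
          p5 = qs[1], p25 = qs[2], p50 = qs[3], p75 = qs[4], p95 = qs[5],
          low_n = length(v) < min_n, stringsAsFactors = FALSE)
      }
    }
  }
  norms <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  norms <- norms[order(norms$ethnicity, norms$sex, norms$age_bin,
                       match(norms$region, regions), norms$scale), ]
  rownames(norms) <- NULL
  class(norms) <- c("norm_table", "data.frame")
  norms
}

#' Z-score a subject against normative tables
#'
#' Looks up the subject's ethnicity x sex x age-bin stratum and z-scores
#' each region's relative volume against the stratum mean and SD. A
#' zero-SD stratum yields NA with `undefined = TRUE` for that region.
#'
#' @param record One-row `cohort` table (or data.frame with `age`, `sex`,
#'   `ethnicity`, `icv_mm3` and the volume columns).
#' @param norms A `norm_table` from [build_norms()].
#' @return data.frame: `region`, `rel_volume`, `norm_mean`, `norm_sd`,
#'   `z`, `undefined`.
#' @export
zscore_subject <- function(record, norms) {
  if (nrow(record) != 1) stop("record must be a single row")
  bin <- assign_age_bin(record$age)
  sel <- norms$ethnicity == record$ethnicity & norms$sex == record$sex &
    norms$age_bin == bin & norms$scale == "relative"
  if (!any(sel))
    stop("no matching norm stratum for ", record$ethnicity, "/",
         record$sex, "/", bin)
  strat <- norms[sel, , drop = FALSE]
  out <- lapply(seq_len(nrow(strat)), function(i) {
    reg <- strat$region[i]
    rel <- relative_volume(record[[paste0("vol_", reg, "_mm3")]],
                           record$icv_mm3)
    undef <- strat$sd[i] == 0
    data.frame(region = reg, rel_volume = rel, norm_mean = strat$mean[i],
               norm_sd = strat$sd[i],
               z = if (undef) NA_real_ else (rel - strat$mean[i]) / strat$sd[i],
               undefined = undef, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
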