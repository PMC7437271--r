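#' @importFrom stats complete.cases lm pf pt quantile rnorm runif sd setNames var
NULL

COGNITIVE_DOMAINS <- c("attention", "language", "visuospatial", "memory",
                       "executive")

#' Construct a cohort table
#'
#' A cohort table is a data.frame with one row per subject and class
#' `cohort`. Required columns: `subject_id`, `age`, `sex`, `ethnicity`,
#' `education`, `icv_mm3` and one absolute volume column per region
#' (`vol_<region>_mm3`). Optional columns: `mmse`, the five cognitive-domain
#' z-scores (`z_attention`, `z_language`, `z_visuospatial`, `z_memory`,
#' `z_executive`), APOE SNP genotypes (`apoe_rs429358`, `apoe_rs7412`) or a
#' derived `apoe_genotype` (e.g. `"e3/e4"`) and `apoe_carrier` (logical).
#'
#' If SNP columns are present but no genotype column, the APOE genotype and
#' carrier status are derived via [apoe_from_snps()]. When a genotype is
#' present, `apoe_carrier` is always recomputed as "contains at least one
#' e4" so the two can never disagree.
#'
#' @param df data.frame of subject rows.
#' @param regions Character vector of region names or a `region_set`
#'   (default: the shipped 15-region set).
#' @param provenance Free-text description of where the rows came from.
#' @param validate Run [validate_cohort()] (default TRUE).
#' @return A `cohort` data.frame.
#' @export
cohort_table <- function(df, regions = default_region_set(),
                         provenance = "", validate = TRUE) {
  if (inherits(regions, "region_set")) regions <- regions$regions
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "sex", "ethnicity", "education",
                "icv_mm3", region_columns(regions))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)

  has_snps <- all(c("apoe_rs429358", "apoe_rs7412") %in% names(df))
  if (!("apoe_genotype" %in% names(df)) && has_snps) {
    called <- apoe_from_snps(df$apoe_rs429358, df$apoe_rs7412)
    df$apoe_genotype <- called$genotype
    df$apoe_carrier <- called$carrier
  }
  if ("apoe_genotype" %in% names(df)) {
    df$apoe_carrier <- ifelse(is.na(df$apoe_genotype), NA,
                              grepl("e4", df$apoe_genotype, fixed = TRUE))
  }

  structure(df,
            class = c("cohort", "data.frame"),
            regions = regions,
            provenance = provenance) -> out
  if (validate) validate_cohort(out)
  out
}

#' Region names attached to a cohort
#' @param cohort A `cohort` table.
#' @return Character vector of region names.
#' @export
cohort_regions <- function(cohort) attr(cohort, "regions")

#' Validate a cohort table
#'
#' Checks the structural invariants: unique subject ids, positive ICV,
#' non-negative finite volumes, every regional volume strictly below ICV,
#' and (when APOE columns are present) agreement between genotype and
#' carrier flag. Violations raise a single error listing every offending
#' row.
#'
#' @param cohort A `cohort` table.
#' @param age_bounds Permitted age range (default `c(65, 85)`, the screened
#'   cohort range; use wider bounds for unscreened data).
#' @return Invisibly TRUE.
#' @export
validate_cohort <- function(cohort, age_bounds = c(65, 85)) {
  problems <- character(0)
  row_ref <- function(i) paste0("row ", i, " (", cohort$subject_id[i], ")")

  dup <- which(duplicated(cohort$subject_id))
  if (length(dup) > 0)
    problems <- c(problems, paste0("duplicate subject_id at ",
                                   paste(vapply(dup, row_ref, ""), collapse = "; ")))
  bad_icv <- which(!is.finite(cohort$icv_mm3) | cohort$icv_mm3 <= 0)
  if (length(bad_icv) > 0)
    problems <- c(problems, paste0("non-positive icv_mm3 at ",
                                   paste(vapply(bad_icv, row_ref, ""), collapse = "; ")))
  bad_age <- which(is.finite(cohort$age) &
                     (cohort$age < age_bounds[1] | cohort$age > age_bounds[2]))
  if (length(bad_age) > 0)
    problems <- c(problems, paste0("age outside [", age_bounds[1], ", ",
                                   age_bounds[2], "] at ",
                                   paste(vapply(bad_age, row_ref, ""), collapse = "; ")))
  for (col in region_columns(cohort_regions(cohort))) {
    v <- cohort[[col]]
    neg <- which(!is.finite(v) | v < 0)
    if (length(neg) > 0)
      problems <- c(problems, paste0("negative or non-finite ", col, " at ",
                                     paste(vapply(neg, row_ref, ""), collapse = "; ")))
    big <- which(is.finite(v) & v >= cohort$icv_mm3)
    if (length(big) > 0)
      problems <- c(problems, paste0(col, " >= icv_mm3 at ",
                                     paste(vapply(big, row_ref, ""), collapse = "; ")))
  }
  if (all(c("apoe_genotype", "apoe_carrier") %in% names(cohort))) {
    got <- grepl("e4", cohort$apoe_genotype, fixed = TRUE)
    mism <- which(!is.na(cohort$apoe_genotype) & !is.na(cohort$apoe_carrier) &
                    got != cohort$apoe_carrier)
    if (length(mism) > 0)
      problems <- c(problems, paste0("apoe_carrier inconsistent with genotype at ",
                                     paste(vapply(mism, row_ref, ""), collapse = "; ")))
  }
  if (length(problems) > 0)
    stop("cohort validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(TRUE)
}

#' Cognitively-normal screening
#'
#' Applies the two published exclusion rules: MMSE below `mmse_min`
#' (default 19) excludes, and a z-score below `z_cut` (default -1.5) in any
#' of the five cognitive domains (attention, language, visuospatial,
#' memory, frontal/executive) excludes. The returned reason names the first
#' failing criterion (`"mmse"` first, then the domains in the order above).
#'
#' @param cohort A `cohort` table with `mmse` and all five `z_*` columns.
#' @param mmse_min Minimum MMSE score for inclusion (exclude iff
#'   `mmse < mmse_min`).
#' @param z_cut Domain z threshold (exclude iff any `z < z_cut`).
#' @return data.frame with `subject_id`, `include` (logical) and `reason`
#'   (NA for included subjects).
#' @export
#' @examples
#' coh <- generate_cohort(default_specs()[1], seed = 1)
#' table(screen_cognitively_normal(coh)$include)
screen_cognitively_normal <- function(cohort, mmse_min = 19, z_cut = -1.5) {
  zcols <- paste0("z_", COGNITIVE_DOMAINS)
  need <- c("mmse", zcols)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0 ||
      anyNA(cohort$mmse) || anyNA(as.matrix(cohort[zcols])))
    stop("insufficient neuropsychological data", call. = FALSE)

  n <- nrow(cohort)
  reason <- rep(NA_character_, n)
  fail_mmse <- cohort$mmse < mmse_min
  reason[fail_mmse] <- "mmse"
  for (d in rev(COGNITIVE_DOMAINS)) {   # reverse so earlier domains win
    fail_d <- cohort[[paste0("z_", d)]] < z_cut
    reason[!fail_mmse & fail_d] <- d
  }
  data.frame(subject_id = cohort$subject_id,
             include = is.na(reason),
             reason = reason,
             stringsAsFactors = FALSE)
}

#' Filter a cohort to its cognitively normal members
#'
#' @inheritParams screen_cognitively_normal
#' @return The screened `cohort`; the screening decision table is attached
#'   as attribute `"screen"`.
#' @export
screen_cohort <- function(cohort, mmse_min = 19, z_cut = -1.5) {
  dec <- screen_cognitively_normal(cohort, mmse_min, z_cut)
  out <- cohort[dec$include, , drop = FALSE]
  attr(out, "screen") <- dec
  attr(out, "regions") <- cohort_regions(cohort)
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- class(cohort)
  out
}

#' APOE genotype from the two coding SNPs
#'
#' Derives the APOE genotype from unphased diploid genotypes at rs429358
#' and rs7412. The canonical haplotype table is: e2 = rs429358-T/rs7412-T,
#' e3 = T/C, e4 = C/C (and the very rare e1 = C/T). The double heterozygote
#' (C/T at both SNPs) cannot be phased without population information — it
#' is e2/e4 or e1/e3 — and is reported as ambiguous (NA genotype and
#' carrier), never guessed.
#'
#' @param rs429358,rs7412 Character vectors of diploid genotypes, e.g.
#'   `"CT"`, `"C/T"`, `"TT"` (order of the two alleles is irrelevant).
#' @return data.frame with `genotype` (e.g. `"e3/e4"`, NA if ambiguous),
#'   `carrier` (TRUE iff at least one e4; NA if ambiguous) and `ambiguous`.
#' @export
#' @examples
#' apoe_from_snps(c("TT", "CC", "CT"), c("CC", "CC", "CC"))
apoe_from_snps <- function(rs429358, rs7412) {
  if (length(rs429358) != length(rs7412))
    stop("rs429358 and rs7412 must have equal length")
  clean <- function(x) {
    x <- toupper(gsub("[/|[:space:]]", "", as.character(x)))
    bad <- !is.na(x) & !grepl("^[CT]{2}$", x)
    if (any(bad))
      stop("invalid allele pair(s): ", paste(unique(x[bad]), collapse = ", "),
           " (alleles must be C or T)", call. = FALSE)
    x
  }
  s1 <- clean(rs429358)
  s2 <- clean(rs7412)
  n_c1 <- vapply(strsplit(s1, ""), function(a) sum(a == "C"), 0L)
  n_t2 <- vapply(strsplit(s2, ""), function(a) sum(a == "T"), 0L)

  # genotype lookup indexed by (C count at rs429358, T count at rs7412)
  lut <- matrix(c("e3/e3", "e2/e3", "e2/e2",
                  "e3/e4", NA,      "e1/e2",
                  "e4/e4", "e1/e4", "e1/e1"),
                nrow = 3, byrow = TRUE)
  geno <- rep(NA_character_, length(s1))
  ok <- !is.na(n_c1) & !is.na(n_t2)
  geno[ok] <- lut[cbind(n_c1[ok] + 1L, n_t2[ok] + 1L)]
  ambiguous <- ok & n_c1 == 1L & n_t2 == 1L
  carrier <- ifelse(is.na(geno), NA, grepl("e4", geno, fixed = TRUE))
  data.frame(genotype = geno, carrier = carrier, ambiguous = ambiguous,
             stringsAsFactors = FALSE)
}

#' Read a cohort from delimited text
#'
#' @param path CSV or TSV file with a header row.
#' @param dialect `"auto"` (by file extension, default), `"csv"` or
#'   `"tsv"`.
#' @param regions Region names or a `region_set` expected in the file.
#' @param age_bounds Passed to [validate_cohort()].
#' @return A `cohort` table (provenance set to the file path).
#' @export
read_cohort <- function(path, dialect = c("auto", "csv", "tsv"),
                        regions = default_region_set(),
                        age_bounds = c(65, 85)) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  coh <- cohort_table(df, regions = regions, provenance = path,
                      validate = FALSE)
  validate_cohort(coh, age_bounds = age_bounds)
  coh
}

#' Write a cohort to delimited text
#'
#' Numeric columns are written with 17 significant digits so that
#' write-then-read round-trips reproduce all values exactly.
#'
#' @param cohort A `cohort` table.
#' @param path Output path (`.tsv` extension selects tab separation).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      v <- formatC(out[[col]], digits = 17, format = "g")
      v[is.na(out[[col]])] <- NA
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
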