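# End-to-end pipeline: screen -> regress -> slopes -> compare -> apoe ->
# norms, with a reproducibility manifest.

#' Build a run configuration
#'
#' @param cohort_file Input cohort CSV/TSV (NULL to simulate from the
#'   default specs with `seed`).
#' @param out_dir Output directory (created if absent).
#' @param B Bootstrap iterations (default 10,000).
#' @param level CI level (default 0.95).
#' @param seed Master seed for simulation and every bootstrap stream.
#' @param alpha,m Bonferroni inputs (defaults 0.05 across 15 regions).
#' @param min_n Low-n floor for norm strata.
#' @param screen Apply the cognitively-normal screen if the
#'   neuropsychological columns are present (default TRUE).
#' @param mapping_file Optional region-mapping CSV overriding the shipped
#'   one.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_file = NULL, out_dir = "brainaging_out",
                       B = 10000, level = 0.95, seed = 1, alpha = 0.05,
                       m = 15, min_n = 10, screen = TRUE,
                       mapping_file = NULL) {
  stopifnot(B >= 1, level > 0, level < 1, alpha > 0, alpha < 1, m >= 1)
  if (!is.null(cohort_file) && !file.exists(cohort_file))
    stop("cohort file not found: ", cohort_file)
  if (!is.null(mapping_file) && !file.exists(mapping_file))
    stop("mapping file not found: ", mapping_file)
  structure(list(cohort_file = cohort_file, out_dir = out_dir,
                 B = as.integer(B), level = level, seed = as.integer(seed),
                 alpha = alpha, m = as.integer(m), min_n = as.integer(min_n),
                 screen = isTRUE(screen), mapping_file = mapping_file),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file whose keys match the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a cohort, optionally screens it, and writes the
#' regression table, slope table, pairwise CI-overlap comparisons,
#' APOE-e4 effect table, normative tables and a JSON run manifest into
#' `config$out_dir`. Identical config and seed produce byte-identical
#' outputs.
#'
#' @param config A `run_config`.
#' @param quiet Suppress per-stage timing messages.
#' @return Invisibly, a named list of the output file paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    if (!quiet)
      message(sprintf("[%s] %.2fs", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  regions <- if (is.null(config$mapping_file)) default_region_set()
             else default_region_set(config$mapping_file)

  cohort <- stage("load", {
    if (is.null(config$cohort_file))
      generate_cohort(default_specs(regions$regions), seed = config$seed)
    else read_cohort(config$cohort_file, regions = regions)
  })
  if (config$screen &&
      all(c("mmse", paste0("z_", COGNITIVE_DOMAINS)) %in% names(cohort)) &&
      !anyNA(cohort$mmse))
    cohort <- stage("screen", screen_cohort(cohort))

  paths <- list()
  write_out <- function(df, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }

  write_out(stage("regress",
                  volume_regressions(cohort, alpha = config$alpha,
                                     m = config$m)), "regression")
  slopes <- stage("slopes",
                  aging_slopes(cohort, B = config$B, level = config$level,
                               seed = config$seed))
  write_out(slopes, "slopes")
  write_out(stage("compare", compare_group_slopes(slopes)), "comparisons")
  write_out(stage("apoe",
                  suppressMessages(
                    apoe_effects(cohort, B = config$B, level = config$level,
                                 seed = config$seed))), "apoe_effects")
  write_out(stage("norms", build_norms(cohort, min_n = config$min_n)),
            "norms")

  manifest <- list(
    package_version = as.character(utils::packageVersion("brainaging")),
    r_version = as.character(getRversion()),
    config = unclass(config),
    n_subjects = nrow(cohort),
    outputs = lapply(paths, function(p)
      unname(tools::md5sum(p))))
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  paths$manifest <- mpath
  invisible(paths)
}
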