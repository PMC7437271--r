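#' Parse a FreeSurfer aseg.stats file
#'
#' Reads the standard FreeSurfer subcortical-segmentation statistics
#' dialect: `#`-prefixed header lines, among them
#' `# Measure <id>, <name>, <description>, <value>, <unit>` lines (which
#' must include `EstimatedTotalIntraCranialVol`), a `# ColHeaders` line,
#' then whitespace-delimited rows with at least `StructName` and
#' `Volume_mm3` columns.
#'
#' @param con A file path or text connection; a character vector of length
#'   > 1 is treated as lines.
#' @return An `aseg_stats` object: list with `measures` (named numeric,
#'   keyed by both measure id and short name), `structures` (named numeric,
#'   StructName -> volume in mm^3) and `etiv`.
#' @export
parse_aseg_stats <- function(con) {
  parse_fs_stats(con, volume_col = "Volume_mm3", require_etiv = TRUE)
}

#' Parse a FreeSurfer cortical parcellation stats file
#'
#' Reads the `?h.aparc.DKTatlas.stats` dialect (`StructName` and `GrayVol`
#' columns) for one hemisphere.
#'
#' @inheritParams parse_aseg_stats
#' @param hemisphere `"lh"` or `"rh"`.
#' @return An `aparc_stats` object: list with `hemisphere`, `volumes`
#'   (named numeric, parcel -> gray-matter volume mm^3) and `measures`.
#' @export
parse_aparc_stats <- function(con, hemisphere = c("lh", "rh")) {
  hemisphere <- match.arg(hemisphere)
  parsed <- parse_fs_stats(con, volume_col = "GrayVol", require_etiv = FALSE)
  structure(list(hemisphere = hemisphere,
                 volumes = parsed$structures,
                 measures = parsed$measures),
            class = "aparc_stats")
}

# Shared parser for the two FreeSurfer stats dialects. The format is
# self-describing via the ColHeaders line; rows are validated against it.
parse_fs_stats <- function(con, volume_col, require_etiv) {
  lines <- if (is.character(con) && length(con) > 1) {
    con
  } else if (is.character(con) && file.exists(con)) {
    readLines(con, warn = FALSE)
  } else if (inherits(con, "connection")) {
    readLines(con, warn = FALSE)
  } else if (is.character(con)) {
    strsplit(con, "\n", fixed = TRUE)[[1]]
  } else stop("unsupported input")
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("empty stats stream")

  measures <- numeric(0)
  col_headers <- NULL
  for (ln in lines) {
    if (startsWith(ln, "# Measure")) {
      fields <- trimws(strsplit(sub("^# Measure\\s+", "", ln), ",")[[1]])
      if (length(fields) < 4) stop("malformed Measure line: ", ln)
      val <- suppressWarnings(as.numeric(fields[length(fields) - 1]))
      if (is.na(val)) stop("non-numeric Measure value: ", ln)
      measures[fields[1]] <- val
      measures[fields[2]] <- val
    } else if (startsWith(ln, "# ColHeaders")) {
      col_headers <- strsplit(trimws(sub("^# ColHeaders", "", ln)),
                              "\\s+")[[1]]
    }
  }
  if (is.null(col_headers))
    stop("missing ColHeaders line in stats stream")
  for (need in c("StructName", volume_col)) {
    if (!(need %in% col_headers))
      stop("stats stream lacks required column ", need)
  }
  i_name <- match("StructName", col_headers)
  i_vol <- match(volume_col, col_headers)

  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  structures <- numeric(0)
  for (i in body) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) < max(i_name, i_vol))
      stop("malformed stats row at line ", i, ": ", lines[i])
    vol <- suppressWarnings(as.numeric(fields[i_vol]))
    if (is.na(vol))
      stop("non-numeric volume at line ", i, ": ", lines[i])
    if (vol < 0)
      stop("negative volume at line ", i, ": ", lines[i])
    structures[fields[i_name]] <- vol
  }

  etiv <- unname(measures["EstimatedTotalIntraCranialVol"])
  if (require_etiv) {
    if (is.na(etiv)) stop("missing EstimatedTotalIntraCranialVol measure")
    if (etiv <= 0) stop("non-positive eTIV")
    return(structure(list(measures = measures, structures = structures,
                          etiv = etiv),
                     class = "aseg_stats"))
  }
  structure(list(measures = measures, structures = structures,
                 etiv = if (is.na(etiv)) NULL else etiv),
            class = "fs_stats")
}

#' Aggregate FreeSurfer structures into the 15 composite regions
#'
#' Each composite volume is the sum of its mapped constituents: aparc
#' parcels are summed over both hemispheres, aseg structures are summed as
#' named (left/right structures are listed explicitly in the mapping), and
#' `measure` entries are read from the aseg header (whole-brain volume).
#' ICV is the aseg eTIV.
#'
#' @param aseg An `aseg_stats` object.
#' @param aparc_lh,aparc_rh `aparc_stats` for the two hemispheres.
#' @param regions A `region_set` (default: shipped mapping).
#' @return List with `volumes` (named numeric over the region set, mm^3)
#'   and `icv` (mm^3).
#' @export
aggregate_regions <- function(aseg, aparc_lh, aparc_rh,
                              regions = default_region_set()) {
  stopifnot(inherits(regions, "region_set"))
  cort <- c(aparc_lh$volumes, aparc_rh$volumes)
  map <- regions$mapping

  missing <- character(0)
  vols <- setNames(numeric(length(regions$regions)), regions$regions)
  for (reg in regions$regions) {
    rows <- map[map$region == reg, , drop = FALSE]
    total <- 0
    for (k in seq_len(nrow(rows))) {
      src <- rows$source[k]; nm <- rows$name[k]
      if (src == "measure") {
        v <- unname(aseg$measures[nm])
        if (is.null(v) || is.na(v)) { missing <- c(missing, nm); next }
        total <- total + v
      } else if (src == "aseg") {
        v <- unname(aseg$structures[nm])
        if (is.null(v) || is.na(v)) { missing <- c(missing, nm); next }
        total <- total + v
      } else {
        hit <- which(names(cort) == nm)
        if (length(hit) == 0) { missing <- c(missing, nm); next }
        total <- total + sum(cort[hit])
      }
    }
    vols[reg] <- total
  }
  if (length(missing) > 0)
    stop("mapped structure(s) absent from stats input: ",
         paste(unique(missing), collapse = ", "))
  list(volumes = vols, icv = aseg$etiv)
}

#' Read one FreeSurfer subject directory into a cohort row
#'
#' Expects `aseg.stats`, `lh.aparc.DKTatlas.stats` and
#' `rh.aparc.DKTatlas.stats` under `dir` (or under `dir/stats`).
#'
#' @param dir Subject stats directory.
#' @param regions A `region_set`.
#' @return One-row data.frame with `icv_mm3` and `vol_<region>_mm3`
#'   columns.
#' @export
read_freesurfer_subject <- function(dir, regions = default_region_set()) {
  find <- function(f) {
    for (p in c(file.path(dir, f), file.path(dir, "stats", f)))
      if (file.exists(p)) return(p)
    stop("missing ", f, " under ", dir)
  }
  agg <- aggregate_regions(parse_aseg_stats(find("aseg.stats")),
                           parse_aparc_stats(find("lh.aparc.DKTatlas.stats"), "lh"),
                           parse_aparc_stats(find("rh.aparc.DKTatlas.stats"), "rh"),
                           regions)
  row <- as.data.frame(as.list(agg$volumes))
  names(row) <- region_columns(regions)
  cbind(data.frame(icv_mm3 = agg$icv), row)
}

#' Write fixture FreeSurfer stats files
#'
#' Minimal writers for the two stats dialects, intended for building test
#' fixtures and synthetic subject directories only — real stats files come
#' from FreeSurfer.
#'
#' @param structures Named numeric vector of volumes (mm^3).
#' @param etiv eTIV in mm^3.
#' @param measures Optional extra named header measures (e.g.
#'   `BrainSegVolNotVent`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_aseg_stats <- function(structures, etiv, measures = numeric(0), path) {
  lines <- c("# Title Segmentation Statistics (synthetic fixture)")
  for (nm in names(measures))
    lines <- c(lines, sprintf("# Measure %s, %s, %s, %.4f, mm^3",
                              nm, nm, nm, measures[[nm]]))
  lines <- c(lines,
             sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %.4f, mm^3", etiv),
             "# ColHeaders  Index SegId NVoxels Volume_mm3 StructName")
  for (k in seq_along(structures))
    lines <- c(lines, sprintf("%3d %3d %6d %10.1f %s", k, k,
                              round(structures[[k]]), structures[[k]],
                              names(structures)[k]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_aseg_stats
#' @param volumes Named numeric vector of parcel gray-matter volumes.
#' @param hemisphere `"lh"` or `"rh"`.
#' @export
write_aparc_stats <- function(volumes, hemisphere, path) {
  lines <- c(sprintf("# Title Cortical Parcellation Statistics (synthetic fixture, %s)",
                     hemisphere),
             "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg")
  for (k in seq_along(volumes))
    lines <- c(lines, sprintf("%s %6d %6d %10.1f %.3f",
                              names(volumes)[k], 1000L, 700L,
                              volumes[[k]], 2.5))
  writeLines(lines, path)
  invisible(path)
}
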