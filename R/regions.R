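#' The 15 composite brain regions
#'
#' The analysis works on 15 composite regions: whole brain, six cortical
#' lobar composites aggregated from the Desikan--Killiany--Tourville (DKT)
#' parcellation, and eight subcortical structures taken from the FreeSurfer
#' aseg segmentation. A `region_set` couples the ordered region names with
#' the parcel composition used by [aggregate_regions()].
#'
#' The shipped mapping (`inst/extdata/dkt_region_mapping.csv`) is a declared
#' convention, editable as data: the standard lobar grouping of the 31 DKT
#' cortical parcels, the common "ventricular system" composite
#' (lateral + inferior-lateral + 3rd + 4th ventricles), and whole-brain
#' volume taken from the `BrainSegVolNotVent` header measure so brain
#' shrinkage and ventricular expansion remain separable trends.
#'
#' @param mapping_file Path to a CSV with columns `region`, `source`
#'   (`measure`, `aparc` or `aseg`) and `name`. Defaults to the shipped
#'   mapping.
#' @return An object of class `region_set`: a list with `regions` (ordered
#'   character vector of the 15 names) and `mapping` (the composition
#'   data.frame).
#' @export
#' @examples
#' rs <- default_region_set()
#' rs$regions
default_region_set <- function(mapping_file = NULL) {
  if (is.null(mapping_file)) {
    mapping_file <- system.file("extdata", "dkt_region_mapping.csv",
                                package = "brainaging", mustWork = TRUE)
  }
  mapping <- utils::read.csv(mapping_file, stringsAsFactors = FALSE)
  region_set(mapping)
}

#' Construct a region set from a composition mapping
#'
#' @param mapping data.frame with columns `region`, `source`, `name`.
#' @return A `region_set` object.
#' @export
region_set <- function(mapping) {
  stopifnot(is.data.frame(mapping),
            all(c("region", "source", "name") %in% names(mapping)))
  bad <- setdiff(unique(mapping$source), c("measure", "aparc", "aseg"))
  if (length(bad) > 0)
    stop("unknown mapping source(s): ", paste(bad, collapse = ", "))
  regions <- unique(mapping$region)
  if (anyDuplicated(regions)) stop("region names must be unique")
  structure(list(regions = regions, mapping = mapping),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set>", length(x$regions), "regions:\n ",
      paste(x$regions, collapse = ", "), "\n")
  invisible(x)
}

#' Names of the volume columns for a region set
#'
#' Cohort tables store one absolute volume column per region, named
#' `vol_<region>_mm3`.
#'
#' @param regions Character vector of region names or a `region_set`.
#' @return Character vector of column names.
#' @export
region_columns <- function(regions = default_region_set()) {
  if (inherits(regions, "region_set")) regions <- regions$regions
  paste0("vol_", regions, "_mm3")
}
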