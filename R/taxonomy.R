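#' Three-level lung anatomy: lungs, lobes, bronchopulmonary segments
#'
#' The human lungs divide into 5 lobes (3 right, 2 left) and, by surgical
#' convention, 18 bronchopulmonary segments, each supplied by its own
#' tertiary (segmental) bronchus. On the left, B1/B2 and B7/B8 are fused
#' into single segments. `build_taxonomy()` returns this fixed anatomy as a
#' queryable object with stable integer codes used as voxel label values:
#' right B1..B10 are 1-10 (reading order RUL, RML, RLL) and the eight left
#' segments are 11-18 (LUL then LLL); 0 is reserved for background.
#'
#' @return An object of class `segment_taxonomy`: a list with
#'   \describe{
#'     \item{segments}{data frame with columns `code` (1-18), `short`
#'       (e.g. "B1/2"), `name` (anatomical name), `lobe`, `side`.}
#'     \item{lobes}{character vector `c("RUL","RML","RLL","LUL","LLL")`.}
#'   }
#' @examples
#' tax <- build_taxonomy()
#' segments_for_lobe(tax, "RML")
#' lobe_of(tax, 12)  # left B3 -> "LUL"
#' @export
build_taxonomy <- function() {
  segments <- data.frame(
    code = 1:18,
    short = c("B1", "B2", "B3", "B4", "B5",
              "B6", "B7", "B8", "B9", "B10",
              "B1/2", "B3", "B4", "B5",
              "B6", "B7/8", "B9", "B10"),
    name = c("Apical segment (B1)",
             "Posterior segment (B2)",
             "Anterior segment (B3)",
             "Lateral segment (B4)",
             "Medial segment (B5)",
             "Superior segment (B6)",
             "Medial basal segment (B7)",
             "Anterior basal segment (B8)",
             "Lateral basal segment (B9)",
             "Posterior basal segment (B10)",
             "Apicoposterior segment (B1/2)",
             "Anterior segment (B3)",
             "Superior lingular segment (B4)",
             "Inferior lingular segment (B5)",
             "Superior segment (B6)",
             "Anteromedial basal segment (B7/8)",
             "Lateral basal segment (B9)",
             "Posterior basal segment (B10)"),
    lobe = c(rep("RUL", 3), rep("RML", 2), rep("RLL", 5),
             rep("LUL", 4), rep("LLL", 4)),
    stringsAsFactors = FALSE
  )
  segments$side <- ifelse(substr(segments$lobe, 1, 1) == "R", "right", "left")
  structure(list(segments = segments,
                 lobes = c("RUL", "RML", "RLL", "LUL", "LLL")),
            class = "segment_taxonomy")
}

#' @export
print.segment_taxonomy <- function(x, ...) {
  cat("<segment_taxonomy> 18 bronchopulmonary segments across 5 lobes\n")
  for (lb in x$lobes) {
    s <- x$segments[x$segments$lobe == lb, ]
    cat(sprintf("  %s (%s): %s\n", lb, s$side[1],
                paste(sprintf("%d=%s", s$code, s$short), collapse = ", ")))
  }
  invisible(x)
}

#' Segments belonging to a lobe
#'
#' The hierarchical lobe/segment relationship is what caps the search space
#' of the nearest-bronchus assignment at five candidates per voxel (the
#' largest lobe, RLL, holds five segments).
#'
#' @param tax a [build_taxonomy()] object.
#' @param lobe one of `"RUL"`, `"RML"`, `"RLL"`, `"LUL"`, `"LLL"`.
#' @return Integer vector of segment codes in that lobe.
#' @export
segments_for_lobe <- function(tax, lobe) {
  stopifnot(inherits(tax, "segment_taxonomy"))
  if (length(lobe) != 1L || !lobe %in% tax$lobes)
    stop("unknown lobe id: '", paste(lobe, collapse = ","), "'")
  tax$segments$code[tax$segments$lobe == lobe]
}

#' Lobe containing a segment
#'
#' @param tax a [build_taxonomy()] object.
#' @param code segment code(s) in 1..18.
#' @return Character vector of lobe identifiers.
#' @export
lobe_of <- function(tax, code) {
  stopifnot(inherits(tax, "segment_taxonomy"))
  i <- match(code, tax$segments$code)
  if (anyNA(i)) stop("unknown segment code: ", paste(code[is.na(i)], collapse = ", "))
  tax$segments$lobe[i]
}

#' Lobe integer codes used in label volumes
#'
#' Lobe masks use 1=RUL, 2=RML, 3=RLL, 4=LUL, 5=LLL (0 background).
#'
#' @param tax a [build_taxonomy()] object.
#' @return Named integer vector mapping lobe id to label value.
#' @export
lobe_codes <- function(tax) {
  stopifnot(inherits(tax, "segment_taxonomy"))
  stats::setNames(seq_along(tax$lobes), tax$lobes)
}

#' Export the taxonomy as JSON
#'
#' Writes one record per segment (code, short name, full name, lobe, side)
#' for use as a label legend by downstream tools.
#'
#' @param tax a [build_taxonomy()] object.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
taxonomy_json <- function(tax, path = NULL) {
  stopifnot(inherits(tax, "segment_taxonomy"))
  js <- jsonlite::toJSON(tax$segments, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
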