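# Marker maps: ordered STR loci with physical (bp) and genetic (cM) positions
# under two genetic-map sources.

#' Build and validate a marker map
#'
#' A marker map is a tibble of ordered short-tandem-repeat (STR) loci with one
#' row per locus and columns `marker`, `chrom`, `pos_bp`, `cM_hapmap`,
#' `cM_rutgers`. Physical positions must be strictly increasing and genetic
#' positions non-decreasing within each map source. The position of the
#' disease locus itself (which is not one of the typed markers) is carried as
#' the `disease_bp` attribute and interpolated onto the genetic scale when
#' needed.
#'
#' @param x A data frame with the columns above.
#' @param disease_bp Physical position (bp) of the disease locus; must lie
#'   within the map.
#' @return A tibble of class `marker_map`.
#' @seealso [aip_marker_map()] for the bundled synthetic map.
#' @export
marker_map <- function(x, disease_bp) {
  x <- tibble::as_tibble(x)
  needed <- c("marker", "chrom", "pos_bp", "cM_hapmap", "cM_rutgers")
  if (!all(needed %in% names(x))) {
    abort(paste0("Marker map needs columns: ", paste(needed, collapse = ", ")))
  }
  if (nrow(x) < 2L) abort("A marker map needs at least 2 loci.")
  if (any(diff(x$pos_bp) <= 0)) abort("`pos_bp` must be strictly increasing.")
  for (src in c("cM_hapmap", "cM_rutgers")) {
    if (any(diff(x[[src]]) < 0)) abort(sprintf("`%s` must be non-decreasing.", src))
  }
  if (anyDuplicated(x$marker)) abort("Marker names must be unique.")
  disease_bp <- check_number(disease_bp, "disease_bp")
  if (disease_bp < min(x$pos_bp) || disease_bp > max(x$pos_bp)) {
    abort("`disease_bp` must lie within the mapped region.")
  }
  structure(x, disease_bp = disease_bp, class = c("marker_map", class(x)))
}

#' Synthetic 14-locus STR map around the AIP locus
#'
#' A synthetic marker map emulating a panel of 14 microsatellites spanning
#' 8.3 Mbp of chromosome 11q13.2 around *AIP*. Marker names are synthetic
#' placeholders (`STR01` ... `STR14`) apart from `D11S1249`, the locus at
#' which a within-haploblock repeat mutation is observed in the worked
#' example. Coordinates and centimorgan positions are synthetic but chosen so
#' that the conserved-haploblock geometry of the worked example is realistic:
#' the markers bracketing the core block lie 2.79 Mbp (1.83 cM on the HapMap
#' scale) apart and the nearest flanking markers 3.63 Mbp (2.59 cM) apart.
#'
#' @return A `marker_map` tibble with 14 rows.
#' @export
#' @examples
#' aip_marker_map()
aip_marker_map <- function() {
  m <- tibble::tibble(
    marker = c("STR01", "STR02", "STR03", "STR04", "STR05", "STR06",
               "D11S1249", "STR08", "STR09", "STR10", "STR11", "STR12",
               "STR13", "STR14"),
    chrom = "11",
    pos_bp = c(63100000, 64150000, 65000000, 65600000, 66000000, 66700000,
               67100000, 67600000, 68200000, 68790000, 69230000, 70000000,
               70700000, 71400000),
    cM_hapmap = c(0.00, 0.80, 1.45, 1.95, 2.31, 2.77, 3.03, 3.35, 3.74,
                  4.14, 4.54, 5.10, 5.62, 6.20),
    cM_rutgers = c(0.00, 0.74, 1.38, 1.86, 2.20, 2.64, 2.90, 3.20, 3.57,
                   3.97, 4.36, 4.88, 5.37, 5.90)
  )
  marker_map(m, disease_bp = 67250000)
}

# Genetic position (cM) of an arbitrary bp coordinate by linear interpolation
# between flanking markers.
map_cm_at <- function(map, bp, map_source = c("hapmap", "rutgers")) {
  map_source <- match.arg(map_source)
  col <- paste0("cM_", map_source)
  stats::approx(map$pos_bp, map[[col]], xout = bp, rule = 2, ties = "ordered")$y
}

# Distances (cM) from the disease locus to every marker, split by side, plus
# the flank extents to the ends of the typed region. Used by the ABC engine.
map_geometry <- function(map, map_source = c("hapmap", "rutgers")) {
  map_source <- match.arg(map_source)
  col <- paste0("cM_", map_source)
  d_cm <- map_cm_at(map, attr(map, "disease_bp"), map_source)
  off <- map[[col]] - d_cm
  list(
    disease_cm = d_cm,
    left_offsets = sort(-off[off < 0]),   # ascending distance to the left
    right_offsets = sort(off[off > 0]),   # ascending distance to the right
    flank_left = d_cm - min(map[[col]]),
    flank_right = max(map[[col]]) - d_cm,
    span_cm = max(map[[col]]) - min(map[[col]])
  )
}

#' Read / write a marker map as TSV
#'
#' The TSV schema is `marker`, `chrom`, `pos_bp`, `cM_hapmap`, `cM_rutgers`;
#' the disease-locus position travels in a `# disease_bp=` header comment so
#' that the file round-trips.
#'
#' @param map A `marker_map`.
#' @param path File path.
#' @return `read_marker_map()` returns a `marker_map`;
#'   `write_marker_map()` returns `path` invisibly.
#' @export
write_marker_map <- function(map, path) {
  writeLines(sprintf("# disease_bp=%.0f", attr(map, "disease_bp")), path)
  readr::write_tsv(tibble::as_tibble(map), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) {
  first <- readLines(path, n = 1L)
  disease_bp <- as.numeric(sub("# disease_bp=", "", first, fixed = TRUE))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(
                         marker = "c", chrom = "c", pos_bp = "d",
                         cM_hapmap = "d", cM_rutgers = "d"))
  marker_map(x, disease_bp = disease_bp)
}
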