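#' Peripapillary sector grid geometry
#'
#' The peripapillary chart is centred on the optic disc with circle diameters
#' of 1, 2 and 3 mm. The annulus between 1 and 2 mm ("inner ring", labelled
#' "2") and the annulus between 2 and 3 mm ("outer ring", labelled "3") are
#' each divided into four quadrants (superior, nasal, inferior, temporal),
#' giving eight sectors per eye. Thickness is recorded in micrometres,
#' volume in cubic millimetres.
#'
#' @name sector-grid
#' @keywords internal
NULL

#' @rdname sector-grid
#' @format NULL
.quadrants <- c("superior", "nasal", "inferior", "temporal")

#' @rdname sector-grid
#' @format NULL
.rings <- c(outer = "3", inner = "2")

#' Canonical sector labels
#'
#' Returns the eight sector labels in canonical order: outer ("3") then inner
#' ("2") within each quadrant, quadrants ordered superior, nasal, inferior,
#' temporal. These match the per-sector rows of the normative-range table
#' ("3-superior", "2-superior", ...).
#'
#' @return Character vector of length 8, e.g. `"3_superior"`.
#' @export
#' @examples
#' sector_labels()
sector_labels <- function() {
  as.vector(vapply(.quadrants, function(q) paste(c("3", "2"), q, sep = "_"),
                   character(2)))
}

#' Sector measurement column names
#'
#' @param measure `"trt"` (thickness, um) or `"trv"` (volume, mm^3).
#' @return Character vector of 8 cohort-CSV column names such as
#'   `"trt_3_superior"`.
#' @export
sector_columns <- function(measure = c("trt", "trv")) {
  measure <- match.arg(measure)
  paste(measure, sector_labels(), sep = "_")
}

#' Quadrant area of a peripapillary ring
#'
#' Area of one quadrant of the annulus: the inner ring lies between the 1 mm
#' and 2 mm circles, the outer ring between 2 mm and 3 mm.
#'
#' @param ring `"inner"` or `"outer"`.
#' @return Area in mm^2 (inner quadrant ~0.5890, outer quadrant ~0.9817).
#' @export
sector_area <- function(ring = c("inner", "outer")) {
  ring <- match.arg(ring)
  if (ring == "inner") pi * (1.0^2 - 0.5^2) / 4 else pi * (1.5^2 - 1.0^2) / 4
}

#' Convert sector thickness to sector volume
#'
#' Approximates the retinal volume of one sector as its mean thickness times
#' the quadrant's annular area. Used by the synthetic generator so that
#' thickness and volume stay geometrically coherent.
#'
#' @param thickness_um Sector mean thickness in micrometres (> 0).
#' @param ring `"inner"` or `"outer"`.
#' @return Volume in mm^3.
#' @export
#' @examples
#' sector_volume_from_thickness(378, "inner")  # ~0.223 mm^3
sector_volume_from_thickness <- function(thickness_um, ring = c("inner", "outer")) {
  ring <- match.arg(ring)
  stopifnot(all(thickness_um > 0, na.rm = TRUE))
  (thickness_um / 1000) * sector_area(ring)
}
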