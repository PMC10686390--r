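#' OCT scan geometry
#'
#' Describes the en-face raster of a volume OCT acquisition: number of
#' A-scans per B-scan, number of B-scans, axial samples, angular extent and
#' the retinal magnification used to convert visual degrees to millimetres.
#' All derived spacings are computed once and carried with the object.
#'
#' With the defaults (1024 x 97 raster over 20 x 20 degrees at 0.30 mm/deg)
#' the unit en-face pixel area is (6.0/1024) x (6.0/97) mm^2, i.e. 0.000362
#' mm^2 to three significant figures — the constant used when converting
#' summed A-scan thicknesses to volumes.
#'
#' @param n_ascan number of A-scans per B-scan (raster width).
#' @param n_bscan number of B-scans (raster height).
#' @param n_axial number of axial samples per A-scan (carried for metadata;
#'   the en-face pipeline does not use it).
#' @param extent_deg angular extent, length-2 `c(x, y)` in degrees.
#' @param mm_per_degree retinal magnification, mm per visual degree.
#' @return An object of class `scan_geometry`: a list with the inputs plus
#'   `extent_mm`, `ascan_spacing_mm`, `bscan_spacing_mm`, `pixel_area_mm2`.
#' @examples
#' g <- scan_geometry()
#' signif(g$pixel_area_mm2, 3)  # 0.000362
#' @export
scan_geometry <- function(n_ascan = 1024L, n_bscan = 97L, n_axial = 496L,
                          extent_deg = c(20, 20), mm_per_degree = 0.30) {
  n_ascan <- as.integer(n_ascan); n_bscan <- as.integer(n_bscan)
  n_axial <- as.integer(n_axial)
  if (length(extent_deg) == 1L) extent_deg <- rep(extent_deg, 2L)
  stopifnot(n_ascan > 0L, n_bscan > 0L, n_axial > 0L,
            length(extent_deg) == 2L, all(extent_deg > 0),
            is.numeric(mm_per_degree), mm_per_degree > 0)
  extent_mm <- extent_deg * mm_per_degree
  g <- list(
    n_ascan = n_ascan, n_bscan = n_bscan, n_axial = n_axial,
    extent_deg = as.numeric(extent_deg), mm_per_degree = mm_per_degree,
    extent_mm = extent_mm,
    ascan_spacing_mm = extent_mm[1] / n_ascan,
    bscan_spacing_mm = extent_mm[2] / n_bscan)
  g$pixel_area_mm2 <- g$ascan_spacing_mm * g$bscan_spacing_mm
  structure(g, class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("OCT scan geometry: %d A-scans x %d B-scans over %g x %g deg\n",
              x$n_ascan, x$n_bscan, x$extent_deg[1], x$extent_deg[2]))
  cat(sprintf("  mm/deg %.3f; spacing %.5f x %.5f mm; pixel area %.3g mm^2\n",
              x$mm_per_degree, x$ascan_spacing_mm, x$bscan_spacing_mm,
              x$pixel_area_mm2))
  invisible(x)
}

# default raster-centre fovea (0-based continuous pixel coordinates)
default_fovea_px <- function(geometry) {
  c(x = (geometry$n_ascan - 1) / 2, y = (geometry$n_bscan - 1) / 2)
}
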