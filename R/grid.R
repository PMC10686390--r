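#' Default 45-point high-density microperimetry stimulus grid
#'
#' Concentric-ring pattern emulating a high-density macular microperimetry
#' protocol: one central stimulus plus rings of 4, 8, 8, 12 and 12 points at
#' eccentricities 0.5, 1, 2, 3 and 4 degrees (45 stimuli in total, denser
#' towards the fovea, all within an 8-degree-diameter field). Coordinates
#' are degrees relative to the foveal centre; `+x` is image right, `+y`
#' superior.
#'
#' @return data.frame with columns `spot_id`, `x_deg`, `y_deg`, `ecc_deg`.
#' @examples
#' g <- mp_grid_default()
#' nrow(g)            # 45
#' max(g$ecc_deg)     # 4
#' @export
mp_grid_default <- function() {
  radii <- c(0.5, 1, 2, 3, 4)
  counts <- c(4L, 8L, 8L, 12L, 12L)
  xs <- 0; ys <- 0
  for (k in seq_along(radii)) {
    # stagger alternate rings so spokes do not line up
    ang <- 2 * pi * (seq_len(counts[k]) - 1) / counts[k] +
      if (k %% 2L == 0L) pi / counts[k] else 0
    xs <- c(xs, radii[k] * sin(ang))
    ys <- c(ys, radii[k] * cos(ang))
  }
  # snap values like 6.1e-17 to 0 for clean coordinates
  xs <- round(xs, 12); ys <- round(ys, 12)
  data.frame(spot_id = seq_along(xs), x_deg = xs, y_deg = ys,
             ecc_deg = sqrt(xs^2 + ys^2))
}

#' Read a custom stimulus grid from CSV
#'
#' @param path CSV with columns `spot_id`, `x_deg`, `y_deg`.
#' @return data.frame as [mp_grid_default()].
#' @export
mp_grid_read <- function(path) {
  g <- utils::read.csv(path)
  stopifnot(all(c("spot_id", "x_deg", "y_deg") %in% names(g)))
  if (anyDuplicated(g[, c("x_deg", "y_deg")]))
    stop("duplicate stimulus positions in grid")
  g$ecc_deg <- sqrt(g$x_deg^2 + g$y_deg^2)
  g
}

#' Eccentricity of stimulus positions
#'
#' Euclidean distance from the foveal centre, in degrees.
#'
#' @param x_deg,y_deg coordinates in degrees relative to the fovea.
#' @export
spot_eccentricity <- function(x_deg, y_deg) sqrt(x_deg^2 + y_deg^2)

#' Convert degree offsets from the fovea to raster pixel coordinates
#'
#' Continuous (unrounded) 0-based pixel coordinates; `x` indexes A-scans,
#' `y` B-scans, pixel centres at integer coordinates. Points falling outside
#' the raster are flagged, not dropped.
#'
#' @param x_deg,y_deg offsets from the fovea in degrees.
#' @param fovea_px length-2 `c(x, y)` foveal centre in raster pixels.
#' @param geometry a [scan_geometry()].
#' @return data.frame with `x_px`, `y_px`, `in_raster`.
#' @export
deg_to_px <- function(x_deg, y_deg, fovea_px, geometry) {
  stopifnot(inherits(geometry, "scan_geometry"), length(fovea_px) >= 2)
  x_px <- fovea_px[[1]] + x_deg * geometry$mm_per_degree / geometry$ascan_spacing_mm
  y_px <- fovea_px[[2]] + y_deg * geometry$mm_per_degree / geometry$bscan_spacing_mm
  data.frame(x_px = x_px, y_px = y_px,
             in_raster = x_px >= 0 & x_px <= geometry$n_ascan - 1 &
                         y_px >= 0 & y_px <= geometry$n_bscan - 1)
}

#' Convert raster pixel coordinates back to degree offsets from the fovea
#'
#' Inverse of [deg_to_px()].
#' @inheritParams deg_to_px
#' @param x_px,y_px raster coordinates.
#' @return data.frame with `x_deg`, `y_deg`.
#' @export
px_to_deg <- function(x_px, y_px, fovea_px, geometry) {
  data.frame(
    x_deg = (x_px - fovea_px[[1]]) * geometry$ascan_spacing_mm / geometry$mm_per_degree,
    y_deg = (y_px - fovea_px[[2]]) * geometry$bscan_spacing_mm / geometry$mm_per_degree)
}

#' Assign ETDRS grid sectors to stimulus positions
#'
#' Standard macular ETDRS subfields: central circle of 1 mm diameter
#' (sector 1), inner ring 1-3 mm and outer ring 3-6 mm diameter, each split
#' into superior/nasal/inferior/temporal quadrants on the +-45-degree
#' diagonals. Numbering: 1 centre; 2-5 inner S, N, I, T; 6-9 outer S, N, I,
#' T. `+x` is image right, which is nasal for right eyes (OD) and temporal
#' for left eyes (OS). Points beyond the 3 mm radius get `NA` ("outside").
#'
#' @param x_deg,y_deg stimulus offsets from the fovea, degrees.
#' @param laterality "OD" (right) or "OS" (left), recycled as needed.
#' @param mm_per_degree retinal magnification (default 0.30).
#' @return integer vector of sectors in 1..9, `NA` outside the 6 mm circle.
#' @export
etdrs_sector <- function(x_deg, y_deg, laterality = "OD", mm_per_degree = 0.30) {
  stopifnot(all(laterality %in% c("OD", "OS")))
  n <- max(length(x_deg), length(y_deg))
  laterality <- rep_len(laterality, n)
  x_mm <- x_deg * mm_per_degree
  y_mm <- y_deg * mm_per_degree
  r <- sqrt(x_mm^2 + y_mm^2)
  # mirror left eyes so +x is always nasal
  x_mm <- ifelse(laterality == "OS", -x_mm, x_mm)
  th <- atan2(y_mm, x_mm) * 180 / pi  # (-180, 180]
  quad <- integer(n)                  # 0=S, 1=N, 2=I, 3=T (after mirroring)
  quad[th > 45 & th <= 135] <- 0L
  quad[th > -45 & th <= 45] <- 1L
  quad[th > -135 & th <= -45] <- 2L
  quad[th > 135 | th <= -135] <- 3L
  sec <- ifelse(r < 0.5, 1L,
         ifelse(r < 1.5, 2L + quad,
         ifelse(r <= 3.0, 6L + quad, NA_integer_)))
  as.integer(sec)
}
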