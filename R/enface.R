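#' En-face thickness map container
#'
#' A `n_bscan x n_ascan` numeric matrix of per-A-scan thickness values (in
#' micrometres) with the scan geometry attached. Row index = B-scan (y),
#' column index = A-scan (x), both 0-based in coordinate conventions.
#'
#' @param values numeric matrix, `n_bscan` rows x `n_ascan` columns,
#'   non-negative and finite.
#' @param geometry a [scan_geometry()].
#' @return object of class `enface_map` (a matrix with attributes).
#' @export
enface_map <- function(values, geometry) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(geometry$n_bscan, geometry$n_ascan)))
    stop(sprintf("map shape %d x %d does not match geometry %d x %d",
                 nrow(values), ncol(values), geometry$n_bscan,
                 geometry$n_ascan))
  if (!all(is.finite(values))) stop("non-finite thickness values")
  if (any(values < 0)) stop("negative thickness values")
  structure(values, geometry = geometry, class = c("enface_map", "matrix"))
}

#' @export
print.enface_map <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf(
    "en-face thickness map %d x %d (um); range %.2f-%.2f, %.1f%% nonzero\n",
    nrow(x), ncol(x), min(x), max(x), 100 * mean(x > 0)))
  invisible(x)
}

#' Quantification configuration
#'
#' @param roi_diameter_um diameter of the circular region of interest
#'   centred at each stimulus (default 240 um, read as a diameter).
#' @param hrf_min_volume_mm3 detectability floor: ROI HRF volumes below
#'   this are set to 0 to rule out segmentation noise (default 6e-5 mm^3).
#' @return list of class `quant_config`.
#' @export
quant_config <- function(roi_diameter_um = 240, hrf_min_volume_mm3 = 6e-5) {
  stopifnot(roi_diameter_um > 0, hrf_min_volume_mm3 > 0)
  structure(list(roi_diameter_um = roi_diameter_um,
                 hrf_min_volume_mm3 = hrf_min_volume_mm3),
            class = "quant_config")
}

#' En-face drusen thickness from layer surfaces
#'
#' Drusen thickness per A-scan is the axial distance between the outer RPE
#' surface and Bruch's membrane, clamped at zero where segmentation
#' crossings would make it negative. Surfaces are axial positions in um,
#' increasing with depth, on the same raster.
#'
#' @param rpe_outer_um,bm_um numeric matrices (n_bscan x n_ascan) of axial
#'   surface positions in um.
#' @param geometry a [scan_geometry()].
#' @return an [enface_map()] of thickness in um.
#' @export
drusen_thickness_map <- function(rpe_outer_um, bm_um, geometry) {
  if (!all(dim(rpe_outer_um) == dim(bm_um)))
    stop("surface shapes differ")
  if (!all(is.finite(rpe_outer_um)) || !all(is.finite(bm_um)))
    stop("non-finite surface positions")
  enface_map(pmax(bm_um - rpe_outer_um, 0), geometry)
}

#' Circular region of interest on the anisotropic en-face raster
#'
#' Includes every raster cell whose centre lies within the ROI radius of
#' the (continuous) centre position, with distances measured in physical
#' millimetres so the anisotropic A-scan/B-scan spacings are respected.
#'
#' @param centre_px length-2 `c(x, y)` continuous raster coordinates.
#' @param geometry a [scan_geometry()].
#' @param config a [quant_config()] (its `roi_diameter_um` is used).
#' @return list of class `roi_mask`: `rows`, `cols` (1-based matrix
#'   indices, equal length), `centre_px`, `radius_um`, `n_cells`,
#'   `in_raster` (FALSE when the centre lies outside the raster, in which
#'   case the mask is empty).
#' @export
roi_mask <- function(centre_px, geometry, config = quant_config()) {
  cx <- centre_px[[1]]; cy <- centre_px[[2]]
  radius_mm <- config$roi_diameter_um / 2 / 1000
  in_raster <- cx >= 0 && cx <= geometry$n_ascan - 1 &&
               cy >= 0 && cy <= geometry$n_bscan - 1
  if (!in_raster) {
    return(structure(list(rows = integer(0), cols = integer(0),
                          centre_px = c(cx, cy),
                          radius_um = radius_mm * 1000, n_cells = 0L,
                          in_raster = FALSE), class = "roi_mask"))
  }
  dx <- geometry$ascan_spacing_mm; dy <- geometry$bscan_spacing_mm
  i_rng <- max(0L, ceiling(cx - radius_mm / dx)):
           min(geometry$n_ascan - 1L, floor(cx + radius_mm / dx))
  j_rng <- max(0L, ceiling(cy - radius_mm / dy)):
           min(geometry$n_bscan - 1L, floor(cy + radius_mm / dy))
  ii <- rep(i_rng, times = length(j_rng))
  jj <- rep(j_rng, each = length(i_rng))
  keep <- ((ii - cx) * dx)^2 + ((jj - cy) * dy)^2 <= radius_mm^2
  structure(list(rows = jj[keep] + 1L, cols = ii[keep] + 1L,
                 centre_px = c(cx, cy), radius_um = radius_mm * 1000,
                 n_cells = sum(keep), in_raster = TRUE),
            class = "roi_mask")
}

#' Aggregate lesion load within a region of interest
#'
#' `roi_volume` sums the per-A-scan thicknesses over the mask cells and
#' multiplies by the unit en-face pixel area (0.000362 mm^2 under the
#' default geometry), yielding mm^3. `roi_mean_thickness` averages the
#' thickness over all mask cells (zeros included), in um.
#' `hrf_roi_volume` applies the HRF detectability floor: raw ROI volumes
#' below `config$hrf_min_volume_mm3` are returned as 0.
#'
#' @param map an [enface_map()] (um).
#' @param mask an [roi_mask()].
#' @param config a [quant_config()] (floor for `hrf_roi_volume`).
#' @return volume in mm^3 (0 with attribute `empty_mask = TRUE` for an
#'   empty mask); `roi_mean_thickness` returns um, or `NA` for an empty
#'   mask.
#' @export
roi_volume <- function(map, mask) {
  g <- attr(map, "geometry")
  if (mask$n_cells == 0L)
    return(structure(0, empty_mask = TRUE))
  vals <- map[cbind(mask$rows, mask$cols)]
  sum(vals / 1000) * g$pixel_area_mm2
}

#' @rdname roi_volume
#' @export
roi_mean_thickness <- function(map, mask) {
  if (mask$n_cells == 0L) return(NA_real_)
  mean(map[cbind(mask$rows, mask$cols)])
}

#' @rdname roi_volume
#' @export
hrf_roi_volume <- function(map, mask, config = quant_config()) {
  v <- as.numeric(roi_volume(map, mask))
  if (v < config$hrf_min_volume_mm3) 0 else v
}

#' Extract the per-stimulus feature table from a simulated cohort
#'
#' Runs the measurement arm of the pipeline: per eye, estimate the
#' CFP-to-SLO affine from the (jittered) keypoints, map the stimulus grid
#' into the OCT raster through the marked foveal position and grid scaling,
#' then for every visit aggregate drusen and HRF ROI volumes and mean
#' thicknesses around each mapped stimulus, apply the HRF floor, attach
#' eccentricity, ETDRS sector and the staircase-measured sensitivity.
#'
#' Volumes are reported both in mm^3-derived model units of 1e-3 mm^3
#' (`drusen_vol_e3mm3`, `hrf_vol_e3mm3`) as used by the statistical models.
#'
#' @param cohort a cohort bundle from [simulate_cohort()].
#' @param config a [quant_config()].
#' @param use_true_transform bypass keypoint estimation and use the
#'   generator's ground-truth transforms (for diagnostics; default FALSE).
#' @return data.frame, one row per spot x visit (SpotRecord schema):
#'   `patient_id`, `eye_id`, `laterality`, `visit`, `spot_id`, `x_deg`,
#'   `y_deg`, `ecc_deg`, `sector`, `x_px`, `y_px`, `in_raster`,
#'   `sensitivity_db`, `drusen_vol_e3mm3`, `hrf_vol_e3mm3`,
#'   `drusen_mean_um`, `hrf_mean_um`, `drusen_present`, `hrf_present`.
#' @export
extract_spot_features <- function(cohort, config = quant_config(),
                                  use_true_transform = FALSE) {
  geometry <- cohort$geometry
  grid <- cohort$grid
  out <- vector("list", length(cohort$eyes))
  for (e in seq_along(cohort$eyes)) {
    eye <- cohort$eyes[[e]]
    if (use_true_transform) {
      tf <- eye$true_transform
    } else {
      kp <- cohort$keypoints[cohort$keypoints$eye_id == eye$eye_id, ]
      tf <- fit_affine(kp)
    }
    mapped <- map_grid_to_oct(grid, eye$fovea_cfp, eye$cfp_scale, tf,
                              geometry)
    masks <- lapply(seq_len(nrow(mapped)), function(k)
      roi_mask(c(mapped$x_px[k], mapped$y_px[k]), geometry, config))
    sector <- etdrs_sector(grid$x_deg, grid$y_deg, eye$laterality,
                           geometry$mm_per_degree)
    for (v in seq_len(eye$n_visits)) {
      dmap <- visit_map(eye, v, "drusen")
      hmap <- visit_map(eye, v, "hrf")
      dv <- vapply(masks, function(m) as.numeric(roi_volume(dmap, m)), 0)
      hv <- vapply(masks, function(m) hrf_roi_volume(hmap, m, config), 0)
      dmn <- vapply(masks, function(m) roi_mean_thickness(dmap, m), 0)
      hmn <- vapply(masks, function(m) roi_mean_thickness(hmap, m), 0)
      sens <- cohort$measurements$sensitivity_db[
        cohort$measurements$eye_id == eye$eye_id &
        cohort$measurements$visit == v - 1L]
      out[[e]] <- rbind(out[[e]], data.frame(
        patient_id = eye$patient_id, eye_id = eye$eye_id,
        laterality = eye$laterality, visit = v - 1L,
        spot_id = grid$spot_id, x_deg = grid$x_deg, y_deg = grid$y_deg,
        ecc_deg = grid$ecc_deg, sector = sector,
        x_px = mapped$x_px, y_px = mapped$y_px,
        in_raster = mapped$in_raster,
        sensitivity_db = sens,
        drusen_vol_e3mm3 = dv * 1000, hrf_vol_e3mm3 = hv * 1000,
        drusen_mean_um = dmn, hrf_mean_um = hmn,
        drusen_present = dv > 0, hrf_present = hv > 0))
    }
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  records
}
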