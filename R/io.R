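# Readers/writers for the pipeline's on-disk formats: en-face maps as
# single-channel 32-bit float TIFF (values stored in mm so they fit the
# writer's [0,1] range; a JSON sidecar records the unit scale and scan
# geometry), tables as UTF-8 comma-separated CSV with '.' decimal, and
# transforms/fits/manifests as JSON.

#' Write / read an en-face thickness map as TIFF + JSON sidecar
#'
#' The TIFF stores one 32-bit float sample per raster cell (row = B-scan,
#' column = A-scan) holding thickness divided by `scale_um` (default 1000,
#' i.e. values in mm); the sidecar `<path>.json` records `scale_um` and
#' the scan geometry so the map can be restored exactly.
#'
#' @param map an [enface_map()].
#' @param path output TIFF path.
#' @param scale_um divisor applied before writing (um per unit stored).
#' @return `path`, invisibly.
#' @export
write_enface_tiff <- function(map, path, scale_um = 1000) {
  g <- attr(map, "geometry")
  if (max(map) / scale_um > 1)
    stop("scale_um too small: scaled thickness exceeds 1")
  tiff::writeTIFF(unclass(map) / scale_um, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(
    list(scale_um = scale_um,
         geometry = unclass(g)[c("n_ascan", "n_bscan", "n_axial",
                                 "extent_deg", "mm_per_degree")],
         units = "um"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_enface_tiff
#' @export
read_enface_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- do.call(scan_geometry, side$geometry[c("n_ascan", "n_bscan",
                                              "n_axial", "extent_deg",
                                              "mm_per_degree")])
  vals <- tiff::readTIFF(path) * side$scale_um
  enface_map(vals, g)
}

#' Read an en-face thickness map from CSV
#'
#' Plain rectangular CSV of thickness values in um, `n_bscan` rows x
#' `n_ascan` columns, no header.
#'
#' @param path CSV path.
#' @param geometry a [scan_geometry()].
#' @export
read_enface_csv <- function(path, geometry) {
  vals <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(vals) <- NULL
  enface_map(vals, geometry)
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize an affine transform to JSON (and back)
#'
#' @param tf an `affine2d`.
#' @param path JSON path.
#' @export
write_affine_json <- function(tf, path) {
  jsonlite::write_json(
    list(A = as.numeric(tf$A), b = tf$b, from = tf$from, to = tf$to,
         rms = if (is.null(tf$rms)) NA else tf$rms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf <- affine2d(matrix(x$A, 2, 2), x$b, from = x$from, to = x$to)
  if (!is.null(x$rms) && !is.na(x$rms)) tf$rms <- x$rms
  tf
}

# fit report: coefficient table, variance components, AIC, convergence
fit_report_list <- function(fit) {
  co <- fit$coefficients
  list(terms = rownames(co),
       estimate = co$estimate, se = co$se, z = co$z, p = co$p,
       ci_lo = co$ci_lo, ci_hi = co$ci_hi,
       varcomp = as.list(fit$varcomp),
       AIC = fit$AIC, logLik = fit$logLik, n_obs = fit$n_obs,
       n_groups = as.list(fit$n_groups),
       converged = fit$converged, singular = fit$singular)
}

#' Write a model fit report as JSON and Markdown
#'
#' @param fit an `sf_fit`.
#' @param json_path,md_path output paths (either may be `NULL`).
#' @export
write_fit_report <- function(fit, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(fit_report_list(fit), json_path,
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(md_path)) {
    co <- fit$coefficients
    lines <- c("# Nested mixed model fit", "",
               sprintf("- observations: %d", fit$n_obs),
               sprintf("- groups: %d patients / %d eyes / %d spots",
                       fit$n_groups["patients"], fit$n_groups["eyes"],
                       fit$n_groups["spots"]),
               sprintf("- AIC: %.2f; converged: %s; singular: %s",
                       fit$AIC, fit$converged, fit$singular), "",
               "| term | estimate | SE | 95% CI | p |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.4f | %.4f | %.4f to %.4f | %.3g |",
                       rownames(co), co$estimate, co$se, co$ci_lo,
                       co$ci_hi, co$p), "",
               "Variance components (dB^2): ",
               paste(sprintf("%s = %.4f", names(fit$varcomp),
                             fit$varcomp), collapse = ", "))
    writeLines(lines, md_path)
  }
  invisible(fit)
}
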