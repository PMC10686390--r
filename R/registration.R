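#' Construct a 2D affine transform
#'
#' @param A 2x2 linear part (non-singular).
#' @param b length-2 translation.
#' @param from,to frame labels (free-form; checked when applying).
#' @return object of class `affine2d`.
#' @export
affine2d <- function(A, b = c(0, 0), from = "CFP", to = "SLO") {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < .Machine$double.eps * 100)
    stop("singular linear part in affine transform")
  structure(list(A = A, b = as.numeric(b), from = from, to = to),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat(sprintf("2D affine transform %s -> %s\n", x$from, x$to))
  m <- cbind(x$A, x$b); dimnames(m) <- list(c("x'", "y'"), c("x", "y", "1"))
  print(round(m, 6))
  if (!is.null(x$rms)) cat(sprintf("  fit RMS: %.4g px (%d keypoints)\n",
                                   x$rms, nrow(x$residuals)))
  invisible(x)
}

#' Estimate an affine transform from keypoint pairs by least squares
#'
#' Solves, via QR factorization, for the 6 affine parameters minimizing the
#' summed squared residuals in the target (SLO) frame over all keypoint
#' pairs. This mirrors landmark-based fundus-photo-to-SLO registration
#' where a user marks corresponding points (vessel branches) in both
#' images.
#'
#' @param pairs data.frame with columns `x_cfp`, `y_cfp`, `x_slo`, `y_slo`
#'   (pixels); at least 3 rows, source points not collinear.
#' @param from,to frame labels stored on the result.
#' @return `affine2d` with extra fields `residuals` (n x 2 matrix) and
#'   `rms` (root-mean-square point residual, px).
#' @examples
#' p <- data.frame(x_cfp = c(0, 1, 0, 1), y_cfp = c(0, 0, 1, 1))
#' p$x_slo <- 2 * p$x_cfp + 5; p$y_slo <- 2 * p$y_cfp - 3
#' fit_affine(p)$rms  # 0
#' @export
fit_affine <- function(pairs, from = "CFP", to = "SLO") {
  stopifnot(all(c("x_cfp", "y_cfp", "x_slo", "y_slo") %in% names(pairs)))
  n <- nrow(pairs)
  if (n < 3L) stop("need at least 3 keypoint pairs to estimate an affine")
  X <- cbind(pairs$x_cfp, pairs$y_cfp, 1)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("degenerate keypoint configuration: source points are collinear")
  Y <- cbind(pairs$x_slo, pairs$y_slo)
  beta <- qr.coef(qx, Y)              # 3 x 2: rows x, y, 1
  tf <- affine2d(t(beta[1:2, ]), beta[3, ], from = from, to = to)
  res <- Y - X %*% beta
  tf$residuals <- res
  tf$rms <- sqrt(mean(rowSums(res^2)))
  tf
}

#' Apply, invert and compose affine transforms
#'
#' `apply_affine` maps points (given as a 2-column matrix/data.frame or a
#' length-2 vector) through the transform; `invert_affine` returns the
#' inverse transform (frames swapped); `compose_affine(t2, t1)` returns the
#' transform equivalent to applying `t1` then `t2`.
#'
#' @param tf,t1,t2 `affine2d` objects.
#' @param pts points in the source frame.
#' @param frame optional frame label of `pts`; mismatch with `tf$from`
#'   raises an error.
#' @return matrix of transformed points (or `affine2d` for the other two).
#' @export
apply_affine <- function(tf, pts, frame = NULL) {
  stopifnot(inherits(tf, "affine2d"))
  if (!is.null(frame) && !identical(frame, tf$from))
    stop(sprintf("frame mismatch: points in '%s', transform expects '%s'",
                 frame, tf$from))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pts <- as.matrix(pts[, 1:2, drop = FALSE])
  sweep(pts %*% t(tf$A), 2, tf$b, "+")
}

#' @rdname apply_affine
#' @export
invert_affine <- function(tf) {
  Ai <- solve(tf$A)
  affine2d(Ai, -Ai %*% tf$b, from = tf$to, to = tf$from)
}

#' @rdname apply_affine
#' @export
compose_affine <- function(t2, t1) {
  affine2d(t2$A %*% t1$A, t2$A %*% t1$b + t2$b, from = t1$from, to = t2$to)
}

#' Map the stimulus grid into the OCT raster via an estimated transform
#'
#' Reproduces the manual alignment chain: stimulus offsets in degrees are
#' placed on the fundus photo using the marked foveal centre and the grid
#' scaling, then carried into the SLO/OCT en-face frame by the estimated
#' affine. Each spot is flagged in/out of the raster.
#'
#' @param grid stimulus grid (`spot_id`, `x_deg`, `y_deg`).
#' @param fovea_cfp length-2 foveal centre in CFP pixels.
#' @param cfp_scale grid scaling: scalar or length-2 (px per degree), or a
#'   2x2 matrix mapping degree offsets to CFP pixel offsets.
#' @param tf `affine2d` CFP -> SLO.
#' @param geometry [scan_geometry()] of the OCT raster.
#' @return data.frame `spot_id`, `x_px`, `y_px`, `in_raster`.
#' @export
map_grid_to_oct <- function(grid, fovea_cfp, cfp_scale, tf, geometry) {
  S <- if (is.matrix(cfp_scale)) cfp_scale else diag(rep_len(cfp_scale, 2L))
  d <- cbind(grid$x_deg, grid$y_deg) %*% t(S)
  cfp <- sweep(d, 2, as.numeric(fovea_cfp)[1:2], "+")
  slo <- apply_affine(tf, cfp)
  out <- data.frame(spot_id = grid$spot_id, x_px = slo[, 1], y_px = slo[, 2])
  out$in_raster <- out$x_px >= 0 & out$x_px <= geometry$n_ascan - 1 &
    out$y_px >= 0 & out$y_px <= geometry$n_bscan - 1
  if (!any(out$in_raster))
    stop("alignment failure: no stimulus maps inside the OCT raster")
  out
}
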