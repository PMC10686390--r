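#' Drusen field generator parameters
#'
#' The synthetic drusen field is a sum of isotropic (in physical mm) 2D
#' Gaussian elevation bumps with lognormal amplitudes and widths, centres
#' drawn from an isotropic Gaussian around the fovea (drusen load in
#' early/intermediate AMD concentrates foveally). Thickness below the
#' detection threshold `min_thickness_um` is set to 0, giving the field a
#' finite footprint as a segmentation algorithm would. An optional broad
#' low-amplitude background bump is available as an extra coverage knob
#' (off by default).
#'
#' @param n_bumps_mean Poisson mean of the number of bumps per eye.
#' @param amplitude_meanlog,amplitude_sdlog lognormal peak elevation (um).
#' @param sigma_meanlog,sigma_sdlog lognormal bump width sigma (degrees).
#' @param foveal_concentration_sd_deg radial SD of bump centres (degrees).
#' @param background_amplitude_um,background_sigma_deg optional broad
#'   background bump at the fovea (amplitude 0 disables it).
#' @param min_thickness_um detection threshold; values below are zeroed.
#' @param growth_rate_per_visit multiplicative volume growth per visit
#'   (>= 1; drusen volume grows over a 12-month follow-up).
#' @param growth_noise_sd lognormal SD of per-visit growth noise (0 = exact
#'   geometric growth).
#' @param truncation_sigmas bump support radius in sigmas (evaluation
#'   window; 4 keeps >99.96% of the analytic volume).
#' @return list of class `drusen_field_params`.
#' @export
drusen_field_params <- function(n_bumps_mean = 12.7,
                                amplitude_meanlog = log(40),
                                amplitude_sdlog = 0.8,
                                sigma_meanlog = log(0.35),
                                sigma_sdlog = 0.35,
                                foveal_concentration_sd_deg = 2.0,
                                background_amplitude_um = 0,
                                background_sigma_deg = 6,
                                min_thickness_um = 0.5,
                                growth_rate_per_visit = 1.05,
                                growth_noise_sd = 0,
                                truncation_sigmas = 4) {
  p <- as.list(environment())
  stopifnot(p$n_bumps_mean >= 0, p$amplitude_sdlog >= 0, p$sigma_sdlog >= 0,
            p$foveal_concentration_sd_deg > 0, p$min_thickness_um >= 0,
            p$growth_rate_per_visit >= 1, p$growth_noise_sd >= 0,
            p$truncation_sigmas > 0, p$background_amplitude_um >= 0)
  structure(p, class = "drusen_field_params")
}

#' HRF field generator parameters
#'
#' Hyperreflective foci are generated directly as sparse en-face thickness
#' blobs (small Gaussian profiles); no 3D voxel model or migration depth is
#' simulated. Blob centres are drawn with probability weighted towards
#' drusen-positive raster cells (HRF sit preferentially above drusen),
#' multiplied by a broad foveal placement prior.
#'
#' @param blob_rate Poisson mean number of HRF blobs per eye at baseline.
#' @param amplitude_meanlog,amplitude_sdlog lognormal peak thickness (um).
#' @param sigma_meanlog,sigma_sdlog lognormal blob width sigma (degrees).
#' @param colocalization_weight relative weight of drusen-positive cells
#'   when sampling blob centres (`Inf` restricts centres to drusen).
#' @param placement_sd_deg SD of the foveal placement prior (degrees).
#' @param min_thickness_um detection threshold (um).
#' @param growth_rate_per_visit,growth_noise_sd per-visit volume growth.
#' @param coverage_target nominal fraction of stimuli with post-floor HRF
#'   at baseline that the defaults are calibrated to (2.02%); recorded for
#'   configuration validation, not used by the sampler.
#' @param truncation_sigmas blob support radius in sigmas.
#' @return list of class `hrf_field_params`.
#' @export
hrf_field_params <- function(blob_rate = 2.15,
                             amplitude_meanlog = log(16),
                             amplitude_sdlog = 0.4,
                             sigma_meanlog = log(0.12),
                             sigma_sdlog = 0.25,
                             colocalization_weight = 20,
                             placement_sd_deg = 3.0,
                             min_thickness_um = 0.5,
                             growth_rate_per_visit = 1.08,
                             growth_noise_sd = 0,
                             coverage_target = 0.0202,
                             truncation_sigmas = 4) {
  p <- as.list(environment())
  stopifnot(p$blob_rate >= 0, p$colocalization_weight >= 0,
            p$placement_sd_deg > 0, p$growth_rate_per_visit >= 1,
            p$coverage_target >= 0, p$coverage_target < 1)
  structure(p, class = "hrf_field_params")
}

#' Generative fixed effects and variance components
#'
#' The linear model from which true per-spot sensitivities are produced:
#'
#'   S = intercept + b_visit * visit + b_ecc * ecc + b_drusen * Vd +
#'       b_hrf * Vh + b_dv * Vd * visit + b_de * Vd * ecc +
#'       u_patient + u_eye + u_spot + resid,       clamped to 0-34 dB,
#'
#' with volumes Vd, Vh in 1e-3 mm^3 units and nested Gaussian random
#' intercepts that are constant across visits (longitudinal correlation
#' enters only through them). Defaults mirror the cohort-level estimates
#' the generator is calibrated against; the intercept is calibrated so the
#' default cohort's baseline mean measured sensitivity is ~25.71 dB.
#'
#' @param intercept_db marginal intercept (dB).
#' @param beta_drusen,beta_hrf dB per 1e-3 mm^3 of local lesion volume.
#' @param beta_visit dB per visit (microperimetry learning effect).
#' @param beta_ecc dB per degree of eccentricity.
#' @param beta_drusen_visit,beta_drusen_ecc interaction coefficients.
#' @param sd_patient,sd_eye,sd_spot,sd_resid nested random-intercept and
#'   residual SDs (dB, >= 0).
#' @return list of class `true_effects`.
#' @export
true_effects <- function(intercept_db = 26.45,
                         beta_drusen = -0.991, beta_hrf = -5.230,
                         beta_visit = 0.242, beta_ecc = 0.086,
                         beta_drusen_visit = -0.02,
                         beta_drusen_ecc = -0.02,
                         sd_patient = 1.5, sd_eye = 1.0,
                         sd_spot = 1.5, sd_resid = 1.0) {
  p <- as.list(environment())
  stopifnot(p$sd_patient >= 0, p$sd_eye >= 0, p$sd_spot >= 0,
            p$sd_resid >= 0)
  structure(p, class = "true_effects")
}

# evaluate one Gaussian bump into a thickness matrix (um), physical-mm
# metric on the anisotropic raster, truncated at trunc*sigma
add_bump <- function(mat, geometry, cx_px, cy_px, amp_um, sigma_mm, trunc) {
  dx <- geometry$ascan_spacing_mm; dy <- geometry$bscan_spacing_mm
  rx <- trunc * sigma_mm / dx; ry <- trunc * sigma_mm / dy
  i0 <- max(0L, ceiling(cx_px - rx)); i1 <- min(geometry$n_ascan - 1L, floor(cx_px + rx))
  j0 <- max(0L, ceiling(cy_px - ry)); j1 <- min(geometry$n_bscan - 1L, floor(cy_px + ry))
  if (i0 > i1 || j0 > j1) return(mat)
  ii <- i0:i1; jj <- j0:j1
  ddx2 <- ((ii - cx_px) * dx)^2
  ddy2 <- ((jj - cy_px) * dy)^2
  r2 <- outer(ddy2, ddx2, "+")
  sub <- amp_um * exp(-r2 / (2 * sigma_mm^2))
  sub[r2 > (trunc * sigma_mm)^2] <- 0
  mat[jj + 1L, ii + 1L] <- mat[jj + 1L, ii + 1L] + sub
  mat
}

#' Simulate an en-face drusen thickness field
#'
#' @param geometry a [scan_geometry()].
#' @param params [drusen_field_params()].
#' @param seed integer seed; output is deterministic given it.
#' @param fovea_px foveal centre (default raster centre).
#' @return an [enface_map()] of drusen thickness (um).
#' @export
simulate_drusen_field <- function(geometry, params = drusen_field_params(),
                                  seed = 1L,
                                  fovea_px = default_fovea_px(geometry)) {
  stopifnot(inherits(params, "drusen_field_params"))
  old <- local_seed(seed); on.exit(restore_seed(old))
  mat <- matrix(0, geometry$n_bscan, geometry$n_ascan)
  n <- stats::rpois(1, params$n_bumps_mean)
  if (n > 0) {
    cx_deg <- stats::rnorm(n, 0, params$foveal_concentration_sd_deg)
    cy_deg <- stats::rnorm(n, 0, params$foveal_concentration_sd_deg)
    amp <- stats::rlnorm(n, params$amplitude_meanlog, params$amplitude_sdlog)
    sig_deg <- stats::rlnorm(n, params$sigma_meanlog, params$sigma_sdlog)
    ctr <- deg_to_px(cx_deg, cy_deg, fovea_px, geometry)
    for (k in seq_len(n)) {
      mat <- add_bump(mat, geometry, ctr$x_px[k], ctr$y_px[k], amp[k],
                      sig_deg[k] * geometry$mm_per_degree,
                      params$truncation_sigmas)
    }
  }
  if (params$background_amplitude_um > 0) {
    mat <- add_bump(mat, geometry, fovea_px[[1]], fovea_px[[2]],
                    params$background_amplitude_um,
                    params$background_sigma_deg * geometry$mm_per_degree,
                    params$truncation_sigmas)
  }
  mat[mat < params$min_thickness_um] <- 0
  enface_map(mat, geometry)
}

#' Simulate a sparse en-face HRF thickness field
#'
#' @param geometry a [scan_geometry()].
#' @param drusen_map drusen [enface_map()] on the same raster (placement
#'   weighting).
#' @param params [hrf_field_params()].
#' @param seed integer seed.
#' @param fovea_px foveal centre (default raster centre).
#' @return an [enface_map()] of HRF thickness (um).
#' @export
simulate_hrf_field <- function(geometry, drusen_map,
                               params = hrf_field_params(), seed = 1L,
                               fovea_px = default_fovea_px(geometry)) {
  stopifnot(inherits(params, "hrf_field_params"))
  if (!all(dim(drusen_map) == c(geometry$n_bscan, geometry$n_ascan)))
    stop("drusen map raster does not match geometry")
  old <- local_seed(seed); on.exit(restore_seed(old))
  mat <- matrix(0, geometry$n_bscan, geometry$n_ascan)
  n <- stats::rpois(1, params$blob_rate)
  if (n > 0) {
    # placement weights: foveal prior x drusen colocalization
    ii <- 0:(geometry$n_ascan - 1L); jj <- 0:(geometry$n_bscan - 1L)
    xdeg <- (ii - fovea_px[[1]]) * geometry$ascan_spacing_mm / geometry$mm_per_degree
    ydeg <- (jj - fovea_px[[2]]) * geometry$bscan_spacing_mm / geometry$mm_per_degree
    prior <- exp(-outer(ydeg^2, xdeg^2, "+") / (2 * params$placement_sd_deg^2))
    w <- if (is.infinite(params$colocalization_weight)) {
      pw <- prior * (drusen_map > 0)
      if (all(pw == 0)) stop(
        "colocalization_weight = Inf with an empty drusen map: no support")
      pw
    } else prior * (1 + params$colocalization_weight * (drusen_map > 0))
    cells <- sample.int(length(w), n, replace = TRUE, prob = as.numeric(w))
    cy <- (cells - 1L) %% geometry$n_bscan          # row index, 0-based
    cx <- (cells - 1L) %/% geometry$n_bscan         # col index, 0-based
    amp <- stats::rlnorm(n, params$amplitude_meanlog, params$amplitude_sdlog)
    sig_deg <- stats::rlnorm(n, params$sigma_meanlog, params$sigma_sdlog)
    for (k in seq_len(n)) {
      mat <- add_bump(mat, geometry, cx[k], cy[k], amp[k],
                      sig_deg[k] * geometry$mm_per_degree,
                      params$truncation_sigmas)
    }
  }
  mat[mat < params$min_thickness_um] <- 0
  enface_map(mat, geometry)
}

#' Advance an eye state by one visit
#'
#' Scales the drusen and HRF maps by their per-visit growth factors
#' (optionally with lognormal noise) and increments the visit counter.
#' Random intercepts are unchanged across visits.
#'
#' @param state an eye state (as found in `simulate_cohort()$eyes`).
#' @param drusen_growth,hrf_growth multiplicative growth factors (>= 1).
#' @param noise_sd lognormal SD of growth noise (0 = exact).
#' @param seed seed for the growth noise.
#' @return the updated eye state.
#' @export
advance_visit <- function(state, drusen_growth = 1.05, hrf_growth = 1.08,
                          noise_sd = 0, seed = 1L) {
  stopifnot(drusen_growth >= 1, hrf_growth >= 1, noise_sd >= 0)
  fd <- drusen_growth; fh <- hrf_growth
  if (noise_sd > 0) {
    old <- local_seed(seed); on.exit(restore_seed(old))
    fd <- fd * stats::rlnorm(1, -noise_sd^2 / 2, noise_sd)
    fh <- fh * stats::rlnorm(1, -noise_sd^2 / 2, noise_sd)
  }
  nv <- state$n_visits + 1L
  state$drusen_factors <- c(state$drusen_factors,
                            state$drusen_factors[state$n_visits] * fd)
  state$hrf_factors <- c(state$hrf_factors,
                         state$hrf_factors[state$n_visits] * fh)
  state$n_visits <- nv
  state
}

#' Materialize the en-face map of a given visit
#'
#' Reconstructs the drusen or HRF [enface_map()] of visit `visit`
#' (1-based) from an eye state's baseline field and its cumulative growth
#' factor.
#'
#' @param state an eye state from [simulate_cohort()].
#' @param visit 1-based visit index (`<= state$n_visits`).
#' @param which `"drusen"` or `"hrf"`.
#' @export
visit_map <- function(state, visit, which = c("drusen", "hrf")) {
  which <- match.arg(which)
  base <- if (which == "drusen") state$drusen_base else state$hrf_base
  f <- if (which == "drusen") state$drusen_factors[visit]
       else state$hrf_factors[visit]
  g <- attr(base, "geometry")
  enface_map(unclass(base) * f, g)
}

#' True sensitivity under the generative linear model
#'
#' Vectorized linear predictor of the generative structure-function model,
#' clamped to the instrument's 0-34 dB dynamic range.
#'
#' @param drusen_vol_e3mm3,hrf_vol_e3mm3 local ROI volumes, 1e-3 mm^3
#'   (HRF after the detectability floor).
#' @param ecc_deg eccentricity (degrees).
#' @param visit 0-based visit index.
#' @param effects a [true_effects()].
#' @param u summed random intercepts (u_patient + u_eye + u_spot), dB.
#' @param resid per-observation residual, dB.
#' @return sensitivity in dB, clamped to `[0, 34]`.
#' @export
true_sensitivity <- function(drusen_vol_e3mm3, hrf_vol_e3mm3, ecc_deg,
                             visit, effects = true_effects(), u = 0,
                             resid = 0) {
  lp <- effects$intercept_db +
    effects$beta_visit * visit +
    effects$beta_ecc * ecc_deg +
    effects$beta_drusen * drusen_vol_e3mm3 +
    effects$beta_hrf * hrf_vol_e3mm3 +
    effects$beta_drusen_visit * drusen_vol_e3mm3 * visit +
    effects$beta_drusen_ecc * drusen_vol_e3mm3 * ecc_deg +
    u + resid
  pmin(34, pmax(0, lp))
}

#' Cohort configuration
#'
#' Defaults mirror the emulated study: 35 patients contributing 51 eyes,
#' up to 5 quarterly visits, a 45-point stimulus grid, and generator
#' settings calibrated so that at baseline ~73.47% of stimuli overlie
#' drusen, ~2.02% overlie (post-floor) HRF, and mean measured sensitivity
#' is ~25.71 dB.
#'
#' @param n_patients,n_eyes,n_visits cohort shape (`n_patients <= n_eyes
#'   <= 2 * n_patients`).
#' @param geometry,grid,drusen,hrf,effects,quant component configurations.
#' @param observer staircase observer noise: list with `slope_sd_db`,
#'   `false_pos_rate`, `false_neg_rate`, `start_level_db`.
#' @param registration ground-truth transform family and keypoint set-up:
#'   list with `n_keypoints`, `keypoint_jitter_px`, `rot_max_deg`,
#'   `scale_range`, `trans_max_px`.
#' @param coverage_targets nominal calibration targets (fractions/dB),
#'   used by configuration validation.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 35L, n_eyes = 51L, n_visits = 5L,
                          geometry = scan_geometry(),
                          grid = mp_grid_default(),
                          drusen = drusen_field_params(),
                          hrf = hrf_field_params(),
                          effects = true_effects(),
                          quant = quant_config(),
                          observer = list(slope_sd_db = 0.5,
                                          false_pos_rate = 0.03,
                                          false_neg_rate = 0.03,
                                          start_level_db = 17),
                          registration = list(n_keypoints = 6L,
                                              keypoint_jitter_px = 0.5,
                                              rot_max_deg = 5,
                                              scale_range = c(0.9, 1.1),
                                              trans_max_px = 50),
                          coverage_targets = list(drusen = 0.7347,
                                                  hrf = 0.0202,
                                                  mean_sensitivity_db = 25.71)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1L, cfg$n_eyes >= cfg$n_patients,
            cfg$n_eyes <= 2L * cfg$n_patients, cfg$n_visits >= 1L,
            cfg$n_visits <= 5L)
  structure(cfg, class = "cohort_config")
}

# ground-truth CFP->SLO affine: rotation, per-axis scale, translation
draw_true_transform <- function(reg) {
  th <- stats::runif(1, -reg$rot_max_deg, reg$rot_max_deg) * pi / 180
  sx <- stats::runif(1, reg$scale_range[1], reg$scale_range[2])
  sy <- stats::runif(1, reg$scale_range[1], reg$scale_range[2])
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R %*% diag(c(sx, sy))
  b <- stats::runif(2, -reg$trans_max_px, reg$trans_max_px)
  affine2d(A, b, from = "CFP", to = "SLO")
}

# well-spread SLO landmark positions (vessel-branch stand-ins)
keypoint_sites <- function(geometry, n) {
  fx <- c(0.11, 0.89, 0.11, 0.89, 0.50, 0.50, 0.30, 0.70, 0.30, 0.70)
  fy <- c(0.12, 0.12, 0.87, 0.87, 0.50, 0.17, 0.72, 0.30, 0.30, 0.72)
  n <- min(n, length(fx))
  cbind(fx[1:n] * (geometry$n_ascan - 1), fy[1:n] * (geometry$n_bscan - 1))
}

#' Simulate a complete synthetic cohort
#'
#' Generates, per eye: baseline drusen and HRF fields, per-visit growth,
#' nested random intercepts, a ground-truth CFP-to-SLO affine with
#' (jittered) keypoint pairs, true per-spot sensitivities from the
#' generative linear model evaluated on ROI volumes at the ground-truth
#' stimulus positions, and staircase-measured sensitivities.
#'
#' @param config a [cohort_config()].
#' @param seed master seed; the full bundle is deterministic given it.
#' @return list of class `mp_cohort` with elements `geometry`, `grid`,
#'   `quant`, `eyes` (list of eye states), `keypoints` (data.frame),
#'   `measurements` (eye x visit x spot measured sensitivities),
#'   `truth` (true volumes, linear predictor and sensitivity per row),
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  geometry <- config$geometry; grid <- config$grid
  n_spots <- nrow(grid)
  fovea_px <- default_fovea_px(geometry)
  eff <- config$effects

  # eye -> patient assignment: first (n_eyes - n_patients) patients
  # contribute both eyes
  n_second <- config$n_eyes - config$n_patients
  patient_of_eye <- c(seq_len(config$n_patients),
                      seq_len(n_second))
  laterality <- c(rep("OD", config$n_patients), rep("OS", n_second))
  ord <- order(patient_of_eye, laterality)
  patient_of_eye <- patient_of_eye[ord]; laterality <- laterality[ord]

  u_patient <- vapply(seq_len(config$n_patients), function(p) {
    old <- local_seed(derive_seed(seed, 1L, p)); on.exit(restore_seed(old))
    stats::rnorm(1, 0, eff$sd_patient)
  }, 0)

  # true stimulus positions and ROI masks (fovea at raster centre)
  true_px <- deg_to_px(grid$x_deg, grid$y_deg, fovea_px, geometry)
  masks <- lapply(seq_len(n_spots), function(k)
    roi_mask(c(true_px$x_px[k], true_px$y_px[k]), geometry, config$quant))

  D <- diag(c(geometry$mm_per_degree / geometry$ascan_spacing_mm,
              geometry$mm_per_degree / geometry$bscan_spacing_mm))

  eyes <- vector("list", config$n_eyes)
  kp_list <- vector("list", config$n_eyes)
  meas_list <- vector("list", config$n_eyes)
  truth_list <- vector("list", config$n_eyes)

  for (e in seq_len(config$n_eyes)) {
    pid <- patient_of_eye[e]
    drusen_base <- simulate_drusen_field(geometry, config$drusen,
                                         derive_seed(seed, 2L, e), fovea_px)
    hrf_base <- simulate_hrf_field(geometry, drusen_base, config$hrf,
                                   derive_seed(seed, 3L, e), fovea_px)

    old <- local_seed(derive_seed(seed, 4L, e))
    u_eye <- stats::rnorm(1, 0, eff$sd_eye)
    u_spot <- stats::rnorm(n_spots, 0, eff$sd_spot)
    tf_true <- draw_true_transform(config$registration)
    kp_slo_true <- keypoint_sites(geometry, config$registration$n_keypoints)
    kp_slo_true <- kp_slo_true +
      cbind(stats::runif(nrow(kp_slo_true), -20, 20),
            stats::runif(nrow(kp_slo_true), -6, 6))
    kp_jit <- matrix(stats::rnorm(length(kp_slo_true), 0,
                                  config$registration$keypoint_jitter_px),
                     ncol = 2)
    restore_seed(old)

    tf_inv <- invert_affine(tf_true)
    kp_cfp <- apply_affine(tf_inv, kp_slo_true)
    fovea_cfp <- as.numeric(apply_affine(tf_inv, fovea_px))
    cfp_scale <- solve(tf_true$A) %*% D

    state <- list(patient_id = pid, eye_id = e,
                  laterality = laterality[e],
                  drusen_base = drusen_base, hrf_base = hrf_base,
                  drusen_factors = 1, hrf_factors = 1, n_visits = 1L,
                  fovea_px = fovea_px, true_transform = tf_true,
                  fovea_cfp = fovea_cfp, cfp_scale = cfp_scale,
                  u_patient = u_patient[pid], u_eye = u_eye,
                  u_spot = u_spot)
    for (v in seq_len(config$n_visits - 1L)) {
      state <- advance_visit(state,
                             config$drusen$growth_rate_per_visit,
                             config$hrf$growth_rate_per_visit,
                             max(config$drusen$growth_noise_sd,
                                 config$hrf$growth_noise_sd),
                             derive_seed(seed, 5L, e, v))
    }

    kp_list[[e]] <- data.frame(eye_id = e, visit = 0L,
                               x_cfp = kp_cfp[, 1], y_cfp = kp_cfp[, 2],
                               x_slo = kp_slo_true[, 1] + kp_jit[, 1],
                               y_slo = kp_slo_true[, 2] + kp_jit[, 2])

    # baseline true ROI volumes; growth scales them per visit
    dvol0 <- vapply(masks, function(m)
      as.numeric(roi_volume(drusen_base, m)), 0)
    hraw0 <- vapply(masks, function(m)
      as.numeric(roi_volume(hrf_base, m)), 0)

    for (v in seq_len(config$n_visits)) {
      dvol <- dvol0 * state$drusen_factors[v]
      hraw <- hraw0 * state$hrf_factors[v]
      hvol <- ifelse(hraw < config$quant$hrf_min_volume_mm3, 0, hraw)
      old <- local_seed(derive_seed(seed, 6L, e, v))
      resid <- stats::rnorm(n_spots, 0, eff$sd_resid)
      restore_seed(old)
      tt <- true_sensitivity(dvol * 1000, hvol * 1000, grid$ecc_deg,
                             v - 1L, eff,
                             u = state$u_patient + u_eye + u_spot,
                             resid = resid)
      meas <- simulate_exam(tt, config$observer$slope_sd_db,
                            config$observer$false_pos_rate,
                            config$observer$false_neg_rate,
                            seed = derive_seed(seed, 7L, e, v),
                            start_level_db = config$observer$start_level_db)
      meas_list[[e]] <- rbind(meas_list[[e]], data.frame(
        eye_id = e, visit = v - 1L, spot_id = grid$spot_id,
        sensitivity_db = meas))
      truth_list[[e]] <- rbind(truth_list[[e]], data.frame(
        eye_id = e, visit = v - 1L, spot_id = grid$spot_id,
        true_drusen_vol_e3mm3 = dvol * 1000,
        true_hrf_vol_e3mm3 = hvol * 1000,
        true_sensitivity_db = tt))
    }
    eyes[[e]] <- state
  }

  structure(list(geometry = geometry, grid = grid, quant = config$quant,
                 eyes = eyes,
                 keypoints = do.call(rbind, kp_list),
                 measurements = do.call(rbind, meas_list),
                 truth = do.call(rbind, truth_list),
                 config = config, seed = seed),
            class = "mp_cohort")
}

#' @export
print.mp_cohort <- function(x, ...) {
  base <- x$measurements[x$measurements$visit == 0L, ]
  cat(sprintf(
    "synthetic microperimetry-OCT cohort: %d eyes / %d patients, %d visits\n",
    length(x$eyes), x$config$n_patients, x$config$n_visits))
  cat(sprintf("  %d stimulus records; baseline mean sensitivity %.2f dB\n",
              nrow(x$measurements), mean(base$sensitivity_db)))
  invisible(x)
}
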