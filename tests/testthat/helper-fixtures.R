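# shared fixtures, all generated in code

small_cohort_config <- function(n_patients = 5L, n_eyes = 8L,
                                n_visits = 3L, ...) {
  cohort_config(n_patients = n_patients, n_eyes = n_eyes,
                n_visits = n_visits, ...)
}

# simulate a SpotRecord-shaped table directly from the linear mixed model
# (no imaging, no clamp, no staircase) — used to test the inference stage
# in isolation against known generative values
sim_model_table <- function(n_patients = 10L, n_eyes = 16L, n_visits = 2L,
                            effects = true_effects(), seed = 1L,
                            hrf_cov = 0.05, sector_effects = NULL) {
  set.seed(seed)
  grid <- mp_grid_default()
  n_spots <- nrow(grid)
  n_second <- n_eyes - n_patients
  patient_of_eye <- c(seq_len(n_patients), seq_len(n_second))
  up <- rnorm(n_patients, 0, effects$sd_patient)
  rows <- list()
  for (e in seq_len(n_eyes)) {
    ue <- rnorm(1, 0, effects$sd_eye)
    us <- rnorm(n_spots, 0, effects$sd_spot)
    vd0 <- ifelse(runif(n_spots) < 0.73, rlnorm(n_spots, log(0.4), 1), 0)
    vh0 <- ifelse(runif(n_spots) < hrf_cov,
                  0.06 + rlnorm(n_spots, log(0.05), 0.5), 0)
    lat <- if (e <= n_patients) "OD" else "OS"
    sector <- etdrs_sector(grid$x_deg, grid$y_deg, lat)
    for (v in seq_len(n_visits) - 1L) {
      vd <- vd0 * 1.05^v; vh <- vh0 * 1.08^v
      lp <- effects$intercept_db + effects$beta_visit * v +
        effects$beta_ecc * grid$ecc_deg +
        effects$beta_drusen * vd + effects$beta_hrf * vh +
        effects$beta_drusen_visit * vd * v +
        effects$beta_drusen_ecc * vd * grid$ecc_deg
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_of_eye[e], eye_id = e, laterality = lat,
        visit = v, spot_id = grid$spot_id, ecc_deg = grid$ecc_deg,
        sector = sector, in_raster = TRUE,
        sensitivity_db = lp + up[patient_of_eye[e]] + ue + us +
          rnorm(n_spots, 0, effects$sd_resid),
        drusen_vol_e3mm3 = vd, hrf_vol_e3mm3 = vh,
        drusen_present = vd > 0, hrf_present = vh > 0)
    }
  }
  do.call(rbind, rows)
}

# brute-force ROI accumulation over the whole raster (independent oracle)
brute_roi <- function(map, centre_px, radius_um) {
  g <- attr(map, "geometry")
  acc_vol <- 0; acc_sum <- 0; n <- 0L
  r_mm <- radius_um / 1000
  for (j in seq_len(g$n_bscan)) {
    for (i in seq_len(g$n_ascan)) {
      d2 <- ((i - 1 - centre_px[1]) * g$ascan_spacing_mm)^2 +
            ((j - 1 - centre_px[2]) * g$bscan_spacing_mm)^2
      if (d2 <= r_mm^2) {
        acc_vol <- acc_vol + map[j, i] / 1000 * g$pixel_area_mm2
        acc_sum <- acc_sum + map[j, i]
        n <- n + 1L
      }
    }
  }
  list(volume = acc_vol, mean = if (n) acc_sum / n else NA_real_, n = n)
}
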