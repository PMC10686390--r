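geom <- scan_geometry()

test_that("an empty drusen configuration yields an all-zero field", {
  p <- drusen_field_params(n_bumps_mean = 0, background_amplitude_um = 0)
  m <- simulate_drusen_field(geom, p, seed = 1)
  expect_true(all(m == 0))
})

test_that("a single Gaussian bump integrates to its closed-form volume", {
  # one bump, amplitude 100 um, sigma 0.5 deg, centred mid-raster:
  # discrete sum x pixel area within 1% of 2*pi*sigma_mm^2*A
  add <- function(sigma_deg, min_um, trunc) {
    p <- drusen_field_params(n_bumps_mean = 0, min_thickness_um = min_um,
                             truncation_sigmas = trunc)
    m <- matrix(0, 97, 1024)
    m <- mpstruct:::add_bump(m, geom, 511.5, 48, 100,
                             sigma_deg * geom$mm_per_degree, trunc)
    m[m < min_um] <- 0
    sum(m / 1000) * geom$pixel_area_mm2
  }
  analytic <- function(sigma_deg)
    2 * pi * (sigma_deg * geom$mm_per_degree)^2 * 100 / 1000
  expect_lt(abs(add(0.5, 0.5, 4) / analytic(0.5) - 1), 0.01)
  # with no detection threshold and wide support the match tightens
  expect_lt(abs(add(0.5, 0, 6) / analytic(0.5) - 1), 1e-3)
  # holds across widths resolvable by the B-scan spacing
  for (s in c(0.3, 0.7, 1.0))
    expect_lt(abs(add(s, 0.5, 4) / analytic(s) - 1), 0.01)
})

test_that("drusen fields are deterministic given the seed and non-negative", {
  a <- simulate_drusen_field(geom, seed = 7)
  b <- simulate_drusen_field(geom, seed = 7)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(a >= 0))
  expect_false(identical(unclass(a),
                         unclass(simulate_drusen_field(geom, seed = 8))))
})

test_that("HRF generation respects rate, support and colocalization", {
  dm <- simulate_drusen_field(geom, seed = 3)
  none <- simulate_hrf_field(geom, dm,
                             hrf_field_params(blob_rate = 0), seed = 1)
  expect_true(all(none == 0))
  expect_error(simulate_hrf_field(geom, matrix(0, 5, 5)), "raster")
  # infinite colocalization weight: every blob centre on drusen
  p_inf <- hrf_field_params(blob_rate = 12,
                            colocalization_weight = Inf,
                            sigma_meanlog = log(0.03),
                            truncation_sigmas = 1.01)
  h <- simulate_hrf_field(geom, dm, p_inf, seed = 5)
  peaks <- which(unclass(h) > 0.9 * max(h), arr.ind = TRUE)
  expect_true(all(dm[peaks] > 0))
  expect_error(simulate_hrf_field(geom, enface_map(matrix(0, 97, 1024),
                                                   geom),
                                  p_inf, seed = 1), "empty drusen map")
})

test_that("growth scales maps exactly and compounds across visits", {
  cfg <- small_cohort_config(n_patients = 2L, n_eyes = 2L, n_visits = 1L)
  co <- simulate_cohort(cfg, seed = 9)
  st <- co$eyes[[1]]
  v0_d <- sum(visit_map(st, 1, "drusen"))
  # growth 1.0: unchanged
  st1 <- advance_visit(st, drusen_growth = 1, hrf_growth = 1)
  expect_equal(sum(visit_map(st1, 2, "drusen")), v0_d)
  expect_identical(unclass(visit_map(st1, 2, "hrf")),
                   unclass(visit_map(st1, 1, "hrf")))
  # growth 1.1 over one visit multiplies volume by 1.1 exactly
  st2 <- advance_visit(st, drusen_growth = 1.1, hrf_growth = 1.1)
  expect_equal(sum(visit_map(st2, 2, "drusen")), 1.1 * v0_d)
  # 4 visits at rate g: ratio g^4 (noise off)
  g <- 1.07
  st3 <- st
  for (k in 1:4) st3 <- advance_visit(st3, g, g)
  expect_equal(sum(visit_map(st3, 5, "drusen")) / v0_d, g^4)
  # monotone non-decreasing per-visit volumes for growth >= 1
  vols <- sapply(1:5, function(v) sum(visit_map(st3, v, "drusen")))
  expect_true(all(diff(vols) >= 0))
})

test_that("true sensitivity is the clamped linear predictor", {
  e0 <- true_effects(intercept_db = 26, beta_drusen = 0, beta_hrf = 0,
                     beta_visit = 0, beta_ecc = 0,
                     beta_drusen_visit = 0, beta_drusen_ecc = 0)
  expect_equal(true_sensitivity(5, 1, 3, 2, e0), 26)
  e1 <- true_effects(intercept_db = 26, beta_drusen = -1, beta_hrf = 0,
                     beta_visit = 0, beta_ecc = 0,
                     beta_drusen_visit = 0, beta_drusen_ecc = 0)
  expect_equal(true_sensitivity(2, 0, 0, 0, e1), 24)
  e2 <- true_effects(intercept_db = 2, beta_drusen = -1, beta_hrf = 0,
                     beta_visit = 0, beta_ecc = 0,
                     beta_drusen_visit = 0, beta_drusen_ecc = 0)
  expect_equal(true_sensitivity(5, 0, 0, 0, e2), 0)   # device floor
  e3 <- true_effects(intercept_db = 40)
  expect_equal(true_sensitivity(0, 0, 0, 0, e3), 34)  # device ceiling
})

test_that("cohort bundles are shaped and bit-reproducible", {
  cfg <- small_cohort_config(n_patients = 3L, n_eyes = 5L, n_visits = 2L)
  a <- simulate_cohort(cfg, seed = 17)
  b <- simulate_cohort(cfg, seed = 17)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$keypoints, b$keypoints)
  expect_identical(a$truth, b$truth)
  # 45 spots x n_visits rows per eye
  expect_equal(nrow(a$measurements), 5L * 2L * 45L)
  expect_equal(unname(table(a$measurements$eye_id)), rep(90L, 5L),
               ignore_attr = TRUE)
  expect_true(all(a$measurements$sensitivity_db >= 0 &
                  a$measurements$sensitivity_db <= 34))
  expect_true(all(a$truth$true_drusen_vol_e3mm3 >= 0))
  # at least 5 keypoints per eye, ground-truth transforms invertible
  expect_true(all(table(a$keypoints$eye_id) >= 5L))
  for (eye in a$eyes) expect_gt(abs(det(eye$true_transform$A)), 0.5)
  # eyes of the same patient share u_patient; laterality is paired
  pids <- sapply(a$eyes, function(e) e$patient_id)
  ups <- sapply(a$eyes, function(e) e$u_patient)
  expect_true(all(tapply(ups, pids, function(x) max(x) - min(x)) == 0))
})

test_that("default-cohort calibration brackets the configured targets", {
  # replicate default cohorts; baseline drusen/HRF coverage and mean
  # measured sensitivity must bracket their targets within 2 x MC SE
  seeds <- 101:108
  stats <- sapply(seeds, function(s) {
    co <- simulate_cohort(seed = s)
    tb <- co$truth[co$truth$visit == 0, ]
    mb <- co$measurements[co$measurements$visit == 0, ]
    c(dcov = mean(tb$true_drusen_vol_e3mm3 > 0),
      hcov = mean(tb$true_hrf_vol_e3mm3 > 0),
      msens = mean(mb$sensitivity_db))
  })
  n <- length(seeds)
  # allowance: 2 x Monte-Carlo SE plus the generator's documented
  # calibration precision (0.5 / 0.15 coverage points, 0.05 dB)
  for (row in list(c("dcov", 0.7347, 0.005), c("hcov", 0.0202, 0.0015),
                   c("msens", 25.71, 0.05))) {
    x <- stats[row[1], ]
    target <- as.numeric(row[2])
    se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - target), 2 * se + as.numeric(row[3]),
              label = sprintf("%s: mean %.4f vs target %.4f (MC SE %.4f)",
                              row[1], mean(x), target, se))
  }
})

test_that("HRF stimulus coverage tracks the configured target rate", {
  # Monte-Carlo over many eyes: fraction of the 45 default stimuli with
  # post-floor HRF within 3 MC SE of the 2.02% target
  grid <- mp_grid_default()
  px <- deg_to_px(grid$x_deg, grid$y_deg, c(511.5, 48), geom)
  masks <- lapply(seq_len(45), function(k)
    roi_mask(c(px$x_px[k], px$y_px[k]), geom))
  cov <- sapply(1:150, function(s) {
    dm <- simulate_drusen_field(geom, seed = 5000 + s)
    hm <- simulate_hrf_field(geom, dm, seed = 6000 + s)
    mean(vapply(masks, function(m) hrf_roi_volume(hm, m), 0) > 0)
  })
  se <- sd(cov) / sqrt(length(cov))
  expect_lt(abs(mean(cov) - 0.0202), 3 * se + 1e-12)
})
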