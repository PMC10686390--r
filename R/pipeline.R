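#' Pipeline configuration
#'
#' A thin wrapper around [cohort_config()] adding the run-level settings
#' the pipeline needs: the master seed and the registration quality gate.
#' Configurations can also be loaded from JSON or YAML files whose keys
#' mirror the constructor arguments of the component configs.
#'
#' @param cohort a [cohort_config()].
#' @param master_seed integer seed for the whole run.
#' @param registration_rms_threshold_px accept an eye's registration only
#'   if the keypoint RMS is below this (px); failures are recorded in the
#'   manifest (default 2 px).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), master_seed = 1L,
                            registration_rms_threshold_px = 2) {
  structure(list(cohort = cohort, master_seed = as.integer(master_seed),
                 registration_rms_threshold_px =
                   registration_rms_threshold_px),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON or YAML
#'
#' Top-level keys `master_seed`, `registration_rms_threshold_px`, and any
#' of `cohort` (counts), `geometry`, `drusen`, `hrf`, `effects`, `quant`,
#' `observer`, `registration`; each maps onto the matching constructor
#' arguments, unspecified values keep their defaults.
#'
#' @param path file ending in .json, .yaml or .yml.
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cc_args <- list()
  if (!is.null(x$geometry)) cc_args$geometry <- do.call(scan_geometry, x$geometry)
  if (!is.null(x$drusen)) cc_args$drusen <- do.call(drusen_field_params, x$drusen)
  if (!is.null(x$hrf)) cc_args$hrf <- do.call(hrf_field_params, x$hrf)
  if (!is.null(x$effects)) cc_args$effects <- do.call(true_effects, x$effects)
  if (!is.null(x$quant)) cc_args$quant <- do.call(quant_config, x$quant)
  if (!is.null(x$observer)) cc_args$observer <- utils::modifyList(
    formals(cohort_config)$observer |> eval(), x$observer)
  if (!is.null(x$registration)) cc_args$registration <- utils::modifyList(
    formals(cohort_config)$registration |> eval(), x$registration)
  if (!is.null(x$cohort)) cc_args <- c(cc_args, x$cohort)
  pc_args <- list(cohort = do.call(cohort_config, cc_args))
  if (!is.null(x$master_seed)) pc_args$master_seed <- x$master_seed
  if (!is.null(x$registration_rms_threshold_px))
    pc_args$registration_rms_threshold_px <- x$registration_rms_threshold_px
  do.call(pipeline_config, pc_args)
}

#' Validate a pipeline configuration
#'
#' Report-only: returns schema errors, unit sanity checks and calibration
#' warnings without stopping.
#'
#' @param config a [pipeline_config()] or [cohort_config()].
#' @return list of class `config_report`: `errors`, `warnings`, `ok`.
#' @export
validate_config <- function(config) {
  if (inherits(config, "pipeline_config")) config <- config$cohort
  errors <- character(0); warnings <- character(0)
  add_err <- function(msg) errors <<- c(errors, msg)
  add_warn <- function(msg) warnings <<- c(warnings, msg)
  q <- config$quant
  if (q$roi_diameter_um <= 0) add_err("roi_diameter_um must be positive")
  if (q$roi_diameter_um < 1000 * config$geometry$ascan_spacing_mm)
    add_err("ROI diameter below one A-scan spacing: masks can be empty")
  if (q$hrf_min_volume_mm3 > 1e-2)
    add_warn("hrf_min_volume_mm3 looks large; is it in mm^3, not um^3?")
  if (config$n_eyes < config$n_patients)
    add_err("fewer eyes than patients")
  if (config$n_eyes < 2 * config$n_patients &&
      config$n_eyes >= config$n_patients)
    add_warn("some patients contribute a single eye (allowed)")
  if (config$drusen$n_bumps_mean == 0 &&
      config$coverage_targets$drusen > 0)
    add_err("drusen coverage target > 0 but the generator produces no bumps")
  if (config$hrf$blob_rate == 0 && config$coverage_targets$hrf > 0)
    add_err("HRF coverage target > 0 but blob_rate is 0")
  ob <- config$observer
  if (ob$start_level_db < 0 || ob$start_level_db > 34)
    add_err("staircase start level outside the 0-34 dB range")
  if (max(config$grid$ecc_deg) * config$geometry$mm_per_degree > 3)
    add_warn("grid extends beyond the 6 mm ETDRS circle")
  structure(list(errors = errors, warnings = warnings,
                 ok = length(errors) == 0L), class = "config_report")
}

#' @export
print.config_report <- function(x, ...) {
  cat(if (x$ok) "configuration OK" else "configuration INVALID", "\n")
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the simulate - register - extract - fit pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under `out_dir` before the next starts, and returns a run manifest.
#' Stage outputs: `simulate` — per-eye en-face TIFFs (+ JSON sidecars),
#' `keypoints.csv`, `measurements.csv`; `register` — `transforms.json`
#' with per-eye parameters, RMS and pass/fail against the RMS gate;
#' `extract` — `spot_records.csv` (SpotRecord schema); `fit` —
#' `fit_volume.json`/`.md`, `fit_presence.json`, `learning.csv`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param stages character subset of `c("simulate", "register",
#'   "extract", "fit")`, executed in canonical order. Later stages re-use
#'   in-memory results of earlier ones, so a later stage may only be
#'   requested together with the ones it depends on.
#' @param write_maps write the per-eye TIFF maps (default TRUE; they are
#'   the bulkiest artifact).
#' @return list of class `run_manifest`: per-stage artifact paths and row
#'   counts, seed, package version, timestamps.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         stages = c("simulate", "register", "extract",
                                    "fit"),
                         write_maps = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  order_all <- c("simulate", "register", "extract", "fit")
  stages <- order_all[order_all %in% stages]
  need <- match(stages, order_all)
  if (!identical(need, seq_len(length(need))))
    stop("stages must form a prefix of simulate < register < extract < fit")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$master_seed,
                   package_version =
                     as.character(utils::packageVersion("mpstruct")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())
  rep <- validate_config(config)
  if (!rep$ok) stop("invalid configuration: ",
                    paste(rep$errors, collapse = "; "))

  cohort <- NULL; records <- NULL
  for (st in stages) {
    t0 <- Sys.time()
    arts <- list()
    if (st == "simulate") {
      cohort <- simulate_cohort(config$cohort, config$master_seed)
      arts$keypoints <- write_table_csv(
        cohort$keypoints, file.path(out_dir, "keypoints.csv"))
      arts$measurements <- write_table_csv(
        cohort$measurements, file.path(out_dir, "measurements.csv"))
      arts$grid <- write_table_csv(
        cohort$grid, file.path(out_dir, "grid.csv"))
      if (write_maps) {
        mdir <- file.path(out_dir, "maps")
        dir.create(mdir, showWarnings = FALSE)
        for (eye in cohort$eyes) {
          for (v in seq_len(eye$n_visits)) {
            for (w in c("drusen", "hrf")) {
              f <- file.path(mdir, sprintf("eye%03d_visit%d_%s.tif",
                                           eye$eye_id, v - 1L, w))
              write_enface_tiff(visit_map(eye, v, w), f)
            }
          }
        }
        arts$maps_dir <- mdir
      }
      arts$n_rows <- nrow(cohort$measurements)
    } else if (st == "register") {
      fits <- lapply(cohort$eyes, function(eye) {
        kp <- cohort$keypoints[cohort$keypoints$eye_id == eye$eye_id, ]
        tf <- fit_affine(kp)
        list(eye_id = eye$eye_id, A = as.numeric(tf$A), b = tf$b,
             rms_px = tf$rms,
             pass = tf$rms <= config$registration_rms_threshold_px)
      })
      f <- file.path(out_dir, "transforms.json")
      jsonlite::write_json(fits, f, auto_unbox = TRUE, digits = NA)
      arts$transforms <- f
      arts$n_pass <- sum(vapply(fits, `[[`, TRUE, "pass"))
    } else if (st == "extract") {
      records <- extract_spot_features(cohort, config$cohort$quant)
      arts$spot_records <- write_table_csv(
        records, file.path(out_dir, "spot_records.csv"))
      arts$n_rows <- nrow(records)
    } else if (st == "fit") {
      fv <- fit_volume_model(records)
      write_fit_report(fv, file.path(out_dir, "fit_volume.json"),
                       file.path(out_dir, "fit_volume.md"))
      fp <- fit_presence_model(records)
      write_fit_report(fp, file.path(out_dir, "fit_presence.json"))
      learn <- learning_sensitivity(records)
      write_table_csv(learn$visit_coef,
                      file.path(out_dir, "learning.csv"))
      arts$fit_volume <- file.path(out_dir, "fit_volume.json")
      arts$fit_presence <- file.path(out_dir, "fit_presence.json")
      arts$learning <- file.path(out_dir, "learning.csv")
    }
    manifest$stages[[st]] <- c(arts, list(
      seconds = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2)))
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  manifest$path <- f
  structure(manifest, class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("pipeline run (seed %d, mpstruct %s): stages %s\n",
              x$seed, x$package_version,
              paste(names(x$stages), collapse = " > ")))
  invisible(x)
}
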