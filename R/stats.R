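#' Nested mixed models for point-to-point structure-function analysis
#'
#' `fit_volume_model()` fits the primary model: retinal sensitivity on
#' local drusen volume, HRF volume, visit (learning effect), eccentricity
#' and the drusen-by-visit and drusen-by-eccentricity interactions, with
#' nested random intercepts for patient, eye within patient and stimulus
#' spot within eye. Estimation is REML (via lme4); inference is Wald:
#' z = estimate/SE, two-sided normal p-values and 95% CIs. Volumes must be
#' in 1e-3 mm^3 units (`drusen_vol_e3mm3`, `hrf_vol_e3mm3` as produced by
#' [extract_spot_features()]); rows flagged out-of-raster are excluded.
#'
#' @param records SpotRecord data.frame (see [extract_spot_features()]).
#' @param include_interactions keep the drusen:visit and drusen:ecc
#'   interaction terms (default TRUE, the full model).
#' @param REML REML (default) or ML estimation.
#' @return object of class `sf_fit`; see [print.sf_fit()]. Components:
#'   `coefficients` (data.frame with estimate, se, z, p, ci_lo, ci_hi),
#'   `varcomp` (variance components), `AIC`, `logLik`, `n_obs`,
#'   `n_groups`, `converged`, `singular`, `model` (the underlying lme4
#'   fit), `formula`.
#' @export
fit_volume_model <- function(records, include_interactions = TRUE,
                             REML = TRUE) {
  fixed <- if (include_interactions)
    "drusen_vol_e3mm3 + hrf_vol_e3mm3 + visit + ecc_deg + drusen_vol_e3mm3:visit + drusen_vol_e3mm3:ecc_deg"
  else
    "drusen_vol_e3mm3 + hrf_vol_e3mm3 + visit + ecc_deg"
  fit_nested(records, fixed, REML = REML)
}

#' Presence-only simplified mixed model
#'
#' Same nested random structure as [fit_volume_model()], fixed effects
#' reduced to the drusen- and HRF-presence indicators (volume > 0; HRF
#' after the detectability floor) plus visit.
#'
#' @inheritParams fit_volume_model
#' @export
fit_presence_model <- function(records, REML = TRUE) {
  records <- modelling_rows(records)
  for (term in c("drusen_present", "hrf_present")) {
    if (length(unique(records[[term]])) < 2L)
      stop(sprintf("term '%s' is constant in the modelling rows: %s",
                   term, "presence effect not identifiable"))
  }
  fit_nested(records, "drusen_present + hrf_present + visit", REML = REML)
}

#' ETDRS-sector mixed model with Bonferroni pairwise contrasts
#'
#' Replaces eccentricity by the ETDRS sector as a categorical fixed effect
#' (alongside the volume covariates and visit) and reports all pairwise
#' sector contrasts with Bonferroni-adjusted Wald p-values
#' (`p_adj = min(1, m * p)`, `m` = number of pairs among non-empty
#' sectors). Sectors without observations are dropped with a warning.
#'
#' @inheritParams fit_volume_model
#' @return an `sf_fit` with an extra `contrasts` data.frame: `sector_a`,
#'   `sector_b`, difference `estimate` (a minus b, dB), `se`, `z`, `p`,
#'   `p_bonferroni`.
#' @export
fit_sector_model <- function(records, REML = TRUE) {
  records <- modelling_rows(records)
  records <- records[!is.na(records$sector), ]
  present <- sort(unique(records$sector))
  if (length(present) < length(1:9))
    warning(sprintf("empty ETDRS sectors dropped: %s",
                    paste(setdiff(1:9, present), collapse = ", ")))
  if (length(present) < 2L) stop("need at least two non-empty sectors")
  records$sector_f <- factor(records$sector, levels = present)
  fit <- fit_nested(records,
                    "drusen_vol_e3mm3 + hrf_vol_e3mm3 + visit + sector_f",
                    REML = REML, prefiltered = TRUE)
  fit$contrasts <- sector_contrasts(fit$model, present)
  fit
}

# all pairwise sector contrasts from the fitted fixed-effect vcov
sector_contrasts <- function(model, sectors) {
  beta <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  k <- length(sectors)
  # sector means up to a constant: reference sector has 0 effect
  eff <- stats::setNames(numeric(k), sectors)
  L <- matrix(0, k, length(beta),
              dimnames = list(sectors, names(beta)))
  for (s in sectors[-1]) {
    nm <- paste0("sector_f", s)
    L[as.character(s), nm] <- 1
  }
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- data.frame(sector_a = sectors[pairs[1, ]],
                    sector_b = sectors[pairs[2, ]])
  cl <- L[pairs[1, ], , drop = FALSE] - L[pairs[2, ], , drop = FALSE]
  out$estimate <- as.numeric(cl %*% beta)
  out$se <- sqrt(rowSums((cl %*% V) * cl))
  out$z <- out$estimate / out$se
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$p_bonferroni <- pmin(1, m * out$p)
  out
}

#' Learning-effect sensitivity analysis
#'
#' Refits the full volume model on (a) all visits, (b) excluding the
#' baseline visit, (c) excluding baseline and second visit, and collects
#' the visit coefficient from each refit — the perimetric learning effect
#' under progressively stricter exclusion of early-test improvement.
#'
#' @inheritParams fit_volume_model
#' @return list of class `sf_learning`: `fits` (named list of `sf_fit` or
#'   `NULL` where a subset was not estimable), `visit_coef` (data.frame
#'   with subset, estimate, se, ci_lo, ci_hi, p, estimable).
#' @export
learning_sensitivity <- function(records, include_interactions = TRUE) {
  subsets <- list(full = 0L, drop_baseline = 1L, drop_first_two = 2L)
  fits <- list(); rows <- list()
  for (nm in names(subsets)) {
    sub <- records[records$visit >= subsets[[nm]], ]
    ok <- length(unique(sub$visit)) >= 2L
    f <- NULL
    if (ok) f <- fit_volume_model(sub, include_interactions)
    fits[[nm]] <- f
    co <- if (ok) f$coefficients["visit", ] else NULL
    rows[[nm]] <- data.frame(
      subset = nm,
      estimate = if (ok) co$estimate else NA_real_,
      se = if (ok) co$se else NA_real_,
      ci_lo = if (ok) co$ci_lo else NA_real_,
      ci_hi = if (ok) co$ci_hi else NA_real_,
      p = if (ok) co$p else NA_real_,
      estimable = ok)
  }
  structure(list(fits = fits,
                 visit_coef = do.call(rbind, c(rows,
                                               make.row.names = FALSE))),
            class = "sf_learning")
}

#' @export
print.sf_learning <- function(x, ...) {
  cat("visit (learning) coefficient under baseline-exclusion refits:\n")
  print(x$visit_coef, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Compare fitted models by AIC
#'
#' Models are refitted by maximum likelihood (fixed-effect AIC comparisons
#' are not valid under REML) and must be fitted on identical rows.
#'
#' @param ... named `sf_fit` objects (or a single list of them).
#' @return data.frame with `model`, `df`, `logLik`, `AIC`, `dAIC`
#'   (difference to the best model), sorted by AIC.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "sf_fit"))
    fits <- fits[[1]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  n <- vapply(fits, function(f) f$n_obs, 0L)
  if (length(unique(n)) != 1L)
    stop("models were fitted on differing row sets; comparison refused")
  ml <- lapply(fits, function(f) {
    if (f$REML) lme4::refitML(f$model) else f$model
  })
  ll <- vapply(ml, function(m) as.numeric(stats::logLik(m)), 0)
  df <- vapply(ml, function(m) attr(stats::logLik(m), "df"), 0)
  aic <- 2 * df - 2 * ll
  out <- data.frame(model = names(fits), df = df, logLik = ll, AIC = aic)
  out <- out[order(out$AIC), ]
  out$dAIC <- out$AIC - out$AIC[1]
  rownames(out) <- NULL
  out
}

# ---- internals --------------------------------------------------------

modelling_rows <- function(records) {
  req <- c("sensitivity_db", "patient_id", "eye_id", "spot_id", "visit")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if ("in_raster" %in% names(records))
    records <- records[records$in_raster, ]
  records
}

fit_nested <- function(records, fixed_terms, REML = TRUE,
                       prefiltered = FALSE) {
  if (!prefiltered) records <- modelling_rows(records)
  if (length(unique(records$eye_id)) < 2L)
    warning("degenerate design: a single eye; variance components are not separable")
  records$.patient <- factor(records$patient_id)
  records$.eye <- factor(paste(records$patient_id, records$eye_id,
                               sep = ":"))
  records$.spot <- factor(paste(records$patient_id, records$eye_id,
                                records$spot_id, sep = ":"))
  fml <- stats::as.formula(paste(
    "sensitivity_db ~", fixed_terms,
    "+ (1 | .patient) + (1 | .eye) + (1 | .spot)"))
  model <- lme4::lmer(fml, data = records, REML = REML,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        calc.derivs = FALSE))
  beta <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- beta / se
  coefs <- data.frame(estimate = beta, se = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)),
                      ci_lo = beta - stats::qnorm(0.975) * se,
                      ci_hi = beta + stats::qnorm(0.975) * se)
  vc <- as.data.frame(lme4::VarCorr(model))
  varcomp <- stats::setNames(vc$vcov, vc$grp)
  names(varcomp)[names(varcomp) == ".patient"] <- "patient"
  names(varcomp)[names(varcomp) == ".eye"] <- "eye"
  names(varcomp)[names(varcomp) == ".spot"] <- "spot"
  names(varcomp)[names(varcomp) == "Residual"] <- "residual"
  conv <- length(model@optinfo$conv$lme4$messages) == 0L
  structure(list(
    coefficients = coefs,
    varcomp = varcomp[c("patient", "eye", "spot", "residual")],
    AIC = stats::AIC(model),
    logLik = as.numeric(stats::logLik(model)),
    n_obs = nrow(records),
    n_groups = c(patients = length(unique(records$.patient)),
                 eyes = length(unique(records$.eye)),
                 spots = length(unique(records$.spot))),
    converged = conv,
    singular = lme4::isSingular(model),
    REML = REML,
    formula = fml,
    model = model), class = "sf_fit")
}

#' @export
print.sf_fit <- function(x, ...) {
  cat("nested mixed model of retinal sensitivity",
      if (x$REML) "(REML)" else "(ML)", "\n")
  cat(sprintf("  %d observations; %d patients / %d eyes / %d spots\n",
              x$n_obs, x$n_groups["patients"], x$n_groups["eyes"],
              x$n_groups["spots"]))
  print(round(x$coefficients, 4))
  cat("variance components (dB^2):\n")
  print(round(x$varcomp, 4))
  cat(sprintf("AIC %.1f; logLik %.1f%s%s\n", x$AIC, x$logLik,
              if (!x$converged) "; NOT CONVERGED" else "",
              if (x$singular) "; singular fit (some variance at 0)" else ""))
  invisible(x)
}

#' @export
summary.sf_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.sf_fit")
}

#' @export
print.summary.sf_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$contrasts)) {
    cat("pairwise sector contrasts (Bonferroni-adjusted):\n")
    print(x$fit$contrasts, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.sf_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' @export
confint.sf_fit <- function(object, parm, level = 0.95, ...) {
  co <- object$coefficients
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(co$estimate - q * co$se, co$estimate + q * co$se)
  dimnames(ci) <- list(rownames(co),
                       sprintf("%.1f %%", c((1 - level) / 2,
                                            1 - (1 - level) / 2) * 100))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.sf_fit <- function(object, ...) stats::residuals(object$model)

#' @export
fitted.sf_fit <- function(object, ...) stats::fitted(object$model)

#' @export
plot.sf_fit <- function(x, ...) {
  r <- stats::residuals(x$model); f <- stats::fitted(x$model)
  plot(f, r, xlab = "fitted sensitivity (dB)", ylab = "residual (dB)",
       pch = ".", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
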