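#' Psychometric observer model
#'
#' A cumulative-Gaussian observer for simulated threshold perimetry. The
#' probability of reporting a stimulus of attenuation `level_db` as seen is
#'
#'   P(seen) = (1 - fn) * Phi((T - L) / sigma) + fp * (1 - Phi((T - L) / sigma))
#'
#' where `T` is the observer's true threshold (dB attenuation: higher =
#' more sensitive), `sigma` the psychometric spread, `fp`/`fn` the lapse
#' rates. With `sigma = 0` the observer is deterministic: seen iff
#' `L <= T` (boundary inclusive).
#'
#' @param true_threshold_db true threshold, dB attenuation.
#' @param slope_sd_db psychometric spread sigma (dB, >= 0).
#' @param false_pos_rate,false_neg_rate lapse probabilities in [0, 1).
#' @return list of class `mp_observer`.
#' @export
mp_observer <- function(true_threshold_db, slope_sd_db = 0.5,
                        false_pos_rate = 0.03, false_neg_rate = 0.03) {
  stopifnot(slope_sd_db >= 0,
            false_pos_rate >= 0, false_pos_rate < 1,
            false_neg_rate >= 0, false_neg_rate < 1)
  structure(list(true_threshold_db = true_threshold_db,
                 slope_sd_db = slope_sd_db,
                 false_pos_rate = false_pos_rate,
                 false_neg_rate = false_neg_rate),
            class = "mp_observer")
}

#' Probability that the observer reports a presentation as seen
#' @param observer an [mp_observer()].
#' @param level_db presented attenuation level (dB).
#' @return probability in [0, 1].
#' @export
p_seen <- function(observer, level_db) {
  d <- observer$true_threshold_db - level_db
  base <- if (observer$slope_sd_db == 0) as.numeric(d >= 0)
          else stats::pnorm(d / observer$slope_sd_db)
  (1 - observer$false_neg_rate) * base +
    observer$false_pos_rate * (1 - base)
}

#' Simulate one observer response
#'
#' Uses R's current RNG stream; seed via [set.seed()] upstream.
#' @inheritParams p_seen
#' @return logical: seen?
#' @export
respond <- function(observer, level_db) {
  stats::runif(1) < p_seen(observer, level_db)
}

#' 4-2-1 staircase threshold estimation
#'
#' Adaptive staircase as used by fundus-tracked perimeters: starting at
#' `start_level_db`, a seen response makes the next presentation dimmer
#' (attenuation increased by the current step), a not-seen response makes
#' it brighter. The step shrinks 4 -> 2 -> 1 dB at each response reversal
#' and the run terminates after the first reversal at the 1-dB step. The
#' threshold estimate is the highest (dimmest) attenuation answered seen;
#' an observer that never sees any presentation is scored at the device
#' floor of 0 dB. All levels are clipped to the instrument's dynamic range
#' of 0-34 dB, and a response repeated against a range boundary terminates
#' the run (always-seeing observers score the 34 dB ceiling).
#'
#' @param observer an [mp_observer()].
#' @param start_level_db initial attenuation (default 17 dB).
#' @param max_presentations hard safety bound on presentations.
#' @return list of class `staircase_result`: `estimate_db`,
#'   `presentations` (data.frame `level_db`, `seen`), `n_reversals`.
#' @examples
#' set.seed(1)
#' staircase_421(mp_observer(20, slope_sd_db = 0))$estimate_db  # 20
#' @export
staircase_421 <- function(observer, start_level_db = 17,
                          max_presentations = 30L) {
  stopifnot(start_level_db >= 0, start_level_db <= 34)
  steps <- c(4, 2, 1)
  step_i <- 1L
  level <- start_level_db
  levels <- numeric(0); seen <- logical(0)
  n_rev <- 0L
  repeat {
    s <- respond(observer, level)
    levels <- c(levels, level); seen <- c(seen, s)
    n <- length(levels)
    if (n > 1L && seen[n] != seen[n - 1L]) {        # reversal
      n_rev <- n_rev + 1L
      if (step_i == 3L) break                        # reversal at 1-dB step
      step_i <- step_i + 1L
    }
    nxt <- if (s) level + steps[step_i] else level - steps[step_i]
    nxt <- min(34, max(0, nxt))
    if (nxt == level) break                          # pinned at range edge
    if (n >= max_presentations) break
    level <- nxt
  }
  est <- if (any(seen)) max(levels[seen]) else 0
  structure(list(estimate_db = est,
                 presentations = data.frame(level_db = levels, seen = seen),
                 n_reversals = n_rev),
            class = "staircase_result")
}

#' Simulate a full microperimetry examination
#'
#' Runs one independent 4-2-1 staircase per stimulus location.
#'
#' @param true_thresholds_db numeric vector of per-spot true thresholds
#'   (dB; values outside 0-34 emulate floor/ceiling observers).
#' @param slope_sd_db,false_pos_rate,false_neg_rate observer noise
#'   parameters shared across spots.
#' @param seed integer seed; the exam is deterministic given it.
#' @param start_level_db staircase start level.
#' @return numeric vector of measured sensitivities (dB), same length as
#'   `true_thresholds_db`.
#' @export
simulate_exam <- function(true_thresholds_db, slope_sd_db = 0.5,
                          false_pos_rate = 0.03, false_neg_rate = 0.03,
                          seed = 1L, start_level_db = 17) {
  n <- length(true_thresholds_db)
  if (n == 0L) stop("no thresholds supplied")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  vapply(true_thresholds_db, function(tt) {
    staircase_421(mp_observer(tt, slope_sd_db, false_pos_rate,
                              false_neg_rate),
                  start_level_db = start_level_db)$estimate_db
  }, 0)
}
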