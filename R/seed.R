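# Seed plumbing: every stochastic operation takes an explicit seed and
# leaves the caller's RNG state untouched. Sub-seeds are derived with a
# counter-based hash so that adding eyes/visits does not reshuffle the
# streams of existing ones.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Derive a deterministic sub-seed from a master seed and counters
#'
#' Mixes the master seed with up to three stream counters (e.g. eye index,
#' visit index, purpose code) using multiplicative hashing modulo the
#' Mersenne prime 2^31 - 1, keeping results valid 32-bit seeds.
#'
#' @param master integer master seed.
#' @param ... integer counters (any number).
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1
  x <- as.numeric(master) %% m
  mult <- c(1300997, 32416190071 %% m, 104729, 7919, 52361)
  ctr <- c(...)
  x <- (x * 48271 + 11) %% m
  for (k in seq_along(ctr)) {
    x <- (x + (as.numeric(ctr[k]) + 1) * mult[((k - 1) %% 5) + 1]) %% m
    x <- (x * 69621) %% m
  }
  as.integer(x %% (m - 2)) + 1L
}
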