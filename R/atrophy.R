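# Atrophy accrual: direct toxicity from local misfolded protein plus
# deafferentation from damage in afferent neighbours.

# Row-stochastic afferent weight matrix: entry [i, j] = w_ji / sum_j w_ji,
# the share of region i's inputs that come from region j. Rows of regions
# with no afferents are all zero (their deafferentation term is 0).
afferent_weights <- function(w) {
  instrength <- colSums(w)
  a <- t(w) / ifelse(instrength > 0, instrength, 1)
  a[instrength == 0, ] <- 0
  a
}

# Fast path used by sir_simulate: takes the precomputed afferent matrix.
atrophy_increment <- function(r_now, r_prev, aff, k1, k2, dt) {
  k1 * -expm1(-r_now) * dt + k2 * as.vector(aff %*% -expm1(-r_prev)) * dt
}

#' Atrophy increment from toxicity and deafferentation
#'
#' The per-region atrophy accrued over one timestep is
#' `dL_i = k1 * (1 - exp(-r_i(t))) * dt +
#'         k2 * sum_j (w_ji / sum_j w_ji) * (1 - exp(-r_j(t-1))) * dt`:
#' a direct-toxicity term driven by the region's own current infected
#' fraction, plus a deafferentation term driven by the previous-step infected
#' fractions of its afferent neighbours, weighted by their normalised input
#' strength. Both terms are bounded by `k * dt`, so with `k1 = k2` toxicity
#' and deafferentation have equal maximal effect. Regions with no afferents
#' take a zero deafferentation term; at the first step after injection
#' `r_prev` is the zero vector.
#'
#' Increments are nonnegative, so cumulative atrophy is monotone
#' non-decreasing.
#'
#' @param r_now,r_prev per-region infected fractions at the current and
#'   previous step, each in \[0, 1\].
#' @param weights the symmetric connection weight matrix.
#' @param k1,k2 toxicity and deafferentation weights, >= 0 (default 0.5 each).
#' @param dt timestep length.
#' @return per-region atrophy increment vector.
#' @export
accrue_atrophy <- function(r_now, r_prev, weights, k1 = 0.5, k2 = 0.5,
                           dt = 0.1) {
  if (k1 < 0 || k2 < 0) stop("k1 and k2 must be >= 0")
  if (any(r_now < 0 | r_now > 1) || any(r_prev < 0 | r_prev > 1)) {
    stop("infected fractions must lie in [0, 1]")
  }
  if (length(r_now) != nrow(weights) || length(r_prev) != nrow(weights)) {
    stop("r vectors must match the weight matrix dimension")
  }
  atrophy_increment(r_now, r_prev, afferent_weights(weights), k1, k2, dt)
}
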