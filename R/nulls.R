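#' Degree-preserving rewired null connectome (Maslov-Sneppen)
#'
#' Randomly rewires the binary topology with edge swaps that exactly preserve
#' the binary degree sequence and edge count; each edge's weight rides along
#' with it, so the weight multiset is preserved exactly. A swap picks two
#' edges (a,b) and (c,d) and proposes (a,d) and (c,b); it is rejected if it
#' would create a self-loop or a multi-edge. Edge lengths for newly created
#' edges are taken from the full centroid distance matrix; edges that survive
#' rewiring keep their original lengths.
#'
#' Very dense networks (e.g. complete graphs) admit no swaps; the input is
#' then returned with a warning after the attempt budget is exhausted.
#'
#' @param connectome a [connectome()].
#' @param swaps_per_edge average number of swap attempts per edge
#'   (default 100).
#' @param seed RNG seed for reproducible rewiring.
#' @return a rewired `connectome`.
#' @export
rewire_connectome <- function(connectome, swaps_per_edge = 100, seed = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  w <- connectome$weights
  n <- nrow(w)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(ut)
  if (m < 2) stop("need at least 2 edges to rewire")
  edges <- ut                      # m x 2, i < j
  ew <- w[ut]
  adj <- w > 0
  swaps <- with_seed(seed, {
    n_attempts <- as.integer(swaps_per_edge) * m
    pick <- matrix(sample.int(m, 2L * n_attempts, replace = TRUE), ncol = 2)
    flip <- stats::runif(n_attempts) < 0.5
    done <- 0L
    for (k in seq_len(n_attempts)) {
      e1 <- pick[k, 1]; e2 <- pick[k, 2]
      if (e1 == e2) next
      a <- edges[e1, 1]; b <- edges[e1, 2]
      c_ <- edges[e2, 1]; d <- edges[e2, 2]
      if (flip[k]) { tmp <- c_; c_ <- d; d <- tmp }
      # propose (a,d) and (c_,b)
      if (a == d || c_ == b || a == c_ || b == d) next
      if (adj[a, d] || adj[c_, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c_, d] <- adj[d, c_] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c_, b] <- adj[b, c_] <- TRUE
      edges[e1, ] <- c(min(a, d), max(a, d))
      edges[e2, ] <- c(min(c_, b), max(c_, b))
      done <- done + 1L
    }
    done
  })
  if (swaps == 0L) {
    warning("no admissible swaps found (network too dense or too sparse); ",
            "returning the input connectome")
    return(connectome)
  }
  new_w <- matrix(0, n, n, dimnames = dimnames(w))
  new_w[edges] <- ew
  new_w <- new_w + t(new_w)
  new_d <- connectome$centroid_distances
  survived <- (w > 0) & (new_w > 0)
  new_d[survived] <- connectome$distances[survived]
  connectome(connectome$regions, new_w, new_d)
}

#' Repositioned null connectome
#'
#' Randomly permutes the spatial positions of regions while leaving the
#' connection weights (hence the degree sequence and full connection profile)
#' untouched; the distance matrix is recomputed from the permuted
#' coordinates. Region sizes keep their regions — only geometry is shuffled.
#'
#' @param connectome a [connectome()].
#' @param seed RNG seed.
#' @return a `connectome` with permuted coordinates and recomputed distances.
#' @export
reposition_connectome <- function(connectome, seed = NULL) {
  stopifnot(inherits(connectome, "connectome"))
  n <- n_regions(connectome)
  perm <- with_seed(seed, sample.int(n))
  regions <- connectome$regions
  regions[, c("x", "y", "z")] <- regions[perm, c("x", "y", "z")]
  connectome(regions, connectome$weights)
}

#' Shuffled-expression null profile
#'
#' Randomly reassigns the chosen gene's regional values to regions (a uniform
#' permutation); the other gene is untouched. The value multiset is preserved
#' exactly.
#'
#' @param expr an [expression_profile()].
#' @param which_gene `"synthesis"`, `"clearance"`, or `"both"` (permuted
#'   independently).
#' @param seed RNG seed.
#' @return a permuted `expression_profile`.
#' @export
shuffle_expression <- function(expr, which_gene = c("synthesis", "clearance", "both"),
                               seed = NULL) {
  stopifnot(inherits(expr, "expression_profile"))
  which_gene <- match.arg(which_gene)
  n <- length(expr$synthesis)
  with_seed(seed, {
    if (which_gene %in% c("synthesis", "both")) {
      expr$synthesis <- expr$synthesis[sample.int(n)]
    }
    if (which_gene %in% c("clearance", "both")) {
      expr$clearance <- expr$clearance[sample.int(n)]
    }
  })
  expr
}

#' Distance-binned empirical variogram of a regional map
#'
#' Semivariance `gamma(h) = mean of (x_i - x_j)^2 / 2` over region pairs
#' whose separation falls in each of `n_bins` equal-width distance bins.
#'
#' @param x per-region values.
#' @param distances full symmetric region-pair distance matrix.
#' @param n_bins number of distance bins (default 25).
#' @return tibble with columns `distance` (bin midpoint), `gamma`, `n_pairs`.
#' @export
variogram <- function(x, distances, n_bins = 25) {
  n <- length(x)
  ut <- upper.tri(distances)
  d <- distances[ut]
  if (max(d) <= min(d)) stop("degenerate distances: all region pairs are equidistant")
  sv <- 0.5 * (outer(x, x, "-")[ut])^2
  breaks <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L), n_bins)
  tibble::tibble(
    distance = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
    gamma = as.vector(tapply(sv, factor(bin, levels = seq_len(n_bins)), mean)),
    n_pairs = as.vector(table(factor(bin, levels = seq_len(n_bins))))
  )
}

# Count-weighted mean relative deviation between two variograms on shared
# non-empty bins with positive reference semivariance.
variogram_mismatch <- function(vg_ref, vg_new) {
  ok <- vg_ref$n_pairs > 0 & !is.na(vg_ref$gamma) & !is.na(vg_new$gamma) &
    vg_ref$gamma > 0
  sum(abs(vg_new$gamma[ok] - vg_ref$gamma[ok]) / vg_ref$gamma[ok] *
        vg_ref$n_pairs[ok]) / sum(vg_ref$n_pairs[ok])
}

# Variogram-matched surrogate of a single regional map: permute, smooth with
# a distance-decay kernel over a grid of bandwidths and mixing weights,
# rank-remap each candidate onto the original value multiset, and keep the
# candidate whose binned variogram best matches the original's
# (count-weighted mean relative deviation over the bins). Several random
# permutation restarts are searched because, at atlas-scale region counts,
# per-bin semivariances carry substantial sampling noise; including a
# zero-smoothing candidate means spatially unstructured maps can come back
# as a plain permutation.
surrogate_map <- function(x, distances, n_bins = 25, n_restarts = 30,
                          target_err = 0.08) {
  n <- length(x)
  ut <- upper.tri(distances)
  d <- distances[ut]
  breaks <- seq(min(d), max(d), length.out = n_bins + 1)
  bin <- factor(pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L),
                     n_bins), levels = seq_len(n_bins))
  counts <- as.vector(table(bin))
  binned_vg <- function(v) {
    sv <- 0.5 * (outer(v, v, "-")[ut])^2
    g <- rowsum(sv, bin)  # rowsum drops empty bins; re-expand by level
    out <- rep(NA_real_, n_bins)
    idx <- as.integer(rownames(g))
    out[idx] <- g[, 1] / counts[idx]
    out
  }
  vg0 <- binned_vg(x)
  ok <- counts > 0 & !is.na(vg0) & vg0 > 0
  mismatch <- function(vg) {
    sum(abs(vg[ok] - vg0[ok]) / vg0[ok] * counts[ok]) / sum(counts[ok])
  }
  offd_q <- stats::quantile(d, c(0.05, 0.1, 0.2, 0.35, 0.5, 0.75))
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  xs <- sort(x)
  best <- NULL
  best_err <- Inf
  for (res in seq_len(n_restarts)) {
    xp <- x[sample.int(n)]
    xpz <- zs(xp)
    err <- mismatch(binned_vg(xp))
    if (err < best_err) {
      best <- xp
      best_err <- err
    }
    for (delta in offd_q) {
      k <- exp(-distances / delta)
      s <- as.vector(k %*% xp) / rowSums(k)
      if (stats::sd(s) == 0) next
      sz <- zs(s)
      for (wgt in seq(0.1, 1, by = 0.1)) {
        cand <- xs[rank(wgt * sz + (1 - wgt) * xpz, ties.method = "first")]
        err <- mismatch(binned_vg(cand))
        if (err < best_err) {
          best <- cand
          best_err <- err
        }
      }
    }
    if (best_err < target_err) break
  }
  best
}

#' Spatial-autocorrelation-preserving surrogate expression
#'
#' Generates a null expression map that randomises regional values while
#' preserving both the value multiset (exactly, by rank-remapping onto the
#' original values) and the map's spatial autocorrelation structure
#' (approximately, by matching the distance-binned empirical variogram). The
#' scheme: permute the values, smooth the permutation with distance-decay
#' kernels over a grid of bandwidths and mixing weights, rank-remap each
#' candidate back onto the original values, and keep the candidate whose
#' variogram best matches the original's in `n_bins` bins. This is a compact
#' variogram-matching surrogate in the same family as generative
#' surrogate-map toolboxes used for brain maps.
#'
#' @param expr an [expression_profile()].
#' @param distances full region-pair distance matrix (typically
#'   `connectome$centroid_distances`).
#' @param which_gene `"synthesis"`, `"clearance"`, or `"both"`.
#' @param seed RNG seed.
#' @param n_bins variogram bins (default 25).
#' @return an `expression_profile` with surrogate values for the chosen gene.
#' @export
surrogate_expression <- function(expr, distances,
                                 which_gene = c("synthesis", "clearance", "both"),
                                 seed = NULL, n_bins = 25) {
  stopifnot(inherits(expr, "expression_profile"))
  which_gene <- match.arg(which_gene)
  with_seed(seed, {
    if (which_gene %in% c("synthesis", "both")) {
      expr$synthesis <- surrogate_map(expr$synthesis, distances, n_bins)
    }
    if (which_gene %in% c("clearance", "both")) {
      expr$clearance <- surrogate_map(expr$clearance, distances, n_bins)
    }
  })
  expr
}

#' Null peak-fit distribution for one null-model family
#'
#' Repeatedly randomises one ingredient of the model — the connectome's
#' topology (`"rewired"`), its geometry (`"repositioned"`), or one gene's
#' expression map (`"synthesis_shuffle"`, `"clearance_shuffle"`, or the
#' autocorrelation-preserving `"synthesis_surrogate"`,
#' `"clearance_surrogate"`) — reruns the full simulation and fit, and
#' collects the null peak correlations.
#'
#' @param connectome,expr,config the true inputs ([connectome()],
#'   [expression_profile()], [sir_config()]).
#' @param observed the observed atrophy progression map (see
#'   [correlation_curve()]).
#' @param kind which ingredient to randomise.
#' @param reps number of null repetitions (500 in full analyses; smaller
#'   values are appropriate for quick checks).
#' @param seed RNG seed; per-repetition sub-seeds are derived from it.
#' @param standardize passed to [expression_to_rates()].
#' @param swaps_per_edge for `kind = "rewired"`.
#' @return tibble with columns `kind`, `rep`, `seed`, `peak_r`, `peak_step`.
#' @export
null_peaks <- function(connectome, expr, observed, config,
                       kind = c("rewired", "repositioned",
                                "synthesis_shuffle", "clearance_shuffle",
                                "synthesis_surrogate", "clearance_surrogate"),
                       reps = 500, seed = NULL, standardize = TRUE,
                       swaps_per_edge = 100) {
  kind <- match.arg(kind)
  seeds <- derive_seeds(seed, reps)
  res <- purrr::map(seq_len(reps), function(i) {
    cn <- connectome
    ex <- expr
    s <- seeds[i]
    switch(kind,
      rewired = { cn <- rewire_connectome(cn, swaps_per_edge, seed = s) },
      repositioned = { cn <- reposition_connectome(cn, seed = s) },
      synthesis_shuffle = { ex <- shuffle_expression(ex, "synthesis", seed = s) },
      clearance_shuffle = { ex <- shuffle_expression(ex, "clearance", seed = s) },
      synthesis_surrogate = {
        ex <- surrogate_expression(ex, cn$centroid_distances, "synthesis", seed = s)
      },
      clearance_surrogate = {
        ex <- surrogate_expression(ex, cn$centroid_distances, "clearance", seed = s)
      })
    rates <- expression_to_rates(ex, standardize = standardize)
    traj <- sir_simulate(cn, rates, config, record_populations = FALSE)
    fit <- correlation_curve(traj, observed, n_perm = 0)
    tibble::tibble(kind = kind, rep = i, seed = s,
                   peak_r = fit$peak_r, peak_step = fit$peak_step)
  })
  dplyr::bind_rows(res)
}

#' Significance of the true peak fit against a null distribution
#'
#' One-sample t test of the null peak-fit sample against the empirical peak
#' as the reference constant, plus the nonparametric summary: the rank of the
#' true peak among the nulls and the exceedance proportion
#' `#{null >= true} / reps`.
#'
#' @param true_fit the empirical fit: a `sir_fit` from [correlation_curve()]
#'   or a single peak correlation value.
#' @param null_peaks numeric vector of null peak correlations, or the tibble
#'   from [null_peaks()].
#' @param kind optional label carried into the result.
#' @return an object of class `null_distribution` with `kind`, `peaks`,
#'   `true_peak`, `t_statistic`, `p_value` (two-sided), `rank` (1 = true peak
#'   above every null), and `exceedance`.
#' @export
null_significance <- function(true_fit, null_peaks, kind = NULL) {
  true_peak <- if (inherits(true_fit, "sir_fit")) true_fit$peak_r
               else as.numeric(true_fit)
  if (is.data.frame(null_peaks)) {
    if (is.null(kind) && "kind" %in% names(null_peaks)) {
      kind <- as.character(null_peaks$kind[1])
    }
    null_peaks <- null_peaks$peak_r
  }
  if (length(null_peaks) < 2) stop("need at least 2 null repetitions")
  if (any(!is.finite(null_peaks))) stop("null peaks must be finite")
  if (stats::sd(null_peaks) == 0) {
    tt <- list(statistic = c(t = 0), p.value = if (null_peaks[1] == true_peak) 1 else 0)
  } else {
    tt <- stats::t.test(null_peaks, mu = true_peak)
  }
  structure(list(kind = kind %||% "null", peaks = null_peaks,
                 true_peak = true_peak,
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 rank = sum(null_peaks >= true_peak) + 1L,
                 exceedance = mean(null_peaks >= true_peak)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> ", x$kind, ": true peak ",
      sprintf("%.3f", x$true_peak), " vs ", length(x$peaks),
      " nulls (mean ", sprintf("%.3f", mean(x$peaks)), "); t = ",
      sprintf("%.2f", x$t_statistic), ", p = ", format(x$p_value, digits = 3),
      "; exceedance ", sprintf("%.3f", x$exceedance), "\n", sep = "")
  invisible(x)
}

#' @describeIn null_significance null peaks as a tibble
#' @param x a `null_distribution`
#' @param ... unused
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble::tibble(kind = x$kind, rep = seq_along(x$peaks), peak_r = x$peaks)
}

#' @describeIn null_significance one-row test summary
#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(kind = x$kind, reps = length(x$peaks),
                 true_peak = x$true_peak, null_mean = mean(x$peaks),
                 null_sd = stats::sd(x$peaks), t_statistic = x$t_statistic,
                 p_value = x$p_value, rank = x$rank, exceedance = x$exceedance)
}

#' @describeIn null_significance histogram of null peaks with the true peak
#'   marked.
#' @param object a `null_distribution`
#' @export
autoplot.null_distribution <- function(object, ...) {
  df <- tibble::tibble(peak_r = object$peaks)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$peak_r)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$true_peak, colour = "red") +
    ggplot2::labs(x = "null peak Spearman rho", y = "count",
                  title = paste0(object$kind, " null (true peak in red)")) +
    ggplot2::theme_minimal()
}
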