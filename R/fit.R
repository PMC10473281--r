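#' Spearman correlation curve between simulated and observed atrophy
#'
#' Correlates the simulated regional atrophy pattern at every timestep with a
#' single observed atrophy progression map, using Spearman's rank
#' correlation (midranks for ties), and locates the peak fit: the maximum
#' coefficient, taking the earliest timestep on exact ties. By default the
#' simulated quantity is the cumulative atrophy `L_i(t)`; `use = "increment"`
#' correlates the per-step increment instead.
#'
#' The p-value at the peak uses the usual t approximation with n - 2 degrees
#' of freedom, where n is the number of regions. Because the peak is selected
#' over many timesteps, a search-corrected p-value is also computed by
#' permuting the observed map's region labels `n_perm` times and comparing
#' the true peak against the permuted peak distribution
#' (`(1 + #{perm >= obs}) / (1 + n_perm)`).
#'
#' Timesteps where the simulated pattern is constant across regions get a
#' coefficient of 0 (with one warning); by rank invariance the whole curve is
#' unchanged by any strictly monotone transform of either input.
#'
#' @param trajectory an `atrophy_trajectory` from [sir_simulate()], or a
#'   step-by-region matrix.
#' @param observed the observed map: a tibble with columns `region`, `value`
#'   (as from [progression_map()], using its `value` column) or a plain
#'   (optionally named) numeric vector. Region names, when available on both
#'   sides, must match the trajectory's region order.
#' @param use correlate cumulative atrophy (`"L"`, default) or per-step
#'   increments (`"increment"`).
#' @param n_perm permutations for the search-corrected peak p-value
#'   (default 500; 0 disables).
#' @param seed RNG seed for the permutations.
#' @return an object of class `sir_fit`: tibble `curve` (`step`, `rho`),
#'   `peak_r`, `peak_step`, `peak_p`, `peak_p_perm`, `n_regions`.
#' @export
correlation_curve <- function(trajectory, observed, use = c("L", "increment"),
                              n_perm = 500, seed = NULL) {
  use <- match.arg(use)
  if (inherits(trajectory, "atrophy_trajectory")) {
    sim <- trajectory$L
    labels <- trajectory$labels
  } else {
    sim <- as.matrix(trajectory)
    labels <- colnames(sim)
  }
  if (use == "increment") sim <- rbind(sim[1, , drop = FALSE], diff(sim))
  obs <- observed_vector(observed, labels)
  n <- ncol(sim)
  if (n < 4) stop("need at least 4 regions for a meaningful rank correlation")
  if (nrow(sim) < 1) stop("empty trajectory")

  rnk <- t(apply(sim, 1, rank))  # midranks
  rsd <- apply(rnk, 1, stats::sd)
  const <- rsd == 0
  if (any(const)) {
    warning(sum(const), " timestep(s) had a constant simulated pattern; ",
            "their coefficient is defined as 0")
    rsd[const] <- 1
  }
  rz <- (rnk - rowMeans(rnk)) / rsd
  obs_rank <- rank(obs)
  if (stats::sd(obs_rank) == 0) {
    warning("observed map is constant across regions; all coefficients are 0")
    oz <- numeric(n)
  } else {
    oz <- (obs_rank - mean(obs_rank)) / stats::sd(obs_rank)
  }
  rho <- as.vector(rz %*% oz) / (n - 1)
  rho[const] <- 0

  peak_step <- which.max(rho)
  peak_r <- rho[peak_step]
  peak_p <- spearman_p(peak_r, n)
  peak_p_perm <- NA_real_
  if (n_perm > 0 && stats::sd(obs_rank) > 0) {
    if (!is.null(seed)) {
      peak_p_perm <- with_seed(seed, perm_peak_p(rz, oz, n, n_perm, peak_r))
    } else {
      peak_p_perm <- perm_peak_p(rz, oz, n, n_perm, peak_r)
    }
  }
  structure(list(curve = tibble::tibble(step = seq_len(nrow(sim)), rho = rho),
                 peak_r = peak_r, peak_step = peak_step, peak_p = peak_p,
                 peak_p_perm = peak_p_perm, n_regions = n, use = use),
            class = "sir_fit")
}

perm_peak_p <- function(rz, oz, n, n_perm, peak_r) {
  null_peaks <- vapply(seq_len(n_perm), function(i) {
    max(as.vector(rz %*% oz[sample.int(n)]) / (n - 1))
  }, numeric(1))
  (1 + sum(null_peaks >= peak_r)) / (1 + n_perm)
}

spearman_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

observed_vector <- function(observed, labels) {
  if (is.data.frame(observed)) {
    col <- if ("value" %in% names(observed)) "value" else "wscore"
    if (!col %in% names(observed) || !"region" %in% names(observed)) {
      stop("observed map must have columns region and value (or wscore)")
    }
    obs <- stats::setNames(observed[[col]], observed$region)
  } else {
    obs <- observed
  }
  if (!is.null(labels) && !is.null(names(obs))) {
    if (!setequal(names(obs), labels)) {
      stop("observed map regions do not match the trajectory's regions")
    }
    obs <- obs[labels]
  }
  if (length(obs) == 0 || any(!is.finite(obs))) {
    stop("observed map must be finite and non-empty")
  }
  obs
}

#' @export
print.sir_fit <- function(x, ...) {
  cat("<sir_fit> peak Spearman rho = ", sprintf("%.3f", x$peak_r),
      " at step ", x$peak_step, " (p = ", format(x$peak_p, digits = 3),
      if (!is.na(x$peak_p_perm)) paste0(", search-corrected p = ",
                                        format(x$peak_p_perm, digits = 3)),
      ") over ", nrow(x$curve), " steps, ", x$n_regions, " regions\n",
      sep = "")
  invisible(x)
}

#' @describeIn correlation_curve the per-timestep correlation curve as a
#'   tibble (`step`, `rho`).
#' @param x a `sir_fit`
#' @param ... unused
#' @export
tidy.sir_fit <- function(x, ...) x$curve

#' @describeIn correlation_curve one-row summary: `peak_r`, `peak_step`,
#'   `peak_p`, `peak_p_perm`, `n_regions`.
#' @export
glance.sir_fit <- function(x, ...) {
  tibble::tibble(peak_r = x$peak_r, peak_step = x$peak_step,
                 peak_p = x$peak_p, peak_p_perm = x$peak_p_perm,
                 n_regions = x$n_regions)
}

#' @describeIn correlation_curve plot the correlation curve with the peak
#'   marked.
#' @param object a `sir_fit`
#' @export
autoplot.sir_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$step, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::annotate("point", x = object$peak_step, y = object$peak_r,
                      colour = "red") +
    ggplot2::labs(x = "timestep", y = "Spearman rho",
                  title = sprintf("peak fit %.3f at step %d",
                                  object$peak_r, object$peak_step)) +
    ggplot2::theme_minimal()
}

#' Write a fit result to disk
#'
#' The curve goes to CSV (`step, rho`); the peak summary to JSON.
#' @param x a `sir_fit`
#' @param curve_path,summary_path output paths (`NULL` skips either part)
#' @return `x` invisibly
#' @export
write_fit <- function(x, curve_path = NULL, summary_path = NULL) {
  stopifnot(inherits(x, "sir_fit"))
  if (!is.null(curve_path)) {
    utils::write.csv(x$curve, curve_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(as.list(glance.sir_fit(x)), summary_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(x)
}
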