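#' Simulation configuration for the SIR spreading engine
#'
#' Collects every tunable of the agent-based Susceptible-Infected-Removed
#' engine. Defaults are the values used for the main analyses of the model
#' this package implements: `dt = 0.1`, per-region retention probability
#' `rho = 0.5`, propagation speed `v = 1`, `n_steps = 10000` iterations, and
#' atrophy weights `k1 = k2 = 0.5` so that direct toxicity and
#' deafferentation contribute equally.
#'
#' @param dt time increment per step, in (0, 1].
#' @param rho probability of an agent remaining in its region per unit time;
#'   scalar or per-region vector, each in \[0, 1\].
#' @param v propagation speed multiplier on the edge exit probability
#'   `min(1, v * dt / l_ij)`; > 0.
#' @param n_steps number of post-injection iterations to simulate.
#' @param seed_region label of the region where pathology is injected
#'   (the substantia nigra in the Parkinson's disease application).
#' @param injection misfolded mass placed in the seed region at t = 0; the
#'   amount is not critical (results are compared by rank), default 1.
#' @param k1,k2 weights of direct toxicity and deafferentation in the
#'   atrophy increment; both >= 0.
#' @param burn_in_tol relative change in the susceptible populations below
#'   which the pre-injection burn-in is declared converged.
#' @param burn_in_max cap on burn-in iterations.
#' @return an object of class `sir_config`.
#' @export
sir_config <- function(dt = 0.1, rho = 0.5, v = 1, n_steps = 10000,
                       seed_region = "substantia_nigra", injection = 1,
                       k1 = 0.5, k2 = 0.5,
                       burn_in_tol = 1e-7, burn_in_max = 1e6) {
  if (dt <= 0 || dt > 1) stop("dt must lie in (0, 1]")
  if (any(rho < 0) || any(rho > 1)) stop("rho must lie in [0, 1]")
  if (v <= 0) stop("v must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (injection <= 0) stop("injection must be > 0")
  if (k1 < 0 || k2 < 0) stop("k1 and k2 must be >= 0")
  structure(list(dt = dt, rho = rho, v = v, n_steps = as.integer(n_steps),
                 seed_region = seed_region, injection = injection,
                 k1 = k1, k2 = k2, burn_in_tol = burn_in_tol,
                 burn_in_max = burn_in_max),
            class = "sir_config")
}

#' @export
print.sir_config <- function(x, ...) {
  cat("<sir_config> dt=", x$dt, " rho=", paste(unique(x$rho), collapse = "/"),
      " v=", x$v, " n_steps=", x$n_steps, " seed=", x$seed_region,
      " k1=", x$k1, " k2=", x$k2, "\n", sep = "")
  invisible(x)
}

# Precomputed per-run quantities: transition fractions, rates scaled by dt.
# Regions with no outgoing edges route their outflow back to themselves,
# implemented as a zero exit fraction.
sir_engine <- function(connectome, rates, config) {
  stopifnot(inherits(connectome, "connectome"),
            inherits(rates, "rate_profile"),
            inherits(config, "sir_config"))
  n <- n_regions(connectome)
  if (length(rates$alpha) != n) stop("rate profile length does not match connectome")
  if (!is.null(rates$labels) &&
      !identical(as.character(rates$labels), connectome$regions$label)) {
    stop("rate profile labels do not align with connectome region order")
  }
  w <- connectome$weights
  l <- connectome$distances
  rho <- rep_len(config$rho, n)
  strength <- rowSums(w)
  outfrac <- w / ifelse(strength > 0, strength, 1)
  outfrac[strength == 0, ] <- 0
  exitp <- matrix(0, n, n)
  onedge <- w > 0
  exitp[onedge] <- config$v * config$dt / l[onedge]
  if (any(exitp > 1)) {
    warning(sum(exitp > 1), " edge exit probabilities clamped to 1 ",
            "(v * dt exceeds edge length)")
    exitp <- pmin(exitp, 1)
  }
  list(
    n = n,
    S = connectome$regions$size,
    synth = rates$alpha * connectome$regions$size * config$dt,
    surv = exp(-rates$beta * config$dt),
    g0dt = config$dt / connectome$regions$size,
    exitr = pmin(1, (1 - rho) * config$dt) * (strength > 0),
    outfrac = outfrac,
    exitp = exitp,
    labels = connectome$regions$label
  )
}

#' Initial (empty) SIR state
#'
#' All regional and edge populations zero, step counter zero. Populations are
#' continuous nonnegative reals: the engine is a deterministic mean-field
#' implementation of the agent model, propagating expected population
#' increments rather than individual stochastic agents.
#'
#' @param connectome a [connectome()].
#' @return an object of class `sir_state` with regional vectors `N`
#'   (susceptible), `M` (infected), edge matrices `N_edge`, `M_edge`
#'   (`[i, j]` holds agents in transit from region i to region j), the step
#'   index `t`, and running totals `cum_synthesis` and `cum_clearance`.
#' @export
sir_state <- function(connectome) {
  n <- n_regions(connectome)
  lab <- connectome$regions$label
  structure(list(
    N = stats::setNames(numeric(n), lab),
    M = stats::setNames(numeric(n), lab),
    N_edge = matrix(0, n, n, dimnames = list(lab, lab)),
    M_edge = matrix(0, n, n, dimnames = list(lab, lab)),
    t = 0L,
    cum_synthesis = 0,
    cum_clearance = 0,
    cum_injected = 0
  ), class = "sir_state")
}

#' @export
print.sir_state <- function(x, ...) {
  cat("<sir_state> t=", x$t,
      " total N=", format(sum(x$N) + sum(x$N_edge)),
      " total M=", format(sum(x$M) + sum(x$M_edge)), "\n", sep = "")
  invisible(x)
}

# One update, given a precomputed engine. Process order within a step is
# fixed: clearance -> misfolding -> mobility -> synthesis, which reproduces
# the increment algebra exactly (each loss term acts on the start-of-step
# population; newly synthesised agents are an independent additive term, so
# the isolated-region equilibrium is N* = alpha*S*dt / (1 - exp(-beta*dt))).
# Clearance and misfolding act on regional populations only; agents in
# transit on edges are exempt. Mobility and misfolding conserve agents, so
# the total population changes exactly by synthesis minus clearance (plus
# any injection) each step.
sir_step_engine <- function(state, eng) {
  N <- state$N; M <- state$M
  Ne <- state$N_edge; Me <- state$M_edge

  M_start <- M
  cleared <- sum(N) + sum(M)
  N <- N * eng$surv
  M <- M * eng$surv
  cleared <- cleared - sum(N) - sum(M)

  conv <- N * -expm1(-eng$g0dt * M_start)
  N <- N - conv
  M <- M + conv

  outN <- N * eng$exitr
  outM <- M * eng$exitr
  delivN <- Ne * eng$exitp
  delivM <- Me * eng$exitp
  state$N_edge <- Ne - delivN + outN * eng$outfrac
  state$M_edge <- Me - delivM + outM * eng$outfrac
  state$N <- N - outN + colSums(delivN) + eng$synth
  state$M <- M - outM + colSums(delivM)

  if (any(!is.finite(state$N)) || any(!is.finite(state$M)) ||
      any(state$N < 0) || any(state$M < 0)) {
    stop("population became negative or non-finite: the step size dt is too ",
         "large for these rates")
  }
  state$t <- state$t + 1L
  state$cum_synthesis <- state$cum_synthesis + sum(eng$synth)
  state$cum_clearance <- state$cum_clearance + cleared
  state
}

#' Advance the SIR state by one timestep
#'
#' Applies, in this order: (1) clearance, removing the fraction
#' `1 - exp(-beta_i * dt)` of both regional populations; (2) misfolding,
#' converting the fraction `1 - exp(-M_i * dt / S_i)` (with `M_i` at the
#' start of the step) of the surviving susceptible agents into infected
#' ones; (3) mobility, moving the fraction `min(1, (1 - rho_i) * dt)` of
#' each regional population into edges in proportion to connection weight,
#' while each edge delivers the fraction `min(1, v * dt / l_ij)` of its
#' content into its target region; (4) synthesis, adding
#' `alpha_i * S_i * dt` fresh susceptible agents to each region. This order
#' reproduces the model's increment algebra: every loss term acts on the
#' start-of-step population and synthesis is an independent additive term.
#'
#' @param state a [sir_state()].
#' @param connectome,rates,config aligned [connectome()], `rate_profile`
#'   (see [expression_to_rates()]) and [sir_config()].
#' @return the updated `sir_state`.
#' @export
sir_step <- function(state, connectome, rates, config) {
  stopifnot(inherits(state, "sir_state"))
  sir_step_engine(state, sir_engine(connectome, rates, config))
}

#' Total agent mass of a state (regions plus edges)
#' @param state a `sir_state`
#' @return named numeric with `susceptible`, `infected`, `total`
#' @export
sir_total_mass <- function(state) {
  stopifnot(inherits(state, "sir_state"))
  s <- sum(state$N) + sum(state$N_edge)
  i <- sum(state$M) + sum(state$M_edge)
  c(susceptible = s, infected = i, total = s + i)
}

#' Equilibrate the susceptible population before injection
#'
#' Runs the engine with zero infected agents until the largest relative
#' change of any regional susceptible population over one step falls below
#' `config$burn_in_tol`, so that pathology is injected into a system at its
#' synthesis-clearance steady state.
#'
#' Because the infection-free dynamics are linear in the populations, the
#' steady state can be obtained directly by solving the regional balance
#' equations; with `init = "equilibrium"` (the default) the iteration starts
#' from that solution and the convergence criterion certifies it in one step.
#' `init = "empty"` starts from zero populations and relaxes to equilibrium
#' by iteration alone.
#'
#' @inheritParams sir_step
#' @param state optional starting state (overrides `init`).
#' @param init starting point: the analytic linear-solve equilibrium
#'   (`"equilibrium"`) or the empty state (`"empty"`).
#' @return the equilibrated `sir_state` with attribute `burn_in_steps`.
#' @export
sir_burn_in <- function(connectome, rates, config, state = NULL,
                        init = c("equilibrium", "empty")) {
  init <- match.arg(init)
  eng <- sir_engine(connectome, rates, config)
  if (is.null(state)) {
    state <- sir_state(connectome)
    if (init == "equilibrium") state <- equilibrium_state(state, eng)
  }
  tol <- config$burn_in_tol
  for (k in seq_len(config$burn_in_max)) {
    prev <- state$N
    state <- sir_step_engine(state, eng)
    rel <- max(abs(state$N - prev) / pmax(abs(prev), .Machine$double.xmin))
    if (rel < tol) {
      attr(state, "burn_in_steps") <- k
      return(state)
    }
  }
  stop("burn-in did not converge within ", config$burn_in_max,
       " steps (last relative change ", format(rel), ")")
}

# Infection-free steady state from the linear balance equations:
# N = diag(surv * (1 - exitr)) N + t(G) N + synth, with
# G[i, j] = surv_i * exitr_i * outfrac[i, j]; edge loads follow from
# inflow = delivery at equilibrium. Populations book-keep synthesis and
# clearance as if the state had been reached by iteration, so conservation
# accounting stays consistent (both counters start at 0 here).
equilibrium_state <- function(state, eng) {
  n <- eng$n
  g <- (eng$surv * eng$exitr) * eng$outfrac
  a <- diag(eng$surv * (1 - eng$exitr), n) + t(g)
  nstar <- try(solve(diag(n) - a, eng$synth), silent = TRUE)
  if (inherits(nstar, "try-error") || any(!is.finite(nstar)) || any(nstar < 0)) {
    return(state)  # fall back to the empty state; iteration takes over
  }
  ne <- g * nstar
  ne[eng$exitp > 0] <- ne[eng$exitp > 0] / eng$exitp[eng$exitp > 0]
  ne[eng$exitp == 0] <- 0
  state$N[] <- nstar
  state$N_edge[] <- ne
  state
}

#' Inject misfolded pathology into the seed region
#'
#' @param state a `sir_state`, normally the output of [sir_burn_in()].
#' @param connectome the matching [connectome()].
#' @param seed_region region label receiving the pathology.
#' @param injection misfolded mass to add (> 0 for an actual injection; 0
#'   leaves the state unchanged).
#' @return the state with `M[seed_region]` incremented by `injection`.
#' @export
sir_inject <- function(state, connectome, seed_region, injection = 1) {
  stopifnot(inherits(state, "sir_state"), inherits(connectome, "connectome"))
  idx <- match(seed_region, connectome$regions$label)
  if (is.na(idx)) stop("seed region '", seed_region, "' is not in the atlas")
  if (injection < 0) stop("injection must be >= 0")
  state$M[idx] <- state$M[idx] + injection
  state$cum_injected <- state$cum_injected + injection
  state
}

#' Simulate pathology spread and atrophy accrual
#'
#' Full pipeline for one run: burn the susceptible system in to equilibrium,
#' inject misfolded pathology into the seed region, then iterate
#' `config$n_steps` steps, recording at every step the regional infected
#' fraction `r_i(t) = M_i / (N_i + M_i)` (0 where the region is empty) and
#' the cumulative simulated atrophy `L_i(t)` accrued from direct toxicity
#' plus deafferentation (see [accrue_atrophy()]). Deterministic given its
#' inputs.
#'
#' @inheritParams sir_step
#' @param record_populations also keep per-step `N` and `M` matrices
#'   (default `TRUE`; disable to save memory in large null-model batches).
#' @return an object of class `atrophy_trajectory`: step-by-region matrices
#'   `r` and `L` (and `N`, `M` if recorded), region `labels`, the `config`,
#'   the `final_state`, and `burn_in_steps`.
#' @export
sir_simulate <- function(connectome, rates, config = sir_config(),
                         record_populations = TRUE) {
  eng <- sir_engine(connectome, rates, config)
  state <- sir_burn_in(connectome, rates, config)
  burn_steps <- attr(state, "burn_in_steps")
  state <- sir_inject(state, connectome, config$seed_region, config$injection)
  state$t <- 0L

  n <- eng$n
  ns <- config$n_steps
  r_mat <- matrix(0, ns, n, dimnames = list(NULL, eng$labels))
  L_mat <- matrix(0, ns, n, dimnames = list(NULL, eng$labels))
  if (record_populations) {
    N_mat <- matrix(0, ns, n, dimnames = list(NULL, eng$labels))
    M_mat <- matrix(0, ns, n, dimnames = list(NULL, eng$labels))
  }
  aff <- afferent_weights(connectome$weights)
  r_prev <- numeric(n)
  L <- numeric(n)
  for (s in seq_len(ns)) {
    state <- sir_step_engine(state, eng)
    tot <- state$N + state$M
    r_now <- ifelse(tot > 0, state$M / tot, 0)
    L <- L + atrophy_increment(r_now, r_prev, aff, config$k1, config$k2, config$dt)
    r_mat[s, ] <- r_now
    L_mat[s, ] <- L
    if (record_populations) {
      N_mat[s, ] <- state$N
      M_mat[s, ] <- state$M
    }
    r_prev <- r_now
  }
  out <- list(r = r_mat, L = L_mat,
              N = if (record_populations) N_mat,
              M = if (record_populations) M_mat,
              labels = eng$labels, config = config,
              final_state = state, burn_in_steps = burn_steps)
  class(out) <- "atrophy_trajectory"
  out
}

#' @export
print.atrophy_trajectory <- function(x, ...) {
  cat("<atrophy_trajectory> ", nrow(x$r), " steps x ", ncol(x$r),
      " regions (burn-in ", x$burn_in_steps, " steps)\n", sep = "")
  cat("  final infected fraction: ",
      sprintf("%.4f (min) .. %.4f (max)", min(x$r[nrow(x$r), ]),
              max(x$r[nrow(x$r), ])), "\n", sep = "")
  invisible(x)
}

#' Tidy a simulated trajectory into long format
#'
#' @param x an `atrophy_trajectory` from [sir_simulate()].
#' @param ... unused.
#' @return a tibble with columns `step`, `region`, `r`, `L` and, when
#'   populations were recorded, `N` and `M`.
#' @export
tidy.atrophy_trajectory <- function(x, ...) {
  ns <- nrow(x$r)
  out <- tibble::tibble(
    step = rep(seq_len(ns), times = ncol(x$r)),
    region = rep(x$labels, each = ns),
    r = as.vector(x$r),
    L = as.vector(x$L)
  )
  if (!is.null(x$N)) {
    out$N <- as.vector(x$N)
    out$M <- as.vector(x$M)
  }
  out
}

#' Write a trajectory as long-format CSV
#' @param x an `atrophy_trajectory`
#' @param path output file
#' @param every keep every `every`-th step (default 1 = all steps).
#' @return `x`, invisibly
#' @export
write_trajectory <- function(x, path, every = 1) {
  df <- tidy.atrophy_trajectory(x)
  if (every > 1) df <- df[df$step %% every == 0, , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Plot simulated atrophy and infected-fraction curves
#'
#' @param object an `atrophy_trajectory`
#' @param what `"L"` (cumulative atrophy) or `"r"` (infected fraction)
#' @param ... unused
#' @return a ggplot object with one line per region
#' @export
autoplot.atrophy_trajectory <- function(object, what = c("L", "r"), ...) {
  what <- match.arg(what)
  df <- tidy.atrophy_trajectory(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data[[what]],
                                   group = .data$region)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "timestep",
                  y = if (what == "L") "cumulative simulated atrophy"
                      else "infected fraction r") +
    ggplot2::theme_minimal()
}
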