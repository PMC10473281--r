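#' Specification of a synthetic study
#'
#' Parameters for generating self-contained synthetic inputs with the
#' statistical structure the pipeline assumes: a spatially embedded weighted
#' network whose connection strengths decay with distance, spatially
#' autocorrelated expression maps for the synthesis and clearance genes, and
#' a longitudinal cohort whose deformation values follow a linear age/sex
#' normative model plus an implanted atrophy signal taken from a simulated
#' trajectory.
#'
#' Defaults are sized to the Parkinson's-disease application the model was
#' built for: 42 regions, 157 baseline controls, and 113/104/79 patients at
#' the 1-, 2- and 4-year follow-ups, with control and patient age/sex
#' distributions matching that cohort.
#'
#' @param n_regions number of regions (default 42).
#' @param extent side (mm) of the cubic volume regions are placed in.
#' @param lambda_weight distance-decay scale (mm) of connection strength.
#' @param density target edge density of the thresholded network.
#' @param expr_length spatial autocorrelation length (mm) of expression maps.
#' @param size_meanlog,size_sdlog lognormal parameters of region sizes
#'   (voxel counts).
#' @param weight_noise_sdlog lognormal spread of edge-strength noise.
#' @param n_controls,n_patients control count and named per-follow-up patient
#'   counts.
#' @param control_age,patient_age mean and SD of age (years) per group.
#' @param prop_male_control,prop_male_patient male proportions (sex coded 1).
#' @param beta_age,beta_sex,intercept_sd normative coefficients: deformation
#'   declines slightly with age; per-region intercepts drawn with SD
#'   `intercept_sd`.
#' @param noise_sd residual SD of deformation values around the normative
#'   model.
#' @param amplitude strength of the implanted atrophy signal, in deformation
#'   units per standardised unit of simulated atrophy.
#' @param t_star_frac fractions of the trajectory length at which the atrophy
#'   signal is sampled for baseline and each follow-up.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_regions = 42, extent = 140, lambda_weight = 35,
                       density = 0.35, expr_length = 30,
                       size_meanlog = log(500), size_sdlog = 0.4,
                       weight_noise_sdlog = 0.5,
                       n_controls = 157,
                       n_patients = c(year1 = 113, year2 = 104, year4 = 79),
                       control_age = c(60.1, 11.9),
                       patient_age = c(60.9, 10.0),
                       prop_male_control = 0.66, prop_male_patient = 0.63,
                       beta_age = -0.004, beta_sex = -0.02,
                       intercept_sd = 0.05, noise_sd = 0.1, amplitude = 0.3,
                       t_star_frac = c(baseline = 0.1, year1 = 0.4,
                                       year2 = 0.6, year4 = 0.8)) {
  if (density <= 0 || density >= 1) stop("density must lie in (0, 1)")
  if (any(c(extent, lambda_weight, expr_length, noise_sd) <= 0)) {
    stop("scales must be > 0")
  }
  structure(as.list(environment()), class = "synth_spec")
}

#' Generate a synthetic spatially embedded connectome
#'
#' Regions are placed uniformly at random in a cube; undirected edge
#' strengths are `exp(-d_ij / lambda_weight)` times lognormal noise,
#' thresholded to the target density by keeping the strongest edges; region
#' sizes are lognormal; distances are centroid Euclidean. Connectivity is
#' guaranteed: any disconnected component is re-linked through its shortest
#' centroid distance to the rest of the network.
#'
#' @param spec a [synth_spec()].
#' @param seed RNG seed.
#' @return a [connectome()] with region labels `roi_01`, `roi_02`, ...
#' @export
make_connectome <- function(spec = synth_spec(), seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, {
    n <- spec$n_regions
    regions <- tibble::tibble(
      label = sprintf("roi_%02d", seq_len(n)),
      size = stats::rlnorm(n, spec$size_meanlog, spec$size_sdlog),
      x = stats::runif(n, 0, spec$extent),
      y = stats::runif(n, 0, spec$extent),
      z = stats::runif(n, 0, spec$extent)
    )
    d <- euclidean_distances(regions)
    w <- exp(-d / spec$lambda_weight) *
      matrix(stats::rlnorm(n * n, 0, spec$weight_noise_sdlog), n, n)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    ut <- which(upper.tri(w), arr.ind = TRUE)
    n_keep <- round(spec$density * nrow(ut))
    keep <- order(w[ut], decreasing = TRUE)[seq_len(n_keep)]
    thr <- matrix(0, n, n)
    thr[ut[keep, , drop = FALSE]] <- w[ut[keep, , drop = FALSE]]
    w <- thr + t(thr)

    # re-link any disconnected component through its closest outside region
    repeat {
      comp <- igraph::components(
        igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected"))
      if (comp$no == 1) break
      main <- which(comp$membership == which.max(comp$csize))
      other <- which(comp$membership != which.max(comp$csize))
      dsub <- d[other, main, drop = FALSE]
      idx <- which(dsub == min(dsub), arr.ind = TRUE)[1, ]
      i <- other[idx[1]]; j <- main[idx[2]]
      w[i, j] <- w[j, i] <- exp(-d[i, j] / spec$lambda_weight)
    }
    connectome(regions, w)
  })
}

#' Generate spatially autocorrelated synthetic expression maps
#'
#' Each gene is one draw of a Gaussian random field over the region centroids
#' with exponential covariance `exp(-d_ij / expr_length)`, mimicking the
#' smooth spatial structure of regional transcriptomic maps.
#'
#' @param spec a [synth_spec()].
#' @param connectome the [make_connectome()] output (provides geometry).
#' @param seed RNG seed.
#' @return an [expression_profile()] aligned to the connectome.
#' @export
make_expression <- function(spec, connectome, seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"), inherits(connectome, "connectome"))
  with_seed(seed, {
    d <- connectome$centroid_distances
    n <- nrow(d)
    cc <- exp(-d / spec$expr_length) + diag(1e-9, n)
    cl <- chol(cc)
    field <- function() as.vector(crossprod(cl, stats::rnorm(n)))
    expression_profile(field(), field(), labels = connectome$regions$label)
  })
}

#' Generate a synthetic longitudinal deformation cohort
#'
#' Control deformation values follow the linear normative model
#' `beta3_i + beta_age * age + beta_sex * sex + noise`; patients additionally
#' carry an implanted atrophy signal: at each timepoint the per-region
#' standardised cumulative simulated atrophy `L(T*)` is subtracted, scaled by
#' `amplitude` (more simulated atrophy, more negative deformation). The
#' sampling timestep `T*` advances across timepoints per `spec$t_star_frac`,
#' so later follow-ups express a more advanced stage of the simulated
#' pathology. Each follow-up's patients get a baseline row and one follow-up
#' row (ages advanced by the nominal follow-up interval).
#'
#' @param spec a [synth_spec()].
#' @param connectome region order provider.
#' @param trajectory an `atrophy_trajectory` the signal is sampled from.
#' @param seed RNG seed.
#' @return list with `cohort` (tibble: subject, group, timepoint, age, sex,
#'   one column per region) and `truth` (generator parameters plus the
#'   implanted per-timepoint signal matrix and `t_star` steps), for recovery
#'   tests.
#' @export
make_cohort <- function(spec, connectome, trajectory, seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"), inherits(connectome, "connectome"),
            inherits(trajectory, "atrophy_trajectory"))
  labels <- connectome$regions$label
  n <- length(labels)
  ns <- nrow(trajectory$L)
  t_star <- stats::setNames(pmax(1L, pmin(ns, as.integer(round(spec$t_star_frac * ns)))),
                            names(spec$t_star_frac))
  # One common scale across timepoints (the regional SD of the most advanced
  # sampled map), so the implanted signal grows over time the way cumulative
  # atrophy does; per-timepoint standardisation would give the mild baseline
  # pattern the same weight as the advanced follow-up pattern.
  scale <- stats::sd(trajectory$L[max(t_star), ])
  if (scale == 0) scale <- 1
  zsig <- t(vapply(t_star, function(s) trajectory$L[s, ] / scale, numeric(n)))
  rownames(zsig) <- names(spec$t_star_frac)

  with_seed(seed, {
    beta3 <- stats::rnorm(n, 0, spec$intercept_sd)
    normative <- function(age, sex) {
      outer(age, rep(1, n)) * spec$beta_age +
        outer(as.numeric(sex), rep(1, n)) * spec$beta_sex +
        matrix(beta3, length(age), n, byrow = TRUE)
    }
    noise <- function(m) matrix(stats::rnorm(m * n, 0, spec$noise_sd), m, n)

    ctrl_age <- stats::rnorm(spec$n_controls, spec$control_age[1], spec$control_age[2])
    ctrl_age <- pmax(ctrl_age, 30)
    ctrl_sex <- stats::rbinom(spec$n_controls, 1, spec$prop_male_control)
    ctrl_vals <- normative(ctrl_age, ctrl_sex) + noise(spec$n_controls)
    rows <- list(make_rows(sprintf("ctrl_%03d", seq_len(spec$n_controls)),
                           "control", "baseline", ctrl_age, ctrl_sex,
                           ctrl_vals, labels))

    fu_years <- c(year1 = 1, year2 = 2, year4 = 4)
    for (tp in names(spec$n_patients)) {
      np <- spec$n_patients[[tp]]
      age <- pmax(stats::rnorm(np, spec$patient_age[1], spec$patient_age[2]), 30)
      sex <- stats::rbinom(np, 1, spec$prop_male_patient)
      id <- sprintf("pat_%s_%03d", tp, seq_len(np))
      bl <- normative(age, sex) + noise(np) -
        spec$amplitude * matrix(zsig["baseline", ], np, n, byrow = TRUE)
      fu_age <- age + fu_years[[tp]]
      fu <- normative(fu_age, sex) + noise(np) -
        spec$amplitude * matrix(zsig[tp, ], np, n, byrow = TRUE)
      rows <- c(rows,
                list(make_rows(id, "patient", "baseline", age, sex, bl, labels),
                     make_rows(id, "patient", tp, fu_age, sex, fu, labels)))
    }
    list(cohort = dplyr::bind_rows(rows),
         truth = list(beta_age = spec$beta_age, beta_sex = spec$beta_sex,
                      intercepts = beta3, noise_sd = spec$noise_sd,
                      amplitude = spec$amplitude, t_star = t_star,
                      signal = zsig))
  })
}

make_rows <- function(subject, group, timepoint, age, sex, values, labels) {
  out <- tibble::tibble(subject = subject, group = group,
                        timepoint = timepoint, age = age, sex = sex)
  vals <- tibble::as_tibble(as.data.frame(values))
  names(vals) <- labels
  dplyr::bind_cols(out, vals)
}

#' Generate a stack of per-subject synthetic connectomes
#'
#' Per-subject weight matrices share the same distance-decay backbone but
#' differ by multiplicative lognormal noise and by which edges each subject
#' expresses (each subject keeps their strongest `subject_density` fraction
#' of edges), the structure group-consensus thresholding expects.
#'
#' @param spec a [synth_spec()].
#' @param n_subjects number of subjects.
#' @param subject_density per-subject edge density before consensus.
#' @param seed RNG seed.
#' @return list with `stack` (list of matrices) and `regions` (tibble).
#' @export
make_connectome_stack <- function(spec = synth_spec(), n_subjects = 10,
                                  subject_density = 0.5, seed = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, {
    n <- spec$n_regions
    regions <- tibble::tibble(
      label = sprintf("roi_%02d", seq_len(n)),
      size = stats::rlnorm(n, spec$size_meanlog, spec$size_sdlog),
      x = stats::runif(n, 0, spec$extent),
      y = stats::runif(n, 0, spec$extent),
      z = stats::runif(n, 0, spec$extent)
    )
    d <- euclidean_distances(regions)
    base <- exp(-d / spec$lambda_weight)
    diag(base) <- 0
    ut <- which(upper.tri(base), arr.ind = TRUE)
    n_keep <- round(subject_density * nrow(ut))
    stack <- lapply(seq_len(n_subjects), function(s) {
      noise <- matrix(stats::rlnorm(n * n, 0, spec$weight_noise_sdlog), n, n)
      w <- base * (noise + t(noise)) / 2
      keep <- order(w[ut], decreasing = TRUE)[seq_len(n_keep)]
      thr <- matrix(0, n, n, dimnames = list(regions$label, regions$label))
      thr[ut[keep, , drop = FALSE]] <- w[ut[keep, , drop = FALSE]]
      thr + t(thr)
    })
    list(stack = stack, regions = regions)
  })
}
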