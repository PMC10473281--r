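#' Fit a normative model of regional deformation on healthy controls
#'
#' For every region, ordinary least squares of the deformation value on age,
#' sex and an intercept, fitted over the control subjects:
#' `deformation ~ beta1 * age + beta2 * sex + beta3`. The per-region residual
#' standard deviation over controls (denominator n - 1) becomes the W-score
#' scale, so the controls' own W-scores have mean 0 and SD exactly 1 under
#' this convention.
#'
#' Only baseline controls are used: rows are filtered to
#' `group == control_group` and, when a `timepoint` column is present,
#' `timepoint == baseline`. Follow-up controls are typically too few to
#' stabilise the normative fit.
#'
#' @param cohort a data frame with columns `age` (years, > 0), `sex` (0/1
#'   indicator; the coding is recorded in the model), one column per region,
#'   and optionally `group` and `timepoint` for filtering.
#' @param regions character vector naming the region columns; defaults to all
#'   columns other than the recognised metadata columns
#'   (`subject`, `group`, `timepoint`, `age`, `sex`).
#' @param control_group,baseline values of `group`/`timepoint` selecting the
#'   normative rows (ignored when the column is absent).
#' @return an object of class `normative_model`: coefficient matrix
#'   `coefficients` (rows `age`, `sex`, `intercept`; one column per region),
#'   vector `resid_sd`, `regions`, `n_controls`, and the `sex_coding` note.
#' @export
fit_normative <- function(cohort, regions = NULL, control_group = "control",
                          baseline = "baseline") {
  cohort <- tibble::as_tibble(cohort)
  if ("group" %in% names(cohort)) cohort <- cohort[cohort$group == control_group, ]
  if ("timepoint" %in% names(cohort)) cohort <- cohort[cohort$timepoint == baseline, ]
  if (is.null(regions)) {
    regions <- setdiff(names(cohort), c("subject", "group", "timepoint", "age", "sex"))
  }
  if (length(regions) == 0) stop("no region columns found")
  n <- nrow(cohort)
  if (n < 3) stop("need at least 3 control subjects to fit the normative model")
  if (any(cohort$age <= 0)) stop("ages must be > 0")
  y <- as.matrix(cohort[, regions, drop = FALSE])
  if (any(!is.finite(y))) stop("missing or non-finite deformation values in controls")
  x <- cbind(age = cohort$age, sex = as.numeric(cohort$sex), intercept = 1)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    stop("design is rank-deficient: age and sex must not be constant or collinear")
  }
  if (n <= ncol(x)) stop("fewer control subjects than model parameters")
  coefs <- qr.coef(qx, y)
  resid <- y - x %*% coefs
  resid_sd <- apply(resid, 2, stats::sd)  # n - 1 denominator
  if (any(resid_sd <= .Machine$double.eps^0.5 * apply(abs(y), 2, max))) {
    stop("degenerate normative fit: residual SD is (numerically) zero in ",
         "at least one region")
  }
  structure(list(coefficients = coefs, resid_sd = resid_sd, regions = regions,
                 n_controls = n, sex_coding = "0/1 as supplied"),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model> ", length(x$regions), " regions, fitted on ",
      x$n_controls, " controls (sex coded ", x$sex_coding, ")\n", sep = "")
  invisible(x)
}

#' @describeIn fit_normative tidy the per-region coefficients into a tibble
#'   with columns `region`, `beta_age`, `beta_sex`, `intercept`, `resid_sd`.
#' @param x a `normative_model`
#' @param ... unused
#' @export
tidy.normative_model <- function(x, ...) {
  tibble::tibble(region = x$regions,
                 beta_age = unname(x$coefficients["age", ]),
                 beta_sex = unname(x$coefficients["sex", ]),
                 intercept = unname(x$coefficients["intercept", ]),
                 resid_sd = unname(x$resid_sd))
}

#' @describeIn fit_normative one-row model summary
#' @export
glance.normative_model <- function(x, ...) {
  tibble::tibble(n_controls = x$n_controls, n_regions = length(x$regions),
                 median_resid_sd = stats::median(x$resid_sd))
}

#' W-scores: age- and sex-adjusted regional deviations
#'
#' For a single subject, `W_i = (raw_i - (beta1_i * age + beta2_i * sex +
#' beta3_i)) / SD_i`, where the coefficients and residual SD come from the
#' control normative fit. A value at its age/sex-expected level scores 0; a
#' value one control residual SD away scores 1.
#'
#' @param values per-region raw deformation vector, in the model's region
#'   order (names, if present, are checked).
#' @param age,sex scalar covariates (sex coded as in the normative fit).
#' @param model a [fit_normative()] model.
#' @return named per-region W-score vector.
#' @export
w_score <- function(values, age, sex, model) {
  stopifnot(inherits(model, "normative_model"))
  values <- unlist(values)
  if (length(values) != length(model$regions)) {
    stop("values length does not match the model's region count")
  }
  if (!is.null(names(values)) && !identical(names(values), model$regions)) {
    stop("value names do not match the model's region order")
  }
  pred <- as.vector(crossprod(model$coefficients, c(age, as.numeric(sex), 1)))
  stats::setNames((values - pred) / model$resid_sd, model$regions)
}

#' W-score every row of a cohort table
#'
#' @param cohort data frame with `age`, `sex` and the model's region columns;
#'   metadata columns are carried through unchanged.
#' @param model a [fit_normative()] model.
#' @return tibble with the metadata columns and region columns replaced by
#'   W-scores.
#' @export
cohort_wscores <- function(cohort, model) {
  stopifnot(inherits(model, "normative_model"))
  cohort <- tibble::as_tibble(cohort)
  missing_regions <- setdiff(model$regions, names(cohort))
  if (length(missing_regions) > 0) {
    stop("cohort is missing region column(s): ",
         paste(utils::head(missing_regions, 3), collapse = ", "))
  }
  y <- as.matrix(cohort[, model$regions, drop = FALSE])
  x <- cbind(cohort$age, as.numeric(cohort$sex), 1)
  w <- (y - x %*% model$coefficients) /
    matrix(model$resid_sd, nrow(y), ncol(y), byrow = TRUE)
  out <- cohort
  out[, model$regions] <- w
  out
}

#' Average W-score map at one timepoint
#'
#' Averages subject-level W-scores per region over the selected rows
#' (typically the patients at one timepoint), yielding one regional map.
#'
#' @param wscores output of [cohort_wscores()].
#' @param timepoint value of the `timepoint` column to select.
#' @param group value of the `group` column to select (default `"patient"`;
#'   ignored when the column is absent).
#' @param regions region columns; default: every non-metadata column.
#' @return tibble with columns `region`, `wscore`.
#' @export
wscore_map <- function(wscores, timepoint, group = "patient", regions = NULL) {
  wscores <- tibble::as_tibble(wscores)
  if ("group" %in% names(wscores)) wscores <- wscores[wscores$group == group, ]
  wscores <- wscores[wscores$timepoint == timepoint, ]
  if (nrow(wscores) == 0) stop("no rows at timepoint '", timepoint, "'")
  if (is.null(regions)) {
    regions <- setdiff(names(wscores), c("subject", "group", "timepoint", "age", "sex"))
  }
  tibble::tibble(region = regions,
                 wscore = colMeans(as.matrix(wscores[, regions, drop = FALSE])))
}

#' Atrophy progression map between two timepoints
#'
#' Subtracts the baseline map from the follow-up map and, by default, inverts
#' the sign so that a positive value means atrophy progression (tissue loss
#' appears as increasingly negative deformation W-scores in the usual
#' deformation-based morphometry convention). The sign convention depends on
#' the upstream morphometry pipeline, so the inversion is a configuration,
#' not a constant; the choice is recorded in the result's
#' `"sign_convention"` attribute.
#'
#' `progression_map(a, b) == -progression_map(b, a)` region-wise.
#'
#' @param baseline,followup tibbles from [wscore_map()] (columns `region`,
#'   `wscore`), region-aligned.
#' @param invert multiply the difference by -1 (default `TRUE`).
#' @return tibble with columns `region`, `value`, carrying a
#'   `sign_convention` attribute.
#' @export
progression_map <- function(baseline, followup, invert = TRUE) {
  if (!identical(baseline$region, followup$region)) {
    stop("baseline and follow-up maps are not region-aligned")
  }
  sgn <- if (invert) -1 else 1
  out <- tibble::tibble(region = baseline$region,
                        value = sgn * (followup$wscore - baseline$wscore))
  attr(out, "sign_convention") <-
    if (invert) "positive value = atrophy progression (difference inverted)"
    else "raw follow-up minus baseline difference"
  out
}

#' Serialize / restore a normative model as JSON
#' @param model a `normative_model`
#' @param path file path
#' @return `model` invisibly / the restored `normative_model`
#' @export
write_normative <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  jsonlite::write_json(
    list(coefficients = as.data.frame(t(model$coefficients)),
         resid_sd = model$resid_sd, regions = model$regions,
         n_controls = model$n_controls, sex_coding = model$sex_coding),
    path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_normative
#' @export
read_normative <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- t(as.matrix(x$coefficients))
  colnames(coefs) <- x$regions
  structure(list(coefficients = coefs,
                 resid_sd = stats::setNames(x$resid_sd, x$regions),
                 regions = x$regions, n_controls = x$n_controls,
                 sex_coding = x$sex_coding),
            class = "normative_model")
}
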