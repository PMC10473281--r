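wscore_fixture <- function() {
  # 5 controls, 2 regions, printed values solved by hand against the
  # normal-equations oracle below
  tibble::tibble(
    subject = sprintf("c%d", 1:5), group = "control", timepoint = "baseline",
    age = c(55, 60, 65, 70, 75), sex = c(0, 1, 0, 1, 0),
    ra = c(1.10, 0.95, 0.80, 0.72, 0.55),
    rb = c(0.40, 0.52, 0.45, 0.60, 0.50)
  )
}

ols_oracle <- function(cohort, region) {
  # closed-form normal equations, independent of the package's QR path
  x <- cbind(cohort$age, cohort$sex, 1)
  y <- cohort[[region]]
  beta <- solve(t(x) %*% x, t(x) %*% y)
  resid <- y - x %*% beta
  list(beta = as.vector(beta), sd = sqrt(sum(resid^2) / (length(y) - 1)))
}

test_that("normative fit matches a hand-solved normal-equations oracle", {
  coh <- wscore_fixture()
  nm <- fit_normative(coh)
  for (rg in c("ra", "rb")) {
    o <- ols_oracle(coh, rg)
    expect_equal(unname(nm$coefficients[, rg]), o$beta, tolerance = 1e-10)
    expect_equal(unname(nm$resid_sd[[rg]]), o$sd, tolerance = 1e-10)
  }
  # row permutation changes nothing
  nm2 <- fit_normative(coh[sample(5), ])
  expect_equal(nm2$coefficients, nm$coefficients)
  expect_equal(nm2$resid_sd, nm$resid_sd)
  # tidy/glance surface the same numbers
  td <- tidy(nm)
  expect_equal(td$beta_age, unname(nm$coefficients["age", ]))
  expect_equal(glance(nm)$n_controls, 5)
})

test_that("normative fit rejects degenerate designs and noiseless data", {
  coh <- wscore_fixture()
  coh_const <- coh; coh_const$sex <- 1
  expect_error(fit_normative(coh_const), "rank-deficient")
  expect_error(fit_normative(coh[1:2, ]), "at least 3")
  # exactly linear data has zero residual SD: degeneracy, not a model
  coh_exact <- coh
  coh_exact$ra <- 0.5 + 0.01 * coh_exact$age - 0.2 * coh_exact$sex
  expect_error(fit_normative(coh_exact), "degenerate")
  coh_na <- coh; coh_na$rb[2] <- NA
  expect_error(fit_normative(coh_na), "missing|finite")
})

test_that("W-scores are the SD-scaled deviation from the age/sex prediction", {
  coh <- wscore_fixture()
  nm <- fit_normative(coh)
  pred <- as.vector(crossprod(nm$coefficients, c(62, 1, 1)))
  expect_equal(unname(w_score(pred, 62, 1, nm)), c(0, 0))
  expect_equal(unname(w_score(pred + nm$resid_sd, 62, 1, nm)), c(1, 1))
  # equivariance: +delta in one region shifts its W by delta / SD
  w0 <- w_score(pred, 62, 1, nm)
  w1 <- w_score(pred + c(0.3, 0), 62, 1, nm)
  expect_equal(w1[["ra"]] - w0[["ra"]], 0.3 / nm$resid_sd[["ra"]])
  expect_equal(w1[["rb"]], w0[["rb"]])
})

test_that("control W-scores have mean 0 and SD exactly 1 per region", {
  spec <- tiny_spec()
  cn <- make_connectome(spec, seed = 31)
  rates <- expression_to_rates(make_expression(spec, cn, seed = 32))
  traj <- sir_simulate(cn, rates, sir_config(n_steps = 300, seed_region = "roi_01"),
                       record_populations = FALSE)
  coh <- make_cohort(spec, cn, traj, seed = 33)$cohort
  nm <- fit_normative(coh)
  ws <- cohort_wscores(coh, nm)
  ctrl <- ws[ws$group == "control", nm$regions]
  expect_lt(max(abs(colMeans(as.matrix(ctrl)))), 1e-8)
  expect_equal(unname(apply(as.matrix(ctrl), 2, sd)), rep(1, length(nm$regions)),
               tolerance = 1e-10)
})

test_that("an implanted +2 SD deviation is recovered region-specifically", {
  set.seed(44)
  n_ctrl <- 60
  regions <- sprintf("reg%02d", 1:10)
  age <- runif(n_ctrl, 45, 80)
  sex <- rbinom(n_ctrl, 1, 0.5)
  vals <- sapply(regions, function(r) 0.2 - 0.003 * age + 0.05 * sex +
                                      rnorm(n_ctrl, 0, 0.1))
  coh <- dplyr::bind_cols(tibble::tibble(subject = sprintf("c%d", 1:n_ctrl),
                                         group = "control", timepoint = "baseline",
                                         age = age, sex = sex),
                          tibble::as_tibble(as.data.frame(vals)))
  nm <- fit_normative(coh)
  hit <- c("reg02", "reg05", "reg09")
  patient <- 0.2 - 0.003 * 61 + 0.05 * 1 + rnorm(10, 0, 0.02)
  names(patient) <- regions
  patient[hit] <- patient[hit] + 2 * nm$resid_sd[hit]
  w <- w_score(patient, 61, 1, nm)
  expect_true(all(abs(w[hit] - 2) < 0.5))
  expect_true(all(abs(w[setdiff(regions, hit)]) < 0.5))
})

test_that("progression maps difference, invert and antisymmetrize correctly", {
  base <- tibble::tibble(region = c("a", "b", "c"), wscore = c(0.2, -0.1, 0.5))
  fu <- base
  expect_equal(progression_map(base, fu)$value, c(0, 0, 0))
  fu$wscore[2] <- base$wscore[2] - 1  # one region loses one W unit
  pm <- progression_map(base, fu)
  expect_equal(pm$value, c(0, 1, 0))
  expect_equal(progression_map(fu, base)$value, -pm$value)
  raw <- progression_map(base, fu, invert = FALSE)
  expect_equal(raw$value, -pm$value)
  expect_match(attr(pm, "sign_convention"), "progression")
  fu_bad <- fu; fu_bad$region <- rev(fu_bad$region)
  expect_error(progression_map(base, fu_bad), "aligned")
})

test_that("normative models survive a JSON round trip", {
  nm <- fit_normative(wscore_fixture())
  path <- file.path(tempdir(), "nm.json")
  write_normative(nm, path)
  nm2 <- read_normative(path)
  expect_equal(nm2$coefficients, nm$coefficients, tolerance = 1e-12)
  expect_equal(unname(nm2$resid_sd), unname(nm$resid_sd), tolerance = 1e-12)
  expect_identical(nm2$regions, nm$regions)
  unlink(path)
})
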