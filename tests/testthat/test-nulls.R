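test_that("rewiring preserves degrees, edge count and the weight multiset", {
  spec <- tiny_spec()
  cn <- make_connectome(spec, seed = 51)
  deg0 <- sort(colSums(cn$weights > 0))
  w0 <- sort(cn$weights[upper.tri(cn$weights) & cn$weights > 0])
  changed <- 0
  for (s in 1:25) {
    rw <- rewire_connectome(cn, swaps_per_edge = 20, seed = s)
    expect_identical(sort(colSums(rw$weights > 0)), deg0)
    expect_equal(sort(rw$weights[upper.tri(rw$weights) & rw$weights > 0]), w0)
    expect_identical(rw$weights, t(rw$weights))
    expect_true(all(diag(rw$weights) == 0))
    # distances remain positive on every rewired edge
    expect_true(all(rw$distances[rw$weights > 0] > 0))
    if (!identical(rw$weights, cn$weights)) changed <- changed + 1
  }
  expect_gt(changed, 20)  # rewiring actually moves edges
  # deterministic under a fixed seed
  expect_identical(rewire_connectome(cn, 20, seed = 3)$weights,
                   rewire_connectome(cn, 20, seed = 3)$weights)
})

test_that("complete graphs admit no swaps and are returned intact", {
  regions <- tibble::tibble(label = sprintf("r%d", 1:4), size = 10,
                            x = c(0, 10, 20, 30), y = 0, z = 0)
  w <- matrix(runif(16, 1, 2), 4, 4); w <- (w + t(w)) / 2; diag(w) <- 0
  cn <- connectome(regions, w)
  expect_warning(rw <- rewire_connectome(cn, 10, seed = 1), "no admissible swaps")
  expect_identical(rw$weights, cn$weights)
})

test_that("repositioning permutes geometry but never touches weights", {
  cn <- make_connectome(tiny_spec(), seed = 52)
  for (s in 1:10) {
    rp <- reposition_connectome(cn, seed = s)
    expect_identical(rp$weights, cn$weights)
    expect_identical(rp$regions$size, cn$regions$size)
    expect_identical(rp$regions$label, cn$regions$label)
    # coordinates are a permutation, so the distance multiset is preserved
    expect_equal(sort(rp$centroid_distances[upper.tri(rp$centroid_distances)]),
                 sort(cn$centroid_distances[upper.tri(cn$centroid_distances)]),
                 tolerance = 1e-12)
    expect_equal(sort(rp$regions$x), sort(cn$regions$x))
  }
  expect_identical(reposition_connectome(cn, seed = 9)$regions$x,
                   reposition_connectome(cn, seed = 9)$regions$x)
})

test_that("expression shuffles are value-preserving, targeted and seeded", {
  set.seed(3)
  expr <- expression_profile(rnorm(20), rnorm(20))
  sh <- shuffle_expression(expr, "synthesis", seed = 1)
  expect_equal(sort(sh$synthesis), sort(expr$synthesis))
  expect_identical(sh$clearance, expr$clearance)
  sh2 <- shuffle_expression(expr, "clearance", seed = 1)
  expect_identical(sh2$synthesis, expr$synthesis)
  expect_equal(sort(sh2$clearance), sort(expr$clearance))
  expect_identical(shuffle_expression(expr, "both", seed = 2)$synthesis,
                   shuffle_expression(expr, "both", seed = 2)$synthesis)
  # single-region profile cannot change
  e1 <- expression_profile(1.5, 2.5)
  expect_identical(shuffle_expression(e1, "both", seed = 1), e1)
})

test_that("surrogates preserve values exactly and autocorrelation approximately", {
  spec <- study_spec()
  cn <- make_connectome(spec, seed = 1)
  expr <- make_expression(spec, cn, seed = 2)
  d <- cn$centroid_distances
  vg0 <- variogram(expr$synthesis, d, 25)
  for (s in 1:5) {
    sx <- surrogate_expression(expr, d, "synthesis", seed = s)
    expect_equal(sort(sx$synthesis), sort(expr$synthesis))  # exact multiset
    expect_identical(sx$clearance, expr$clearance)
    mism <- sirspread:::variogram_mismatch(vg0, variogram(sx$synthesis, d, 25))
    expect_lt(mism, 0.2)
  }
  # a smooth gradient keeps its distance-decay structure under the surrogate
  # but loses it under a plain shuffle
  grad <- expression_profile(cn$regions$x / 10, rnorm(42),
                             labels = cn$regions$label)
  moran <- function(x) {
    wm <- exp(-d / 30); diag(wm) <- 0
    z <- (x - mean(x)) / sd(x)
    sum(wm * outer(z, z)) / sum(wm)
  }
  m0 <- moran(grad$synthesis)
  ms <- mean(sapply(1:8, function(s)
    moran(surrogate_expression(grad, d, "synthesis", seed = s)$synthesis)))
  mp <- mean(sapply(1:8, function(s)
    moran(shuffle_expression(grad, "synthesis", seed = s)$synthesis)))
  expect_gt(m0, 0.2)
  expect_gt(ms, 0.6 * m0)
  expect_lt(abs(mp), 0.25 * m0)
  expect_error(variogram(rnorm(4), matrix(1, 4, 4)), "degenerate")
})

test_that("white-noise surrogates stay flat like the original", {
  cn <- make_connectome(study_spec(), seed = 1)
  d <- cn$centroid_distances
  set.seed(21)
  wn <- expression_profile(rnorm(42), rnorm(42))
  errs <- sapply(1:10, function(s) {
    sx <- surrogate_expression(wn, d, "synthesis", seed = s)
    sirspread:::variogram_mismatch(variogram(wn$synthesis, d, 25),
                                   variogram(sx$synthesis, d, 25))
  })
  # spatially unstructured maps come back as (near-)permutations whose
  # variograms are flat like the original's, up to per-bin sampling noise
  expect_lt(median(errs), 0.25)
  expect_lt(max(errs), 0.35)
  # flatness itself: no distance trend in the surrogate variogram
  sx <- surrogate_expression(wn, d, "synthesis", seed = 1)
  vg <- variogram(sx$synthesis, d, 25)
  ok <- vg$n_pairs >= 5
  expect_lt(abs(cor(vg$distance[ok], vg$gamma[ok])), 0.6)
})

test_that("null significance combines the t test with the empirical rank", {
  # all nulls equal to the true peak: t = 0, p = 1
  ns <- null_significance(0.5, rep(0.5, 20))
  expect_equal(ns$t_statistic, 0)
  expect_equal(ns$p_value, 1)

  # tight null far below the true peak: closed-form t, astronomical p
  set.seed(9)
  peaks <- rnorm(500, 0, 0.01)
  ns2 <- null_significance(0.34, peaks)
  t_expected <- (mean(peaks) - 0.34) / (sd(peaks) / sqrt(500))
  expect_equal(ns2$t_statistic, t_expected, tolerance = 1e-12)
  expect_lt(ns2$p_value, 1e-10)
  expect_equal(ns2$rank, 1L)
  expect_equal(ns2$exceedance, 0)

  # works from a sir_fit and a null_peaks tibble, and tidies
  fake_fit <- structure(list(peak_r = 0.4), class = "sir_fit")
  tbl <- tibble::tibble(kind = "rewired", rep = 1:10, peak_r = seq(0.1, 0.28, 0.02))
  ns3 <- null_significance(fake_fit, tbl)
  expect_identical(ns3$kind, "rewired")
  expect_equal(glance(ns3)$true_peak, 0.4)
  expect_equal(nrow(tidy(ns3)), 10)
  expect_s3_class(autoplot(ns3), "ggplot")
  expect_error(null_significance(0.4, 0.3), "at least 2")
})

test_that("the null pipeline is seed-reproducible and randomises one ingredient", {
  spec <- tiny_spec()
  cn <- make_connectome(spec, seed = 61)
  expr <- make_expression(spec, cn, seed = 62)
  rates <- expression_to_rates(expr)
  cfg <- sir_config(n_steps = 200, seed_region = "roi_01")
  traj <- sir_simulate(cn, rates, cfg, record_populations = FALSE)
  obs <- traj$L[150, ]
  np1 <- null_peaks(cn, expr, obs, cfg, kind = "synthesis_shuffle", reps = 4, seed = 5)
  np2 <- null_peaks(cn, expr, obs, cfg, kind = "synthesis_shuffle", reps = 4, seed = 5)
  expect_equal(np1$peak_r, np2$peak_r)
  expect_true(all(np1$peak_r >= -1 & np1$peak_r <= 1))
  expect_identical(nrow(np1), 4L)
})
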