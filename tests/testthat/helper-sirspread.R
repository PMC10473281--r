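# Shared fixtures and independent oracles for the test suite.

# Midranks computed by counting, independently of base::rank.
midranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, numeric(1))
}

# Brute-force Spearman: midranks then the textbook Pearson sum formula.
spearman_oracle <- function(x, y) {
  rx <- midranks(x)
  ry <- midranks(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# A small connectome with hand-set geometry: n regions on a line, unit sizes
# unless given, consecutive regions connected with the supplied weights.
line_connectome <- function(n, weights = rep(1, n - 1), sizes = rep(100, n),
                            spacing = 10) {
  regions <- tibble::tibble(label = sprintf("r%02d", seq_len(n)), size = sizes,
                            x = spacing * (seq_len(n) - 1), y = 0, z = 0)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- weights[i]
  connectome(regions, w)
}

# One isolated region: the closed-form testbed.
single_region <- function(size = 100) {
  regions <- tibble::tibble(label = "r01", size = size, x = 0, y = 0, z = 0)
  connectome(regions, matrix(0, 1, 1))
}

# A modest synthetic study shared by several tests (cached per session).
study_spec <- function() synth_spec()

tiny_spec <- function(n_regions = 16) {
  synth_spec(n_regions = n_regions, n_controls = 40,
             n_patients = c(year1 = 30, year2 = 25, year4 = 20))
}
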