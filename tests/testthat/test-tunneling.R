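wt_series <- function(n = 1e5, seed = 11) {
  generate_distance_mixture(
    mixture_spec(data.frame(weight = 1, mean = 14.1, sd = 0.2),
                 n = n, seed = seed), "WT")
}

mut_series <- function(n = 1e5, seed = 12) {
  generate_distance_mixture(
    mixture_spec(data.frame(weight = c(0.6, 0.4), mean = c(13.5, 14.1),
                            sd = c(0.15, 0.15)), n = n, seed = seed),
    "A52T")
}

test_that("a unimodal series yields a single mode at its mean", {
  modes <- find_modes(wt_series())
  expect_identical(nrow(modes), 1L)
  expect_equal(modes$position[1L], 14.1, tolerance = 0.03 / 14.1)
})

test_that("the bimodal mutant series is prominence-ordered", {
  modes <- find_modes(mut_series())
  expect_gte(nrow(modes), 2L)
  expect_equal(modes$position[1L], 13.5, tolerance = 0.05 / 13.5)
  expect_equal(modes$position[2L], 14.1, tolerance = 0.05 / 14.1)
  expect_gt(modes$height[1L], modes$height[2L])
})

test_that("equal well-separated components give two equal-height modes", {
  ds <- generate_distance_mixture(
    mixture_spec(data.frame(weight = c(0.5, 0.5), mean = c(12, 16),
                            sd = c(0.2, 0.2)), n = 2e5, seed = 13), "sym")
  modes <- find_modes(ds)
  expect_identical(nrow(modes), 2L)
  expect_lt(abs(modes$height[1L] - modes$height[2L]) / modes$height[1L],
            0.05)
})

test_that("degenerate inputs to find_modes are rejected", {
  const <- distance_series(1:5, rep(14, 5))
  expect_error(find_modes(const), "constant")
  small <- distance_series(1:50, rnorm(50, 14, 0.1))
  expect_error(find_modes(small, "auto"), "100 samples")
  expect_silent(find_modes(small, 0.05))
})

test_that("mode recovery holds across randomized mixture specs", {
  set.seed(99)
  for (i in 1:5) {
    m1 <- runif(1, 12, 13)
    sep <- runif(1, 1.5, 2.5)       # >> 3 bandwidths at n = 4e4
    w1 <- runif(1, 0.35, 0.65)
    ds <- generate_distance_mixture(
      mixture_spec(data.frame(weight = c(w1, 1 - w1), mean = c(m1, m1 + sep),
                              sd = c(0.15, 0.15)), n = 4e4,
                   seed = 300 + i), "prop")
    modes <- find_modes(ds)
    pos <- sort(modes$position[1:2])
    expect_lt(abs(pos[1L] - m1), 0.05)
    expect_lt(abs(pos[2L] - (m1 + sep)), 0.05)
  }
})

test_that("peak rate ratios follow the exponential decay model", {
  expect_equal(rate_ratio_peaks(14.1, 14.1, 1.8), 1)
  expect_equal(rate_ratio_peaks(14.1, 13.5, 1.8), exp(1.08))
  expect_equal(signif(rate_ratio_peaks(14.1, 13.5, 1.8), 1), 3)
  # antisymmetry and composition
  expect_equal(rate_ratio_peaks(13.5, 14.1, 1.8),
               1 / rate_ratio_peaks(14.1, 13.5, 1.8), tolerance = 1e-12)
  expect_equal(rate_ratio_peaks(12, 13, 1.8) * rate_ratio_peaks(13, 15, 1.8),
               rate_ratio_peaks(12, 15, 1.8), tolerance = 1e-12)
  expect_error(rate_ratio_peaks(14.1, 13.5, -1), "positive")
  expect_error(rate_ratio_peaks(-14.1, 13.5, 1.8), "positive")
})

test_that("ensemble rate ratios bound and degenerate to the peak ratio", {
  wt <- wt_series(2e4)
  mut <- mut_series(2e4)
  r_ens <- rate_ratio_ensemble(wt, mut, 1.8)
  expect_identical(rate_ratio_ensemble(wt, wt, 1.8), 1)
  # delta-like series reproduce the two-point formula
  d_ref <- distance_series(1:3, rep(14.1, 3))
  d_alt <- distance_series(1:3, rep(13.5, 3))
  expect_equal(rate_ratio_ensemble(d_ref, d_alt, 1.8),
               rate_ratio_peaks(14.1, 13.5, 1.8), tolerance = 1e-6)
  # the mutant ensemble gains rate, but less than its shortest mode alone
  expect_gt(r_ens, 1)
  expect_lte(r_ens, rate_ratio_peaks(14.1, 13.5, 1.8))
})

test_that("ensemble ratios ignore sample order and duplication", {
  wt <- wt_series(5000)
  mut <- mut_series(5000)
  r <- rate_ratio_ensemble(wt, mut, 1.8)
  shuffle <- function(ds) distance_series(ds$time, sample(ds$distance),
                                          attr(ds, "label"))
  dup <- function(ds) distance_series(c(ds$time, ds$time + max(ds$time)),
                                      rep(ds$distance, 2),
                                      attr(ds, "label"))
  set.seed(4)
  expect_equal(rate_ratio_ensemble(shuffle(wt), shuffle(mut), 1.8), r,
               tolerance = 1e-12)
  expect_equal(rate_ratio_ensemble(dup(wt), dup(mut), 1.8), r,
               tolerance = 1e-12)
})

test_that("the Marcus rate has its textbook structure", {
  base <- et_params(beta_decay = 1.8, coupling_h0 = 0.01,
                    reorganization_lambda = 20, driving_dg0 = -20)
  # activationless point maximizes the rate over the driving force
  k_act <- marcus_rate(base, 14.1)
  for (dg0 in c(-30, -10, 0)) {
    p <- et_params(1.8, 0.01, 20, dg0)
    expect_lte(marcus_rate(p, 14.1), k_act)
  }
  # |H|^2 dependence: doubling the coupling quadruples the rate
  p2 <- et_params(1.8, 0.02, 20, -20)
  expect_equal(marcus_rate(p2, 14.1) / k_act, 4, tolerance = 1e-12)
  # distance dependence factors out exactly as the peak ratio
  expect_equal(marcus_rate(base, 13.5) / marcus_rate(base, 14.1),
               rate_ratio_peaks(14.1, 13.5, 1.8), tolerance = 1e-12)
  expect_error(marcus_rate(et_params(1.8), 14.1), "needs")
  expect_error(et_params(reorganization_lambda = -1), "positive")
})
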