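test_that("Zwanzig estimator handles degenerate and Gaussian inputs", {
  expect_equal(zwanzig_dg(rep(2.5, 10)), 2.5, tolerance = 1e-12)
  expect_equal(zwanzig_dg(0.8), 0.8, tolerance = 1e-12)
  expect_error(zwanzig_dg(numeric()), "no samples")
  # Gaussian closed form: dG = mu - sigma^2 / (2 kT)
  kT <- kT_kcal(310)
  set.seed(21)
  mu <- 2; sigma <- 0.5; n <- 2e5
  x <- rnorm(n, mu, sigma)
  est <- zwanzig_dg(x)
  # delta-method stderr of -kT log mean(exp(-x/kT))
  ex <- exp(-x / kT)
  se <- kT * sd(ex) / (mean(ex) * sqrt(n))
  expect_lt(abs(est - (mu - sigma^2 / (2 * kT))), 3 * se)
  # log-sum-exp guard: huge energy gaps must not overflow
  expect_true(is.finite(zwanzig_dg(c(5000, 5001))))
})

test_that("BAR is unbiased on Crooks-consistent Gaussian windows", {
  win <- make_gaussian_window(1.0, 1.0, 4000, seed = 7)
  est <- bar_dg(win)
  expect_true(est$converged)
  expect_lt(abs(est$delta_g - 1.0), 0.05)
  expect_lt(est$stderr, 0.05)
})

test_that("BAR lands at zero when both directions share a distribution", {
  set.seed(2)
  win <- fep_window(0, 1, rnorm(4000, 0, 1), rnorm(4000, 0, 1))
  est <- bar_dg(win)
  expect_lt(abs(est$delta_g), 3 * est$stderr)
})

test_that("BAR matches the independent fixed-point oracle", {
  set.seed(33)
  for (i in 1:5) {
    dg <- runif(1, -3, 3)
    sigma <- runif(1, 0.3, 2)
    win <- make_gaussian_window(dg, sigma, 800, seed = 100 + i)
    mine <- bar_dg(win)$delta_g
    oracle <- bar_fixed_point_oracle(win$forward_du, win$reverse_du)
    expect_lt(abs(mine - oracle), 1e-6)
  }
})

test_that("BAR is antisymmetric under direction reversal", {
  win <- make_gaussian_window(1.3, 0.8, 500, seed = 9)
  swapped <- fep_window(win$lambda_from, win$lambda_to,
                        forward_du = -win$reverse_du,
                        reverse_du = -win$forward_du)
  expect_equal(bar_dg(swapped)$delta_g, -bar_dg(win)$delta_g,
               tolerance = 1e-7)
})

test_that("one-sided windows are routed to Zwanzig explicitly", {
  win <- fep_window(0, 1, forward_du = rnorm(10))
  expect_error(bar_dg(win), "zwanzig_dg")
})

test_that("BAR beats Zwanzig in RMSE on the synthetic suite", {
  n_rep <- 50L
  err_bar <- err_zw <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    win <- make_gaussian_window(1.0, 1.5, 300, seed = 500 + i)
    err_bar[i] <- bar_dg(win)$delta_g - 1.0
    err_zw[i] <- zwanzig_dg(win$forward_du) - 1.0
  }
  expect_lt(sqrt(mean(err_bar^2)), sqrt(mean(err_zw^2)))
})

test_that("BAR stderr scales as 1/sqrt(n)", {
  se_at <- function(n) {
    mean(vapply(1:4, function(r)
      bar_dg(make_gaussian_window(0.5, 1, n, seed = 40 + r))$stderr,
      numeric(1)))
  }
  se <- vapply(c(500L, 2000L, 8000L), se_at, numeric(1))
  expect_equal(se[1L] / se[2L], 2, tolerance = 0.2)
  expect_equal(se[2L] / se[3L], 2, tolerance = 0.2)
})

test_that("window composition tiles the lambda schedule", {
  wins <- generate_fep_samples(rep(0.4, 10), sigma = 0, n = 1, seed = 1)
  ests <- lapply(wins, function(w) bar_dg(w))
  tot <- compose_windows(ests, wins)
  expect_equal(tot$delta_g, 4, tolerance = 1e-6)
  expect_identical(tot$n_windows, 10L)
  # the endpoint-concentrated 11-value schedule is accepted as-is
  expect_equal(tot$per_window$lambda_from, default_lambda_schedule()[-11L])
  # gaps are named
  expect_error(compose_windows(ests[-5L], wins[-5L]), "0.25")
  # overlaps are caught too
  bad <- wins
  bad[[2L]] <- fep_window(0.02, bad[[2L]]$lambda_to, bad[[2L]]$forward_du,
                          bad[[2L]]$reverse_du)
  expect_error(compose_windows(ests, bad), "overlap")
})

test_that("the thermodynamic cycle subtracts its two legs", {
  expect_equal(ddg_cycle(10, 6)$ddg_bind, 4)
  expect_equal(ddg_cycle(3.3, 3.3)$ddg_bind, 0)
  res <- ddg_cycle(10, 6)
  expect_equal(res$ddg_bind, res$dg_mut_unbound - res$dg_mut_bound)
  expect_output(print(res), "less strongly")
})

test_that("the full pipeline recovers a 4 kcal/mol cycle within 0.1", {
  cyc <- generate_cycle_dataset(10, 6, sigma = 1, n = 4000, seed = 1)
  tot <- function(wins) compose_windows(lapply(wins, bar_dg), wins)
  res <- ddg_cycle(tot(cyc$unbound), tot(cyc$bound))
  expect_lt(abs(res$ddg_bind - cyc$true_ddg), 0.1)
  expect_true(is.finite(res$stderr) && res$stderr < 0.1)
})

test_that("a consistent 4-state cycle closes to zero", {
  # legs A->B->C->D->A with true dGs summing to zero
  dgs <- c(1.2, -0.7, 0.9, -1.4)
  legs <- lapply(seq_along(dgs), function(i)
    make_gaussian_window(dgs[i], 1, 2000, seed = 200 + i))
  ests <- lapply(legs, bar_dg)
  total <- sum(vapply(ests, `[[`, numeric(1), "delta_g"))
  se <- sqrt(sum(vapply(ests, `[[`, numeric(1), "stderr")^2))
  expect_lt(abs(total), 3 * se)
})

test_that("kNN density corrections recover a known Gaussian density", {
  set.seed(5)
  pts <- matrix(rnorm(15000), ncol = 3)
  r <- sqrt(rowSums(pts^2))
  kc <- knn_correction(r, r, dimension = 3)
  expect_identical(kc$k, 4L)                  # fourth neighbor by default
  expect_equal(kc$correction, 0)              # identical ensembles
  expect_equal(kc$density_a, (2 * pi)^(-3 / 2), tolerance = 0.15)
  # a twice-as-dense ensemble gives a finite, sign-correct correction
  kc2 <- knn_correction(r, r * 2, dimension = 3)
  expect_true(is.finite(kc2$correction) && kc2$correction < 0)
  expect_error(knn_correction(r[1:4], r, dimension = 3), "more than k")
  expect_error(knn_correction(c(0, 0, 0, 0, 0), r, dimension = 3),
               "duplicate")
})
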