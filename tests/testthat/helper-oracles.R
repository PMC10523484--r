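# Independent reference implementations used only as test oracles.

# Bennett acceptance ratio by fixed-point iteration of the exact identity
#   beta dG = beta C + log<f(beta(C - dU))>_R - log<f(beta(dU - C))>_F
# evaluated at C = dG + kT log(nF/nR).  A different numerical route than
# the package's bracketed bisection on the self-consistent residual.
bar_fixed_point_oracle <- function(fwd, rev, temperature = 310,
                                   tol = 1e-12, max_iter = 10000L) {
  kT <- qtrap::kT_kcal(temperature)
  lmexp <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
  lnr <- log(length(fwd) / length(rev))
  dg <- 0
  for (i in seq_len(max_iter)) {
    C <- dg + kT * lnr
    new <- C + kT * (lmexp(-log1p(exp((C - rev) / kT))) -
                     lmexp(-log1p(exp((fwd - C) / kT)))) + kT * lnr
    if (abs(new - dg) < tol) return(new)
    dg <- new
  }
  dg
}

# Crooks-consistent Gaussian window with known true dG (independent of
# the package's generator so the two can cross-check each other).
make_gaussian_window <- function(dg, sigma, n, temperature = 310, seed = 1,
                                 lambda_from = 0, lambda_to = 1) {
  set.seed(seed)
  shift <- sigma^2 / (2 * qtrap::kT_kcal(temperature))
  qtrap::fep_window(lambda_from, lambda_to,
                    forward_du = rnorm(n, dg + shift, sigma),
                    reverse_du = rnorm(n, dg - shift, sigma))
}

# Shared small double-well pulling setup for work-profile tests.
dw_potential <- function(temperature = 310) {
  qtrap::model_potential("double_well", center = 12, half_separation = 1.5,
                         barrier_height = 3 * qtrap::kT_kcal(temperature))
}

dw_spec <- function(duration, n_traj = 200, seed = 42) {
  qtrap::langevin_spec(friction = 0.05, timestep = 1e-4, spring_k = 2,
                       center_start = 10, center_end = 14,
                       duration = duration, n_traj = n_traj, seed = seed)
}
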