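#' Model potentials for synthetic pulling experiments
#'
#' One-dimensional stand-ins for the free-energy profile along a pulling
#' coordinate, used by [simulate_pulling()] so that every work-based
#' estimator can be tested against a known ground truth.
#'
#' Kinds and their parameters (all energies kcal/mol, lengths Angstrom):
#' * `flat`: U(x) = 0.
#' * `harmonic`: `x0`, `stiffness` (kcal/mol/A^2); U = stiffness/2 (x-x0)^2.
#' * `double_well`: `center`, `half_separation`, `barrier_height`; a
#'   symmetric quartic with minima at `center +/- half_separation` (U = 0)
#'   and a barrier of `barrier_height` at `center`.
#' * `tabulated`: `x`, `u` vectors, interpolated by a natural cubic spline.
#'
#' @param kind One of `"flat"`, `"harmonic"`, `"double_well"`, `"tabulated"`.
#' @param ... Kind-specific parameters, see above.
#' @return An object of class `model_potential` with elements `u` and
#'   `grad` (vectorised functions of position).
#' @export
model_potential <- function(kind = c("flat", "harmonic", "double_well",
                                     "tabulated"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  pot <- switch(kind,
    flat = list(u = function(x) rep(0, length(x)),
                grad = function(x) rep(0, length(x))),
    harmonic = {
      stopifnot(is.numeric(p$x0), is.numeric(p$stiffness), p$stiffness > 0)
      list(u = function(x) 0.5 * p$stiffness * (x - p$x0)^2,
           grad = function(x) p$stiffness * (x - p$x0))
    },
    double_well = {
      stopifnot(is.numeric(p$center), is.numeric(p$half_separation),
                p$half_separation > 0, is.numeric(p$barrier_height),
                p$barrier_height > 0)
      a <- p$half_separation; h <- p$barrier_height; c0 <- p$center
      list(u = function(x) h * ((x - c0)^2 - a^2)^2 / a^4,
           grad = function(x) h * 4 * (x - c0) * ((x - c0)^2 - a^2) / a^4)
    },
    tabulated = {
      stopifnot(is.numeric(p$x), is.numeric(p$u),
                length(p$x) == length(p$u), length(p$x) >= 4L)
      sf <- stats::splinefun(p$x, p$u, method = "natural")
      list(u = function(x) sf(x), grad = function(x) sf(x, deriv = 1L))
    })
  structure(c(list(kind = kind, parameters = p), pot),
            class = "model_potential")
}

#' Free-energy difference of a bare model potential between two points
#'
#' For a 1-D potential the PMF is the potential itself, so the difference
#' is U(x2) - U(x1); analytic for the closed-form kinds, spline-based for
#' `tabulated`.
#'
#' @param potential A [model_potential].
#' @param x1,x2 Positions in Angstrom.
#' @return Free-energy difference in kcal/mol.
#' @export
delta_pmf <- function(potential, x1, x2) {
  stopifnot(inherits(potential, "model_potential"))
  potential$u(x2) - potential$u(x1)
}

#' Restrained free energy along a pulling schedule (ground truth)
#'
#' The equilibrium free energy F(c) of the combined system
#' U(x) + k/2 (x - c)^2 as a function of the restraint center c, computed
#' by numerical quadrature.  This is exactly the quantity that the
#' Jarzynski estimator of a center-binned work profile converges to, so it
#' serves as the analytic reference in recovery tests.
#'
#' @param potential A [model_potential].
#' @param centers Restraint centers (Angstrom) at which to evaluate F.
#' @param spring_k Restraint force constant in kcal/mol/A^2.
#' @param temperature Temperature in K.
#' @param anchor If `TRUE` (default) subtract F at the first center.
#' @return Numeric vector of free energies (kcal/mol).
#' @export
restrained_free_energy <- function(potential, centers, spring_k = 2,
                                   temperature = 310, anchor = TRUE) {
  stopifnot(inherits(potential, "model_potential"), spring_k > 0)
  kT <- kT_kcal(temperature)
  width <- sqrt(kT / spring_k)
  f <- vapply(centers, function(cc) {
    lo <- cc - 12 * width - 2; hi <- cc + 12 * width + 2
    grid <- seq(lo, hi, length.out = 512L)
    e0 <- min(potential$u(grid) + 0.5 * spring_k * (grid - cc)^2)
    val <- stats::integrate(function(x) {
      exp(-(potential$u(x) + 0.5 * spring_k * (x - cc)^2 - e0) / kT)
    }, lo, hi, rel.tol = 1e-10)$value
    e0 - kT * log(val)
  }, numeric(1))
  if (anchor) f <- f - f[1L]
  f
}

#' Specification of an overdamped Langevin pulling protocol
#'
#' @param temperature Temperature in K (default 310).
#' @param friction Friction coefficient gamma in kcal ns / mol / A^2; the
#'   free diffusion constant is kT/gamma.
#' @param timestep Integration step in ns.  Must resolve the fastest
#'   relaxation: `timestep < 0.1 * friction / spring_k` is enforced here,
#'   and [simulate_pulling()] additionally checks the potential curvature.
#' @param spring_k Pulling restraint force constant, kcal/mol/A^2
#'   (default 2, the value used for the CoQ10 extraction pulls).
#' @param center_start,center_end Restraint-center schedule endpoints in
#'   Angstrom (defaults 10 and 58, the full 48 A extraction).
#' @param duration Pull duration in ns (default 3, the fast protocol; the
#'   accurate protocol is 10x slower).
#' @param n_traj Number of independent trajectories (default 10).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `langevin_spec`.
#' @export
langevin_spec <- function(temperature = 310, friction = 0.05,
                          timestep = 2e-4, spring_k = 2,
                          center_start = 10, center_end = 58,
                          duration = 3, n_traj = 10, seed = 1L) {
  stopifnot(temperature > 0, friction > 0, timestep > 0, spring_k > 0,
            duration > 0, n_traj >= 1)
  if (timestep >= 0.1 * friction / spring_k)
    stop(sprintf(
      "timestep %g ns does not resolve the restraint relaxation time %g ns",
      timestep, friction / spring_k), call. = FALSE)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, spring_k = spring_k,
                 center_start = center_start, center_end = center_end,
                 duration = duration, n_traj = as.integer(n_traj),
                 seed = as.integer(seed)),
            class = "langevin_spec")
}

#' Simulate steered pulling on a model potential
#'
#' Overdamped (Brownian) dynamics under a moving harmonic restraint:
#' x <- x - dt (U'(x) + k (x - c)) / gamma + sqrt(2 kT dt / gamma) xi,
#' with unit-normal xi.  External work is accumulated by the stiff-spring
#' bookkeeping W <- W + k (c - x) dc at every restraint-center increment,
#' the same convention MD engines use for their reported SMD work.
#'
#' The particle is first equilibrated at the fixed starting center (no work
#' accumulated), then pulled linearly from `center_start` to `center_end`
#' over `duration`.
#'
#' @param potential A [model_potential].
#' @param spec A [langevin_spec].
#' @param record_every Recording cadence in ns (default 5e-4 ns = 500 fs,
#'   the cadence of the engine logs this package analyses).  Use
#'   `record_every = spec$timestep` to record every step.
#' @return A list of `spec$n_traj` [work_trace] objects.
#' @export
simulate_pulling <- function(potential, spec, record_every = 5e-4) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(spec, "langevin_spec"))
  dt <- spec$timestep; gam <- spec$friction; k <- spec$spring_k
  kT <- kT_kcal(spec$temperature)
  # stability: probe the potential curvature over the region the particle
  # visits -- the schedule range padded by two thermal spring widths
  pad <- 2 * sqrt(kT / k)
  lo <- min(spec$center_start, spec$center_end) - pad
  hi <- max(spec$center_start, spec$center_end) + pad
  xs <- seq(lo, hi, length.out = 400L)
  d2u <- diff(potential$grad(xs)) / diff(xs)
  k_eff <- k + max(0, max(d2u))
  if (dt >= 0.1 * gam / k_eff)
    stop(sprintf(
      "unstable timestep: %g ns >= 0.1 * friction / stiffness = %g ns",
      dt, 0.1 * gam / k_eff), call. = FALSE)

  set.seed(spec$seed)
  n <- spec$n_traj
  nsteps <- max(1L, as.integer(round(spec$duration / dt)))
  centers <- seq(spec$center_start, spec$center_end, length.out = nsteps + 1L)
  stride <- max(1L, as.integer(round(record_every / dt)))
  rec_steps <- unique(c(seq(0L, nsteps, by = stride), nsteps))
  noise_amp <- sqrt(2 * kT * dt / gam)

  # equilibrate at the fixed starting center (~30 relaxation times)
  x <- rep(spec$center_start, n)
  n_equil <- as.integer(ceiling(30 * gam / (k_eff * dt)))
  for (i in seq_len(n_equil)) {
    force <- -potential$grad(x) - k * (x - spec$center_start)
    x <- x + dt * force / gam + noise_amp * stats::rnorm(n)
  }

  nrec <- length(rec_steps)
  X <- matrix(0, nrec, n); W <- matrix(0, nrec, n)
  W_cur <- numeric(n)
  ri <- 1L
  if (rec_steps[1L] == 0L) { X[1L, ] <- x; ri <- 2L }
  for (i in seq_len(nsteps)) {
    c_new <- centers[i + 1L]
    W_cur <- W_cur + k * (c_new - x) * (c_new - centers[i])
    force <- -potential$grad(x) - k * (x - c_new)
    x <- x + dt * force / gam + noise_amp * stats::rnorm(n)
    if (ri <= nrec && i == rec_steps[ri]) {
      X[ri, ] <- x; W[ri, ] <- W_cur; ri <- ri + 1L
    }
  }
  times <- rec_steps * dt
  cc <- centers[rec_steps + 1L]
  lapply(seq_len(n), function(j) {
    work_trace(sprintf("traj%d", j), times, cc, X[, j], W[, j])
  })
}

#' Specification of a Gaussian mixture of donor-acceptor distances
#'
#' @param components A data frame (or list coercible to one) with columns
#'   `weight`, `mean` (Angstrom) and `sd` (Angstrom).  Weights must be
#'   positive and sum to 1 (within 1e-12).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, n, seed = 1L) {
  cmp <- as.data.frame(components)
  stopifnot(all(c("weight", "mean", "sd") %in% names(cmp)), n >= 1)
  if (any(cmp$weight <= 0)) stop("weights must be positive", call. = FALSE)
  if (abs(sum(cmp$weight) - 1) > 1e-12)
    stop(sprintf("weights must sum to 1 (got %.15g)", sum(cmp$weight)),
         call. = FALSE)
  if (any(cmp$sd <= 0)) stop("sds must be positive", call. = FALSE)
  structure(list(components = cmp, n = as.integer(n),
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' Draw a synthetic donor-acceptor distance series from a Gaussian mixture
#'
#' Emulates the headgroup-to-N2 distance distributions seen in equilibrium
#' simulations: unimodal for the wild-type channel, bimodal (with the
#' shorter-distance component dominant) for the mutant.  The generating
#' component of every sample is retained in attribute `"component"` for
#' ground-truth tests.
#'
#' @param spec A [mixture_spec].
#' @param label System tag attached to the series.
#' @return A [distance_series] with attribute `component`.
#' @export
generate_distance_mixture <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "mixture_spec"))
  set.seed(spec$seed)
  cmp <- spec$components
  idx <- sample.int(nrow(cmp), spec$n, replace = TRUE, prob = cmp$weight)
  d <- stats::rnorm(spec$n, cmp$mean[idx], cmp$sd[idx])
  ds <- distance_series((seq_len(spec$n) - 1L) * 5e-4, d, label)
  attr(ds, "component") <- idx
  ds
}

#' Generate Crooks-consistent alchemical window samples
#'
#' For a window with true free-energy difference dG and Gaussian energy
#' differences of standard deviation sigma, the Crooks fluctuation relation
#' fixes the two means: forward samples (drawn in the lambda_from ensemble)
#' are N(dG + sigma^2 / (2 kT), sigma^2) and reverse samples (drawn in the
#' lambda_to ensemble, same sign convention) are
#' N(dG - sigma^2 / (2 kT), sigma^2).  Bennett's acceptance ratio is then
#' asymptotically unbiased for dG, which makes these samples a ground truth
#' for the whole estimation chain.
#'
#' @param true_dg_per_window Numeric vector of true per-window dG values
#'   (kcal/mol); its length sets the number of windows.
#' @param sigma Standard deviation of the energy differences (kcal/mol).
#' @param n Samples per direction per window.
#' @param temperature Temperature in K.
#' @param seed Integer seed.
#' @param lambda Optional vector of window boundaries (length one more than
#'   the number of windows, from 0 to 1, increasing).  Defaults to the
#'   11-value endpoint-concentrated schedule ([default_lambda_schedule()])
#'   for 10 windows and to a uniform partition otherwise.
#' @return A list of [fep_window] objects.
#' @export
generate_fep_samples <- function(true_dg_per_window, sigma, n,
                                 temperature = 310, seed = 1L,
                                 lambda = NULL) {
  stopifnot(sigma >= 0, n >= 1)
  k <- length(true_dg_per_window)
  if (is.null(lambda)) {
    lambda <- if (k == 10L) default_lambda_schedule()
              else seq(0, 1, length.out = k + 1L)
  }
  stopifnot(length(lambda) == k + 1L, all(diff(lambda) > 0),
            lambda[1L] == 0, lambda[k + 1L] == 1)
  set.seed(as.integer(seed))
  shift <- if (sigma > 0) sigma^2 / (2 * kT_kcal(temperature)) else 0
  lapply(seq_len(k), function(i) {
    dg <- true_dg_per_window[i]
    fep_window(lambda[i], lambda[i + 1L],
               forward_du = stats::rnorm(n, dg + shift, sigma),
               reverse_du = stats::rnorm(n, dg - shift, sigma))
  })
}

#' Generate a synthetic thermodynamic-cycle dataset
#'
#' Two alchemical legs (mutation with the substrate unbound, mutation with
#' it bound), each split evenly across `n_windows` windows, generated by
#' [generate_fep_samples()].  The recoverable relative binding free energy
#' is `dg_unbound - dg_bound`.
#'
#' @param dg_unbound,dg_bound True total dG of each leg (kcal/mol).
#' @param sigma,n,temperature,seed As in [generate_fep_samples()]; the
#'   bound leg uses `seed + 1`.
#' @param n_windows Number of windows per leg (default 10).
#' @return A list with elements `unbound`, `bound` (lists of [fep_window])
#'   and `true_ddg`.
#' @export
generate_cycle_dataset <- function(dg_unbound, dg_bound, sigma, n,
                                   temperature = 310, seed = 1L,
                                   n_windows = 10L) {
  list(unbound = generate_fep_samples(rep(dg_unbound / n_windows, n_windows),
                                      sigma, n, temperature, seed),
       bound = generate_fep_samples(rep(dg_bound / n_windows, n_windows),
                                    sigma, n, temperature,
                                    as.integer(seed) + 1L),
       true_ddg = dg_unbound - dg_bound)
}
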