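#' One-sided exponential-averaging (Zwanzig) free-energy estimate
#'
#' dG = -kT log < exp(-dU/kT) > over samples drawn in the starting
#' ensemble, computed with a log-sum-exp guard so large energy gaps do not
#' overflow.  This is the free-energy-perturbation baseline estimator and
#' the cross-check for [bar_dg()].
#'
#' @param samples Energy differences dU = U(to) - U(from) in kcal/mol,
#'   sampled in the `from` ensemble.
#' @param temperature Temperature in K.
#' @return Free-energy difference in kcal/mol.
#' @export
zwanzig_dg <- function(samples, temperature = 310) {
  if (length(samples) == 0L) stop("no samples", call. = FALSE)
  kT <- kT_kcal(temperature)
  -kT * logmeanexp(-samples / kT)
}

fermi <- function(x) 1 / (1 + exp(x))

#' Bennett acceptance ratio (BAR) free-energy estimate for one window
#'
#' Solves the self-consistent Bennett equation
#' sum_F f(beta (dU_i - C)) = sum_R f(beta (C - dU_j)),  with
#' C = dG + kT log(n_F / n_R) and f the Fermi function, where forward
#' samples dU_i were drawn in the lambda_from ensemble and reverse samples
#' dU_j in the lambda_to ensemble (both with the fixed sign convention
#' dU = U(to) - U(from)).  The root is found by bisection on a bracket
#' expanded geometrically from the two one-sided Zwanzig estimates, which
#' is derivative-free and guaranteed to converge because the residual is
#' monotone in dG.  The standard error is the usual asymptotic BAR
#' variance.
#'
#' @param window A [fep_window] with nonempty forward and reverse samples.
#' @param temperature Temperature in K.
#' @param tolerance Convergence tolerance on dG in kcal/mol.
#' @param max_iter Maximum bisection iterations.
#' @return An object of class `bar_estimate` with elements `delta_g`,
#'   `stderr` (both kcal/mol), `iterations`, `converged`, `lambda_from`,
#'   `lambda_to`.
#' @export
bar_dg <- function(window, temperature = 310, tolerance = 1e-8,
                   max_iter = 1000L) {
  stopifnot(inherits(window, "fep_window"))
  fwd <- window$forward_du; rev <- window$reverse_du
  if (length(rev) == 0L)
    stop("window has no reverse samples; use zwanzig_dg() for one-sided ",
         "estimation", call. = FALSE)
  kT <- kT_kcal(temperature)
  n_f <- length(fwd); n_r <- length(rev)
  lnr <- log(n_f / n_r)

  # residual of the self-consistent equation, in log form for stability;
  # strictly increasing in dg
  resid <- function(dg) {
    C <- dg + kT * lnr
    logsumexp(-log1p(exp((fwd - C) / kT))) -
      logsumexp(-log1p(exp((C - rev) / kT)))
  }

  g_f <- zwanzig_dg(fwd, temperature)               # forward Zwanzig
  g_r <- kT * logmeanexp(rev / kT)                  # reverse-direction Zwanzig
  lo <- min(g_f, g_r); hi <- max(g_f, g_r)
  span <- max(hi - lo, kT)
  it <- 0L
  while (resid(lo) > 0 && it < max_iter) { lo <- lo - span; span <- 2 * span; it <- it + 1L }
  while (resid(hi) < 0 && it < max_iter) { hi <- hi + span; span <- 2 * span; it <- it + 1L }
  bracket_ok <- resid(lo) <= 0 && resid(hi) >= 0
  if (bracket_ok && hi - lo > tolerance) {
    sol <- stats::uniroot(resid, c(lo, hi), tol = tolerance,
                          maxiter = max_iter)
    dg <- sol$root
    it <- it + sol$iter
  } else {
    # degenerate bracket (e.g. identical one-sided estimates) or failure
    dg <- (lo + hi) / 2
  }

  # asymptotic variance (Bennett 1976): relative fluctuations of the two
  # Fermi-weight sums at the solution
  C <- dg + kT * lnr
  f_f <- fermi((fwd - C) / kT)
  f_r <- fermi((C - rev) / kT)
  rel_var <- function(w, m) (mean(w^2) / mean(w)^2 - 1) / m
  v <- kT^2 * (rel_var(f_f, n_f) + rel_var(f_r, n_r))
  overlap_ok <- is.finite(v) && mean(f_f) > 0 && mean(f_r) > 0
  converged <- bracket_ok && overlap_ok && abs(resid(dg)) < 1e-6
  if (!converged)
    warning("BAR estimate did not converge (poor forward/reverse overlap?)",
            call. = FALSE)
  structure(list(delta_g = dg,
                 stderr = if (overlap_ok) sqrt(v) else Inf,
                 iterations = it, converged = converged,
                 lambda_from = window$lambda_from,
                 lambda_to = window$lambda_to),
            class = "bar_estimate")
}

#' Compose per-window estimates across the lambda schedule
#'
#' Checks that the windows tile `[0, 1]` without gaps or overlaps, sums the
#' per-window free energies, and propagates the standard errors in
#' quadrature.  When every window also carries reverse samples, the
#' hysteresis |forward-composed - reverse-composed| of the two one-sided
#' Zwanzig totals is reported as a sampling-quality diagnostic.
#'
#' @param estimates List of [bar_estimate] objects (one per window).
#' @param windows The matching list of [fep_window] objects.
#' @param temperature Temperature in K (for the hysteresis diagnostic).
#' @return An object of class `fep_total` with elements `delta_g`,
#'   `stderr`, `n_windows`, `hysteresis` and a `per_window` data frame.
#' @export
compose_windows <- function(estimates, windows, temperature = 310) {
  stopifnot(length(estimates) == length(windows), length(windows) >= 1L)
  lf <- vapply(windows, `[[`, numeric(1), "lambda_from")
  lt <- vapply(windows, `[[`, numeric(1), "lambda_to")
  o <- order(lf)
  lf <- lf[o]; lt <- lt[o]; windows <- windows[o]; estimates <- estimates[o]
  bounds <- c(lf, utils::tail(lt, 1L))
  if (abs(lf[1L]) > 1e-9)
    stop(sprintf("lambda coverage gap in [0, %g]", lf[1L]), call. = FALSE)
  if (abs(utils::tail(lt, 1L) - 1) > 1e-9)
    stop(sprintf("lambda coverage gap in [%g, 1]", utils::tail(lt, 1L)),
         call. = FALSE)
  k <- length(windows)
  if (k > 1L) {
    mism <- which(abs(lt[-k] - lf[-1L]) > 1e-9)
    if (length(mism)) {
      i <- mism[1L]
      stop(sprintf("lambda coverage %s in (%g, %g)",
                   if (lt[i] < lf[i + 1L]) "gap" else "overlap",
                   min(lt[i], lf[i + 1L]), max(lt[i], lf[i + 1L])),
           call. = FALSE)
    }
  }
  dgs <- vapply(estimates, `[[`, numeric(1), "delta_g")
  ses <- vapply(estimates, `[[`, numeric(1), "stderr")
  kT <- kT_kcal(temperature)
  have_rev <- all(vapply(windows, function(w) length(w$reverse_du) > 0,
                         logical(1)))
  hyst <- if (have_rev) {
    fwd_tot <- sum(vapply(windows, function(w)
      zwanzig_dg(w$forward_du, temperature), numeric(1)))
    rev_tot <- sum(vapply(windows, function(w)
      kT * logmeanexp(w$reverse_du / kT), numeric(1)))
    abs(fwd_tot - rev_tot)
  } else NA_real_
  structure(list(delta_g = sum(dgs), stderr = sqrt(sum(ses^2)),
                 n_windows = k, hysteresis = hyst,
                 per_window = data.frame(lambda_from = lf, lambda_to = lt,
                                         delta_g = dgs, stderr = ses)),
            class = "fep_total")
}

#' Relative binding free energy from the thermodynamic cycle
#'
#' Closes the mutation/binding cycle: the (intractable) difference in
#' binding free energy between the wild-type and mutant protein equals the
#' difference between the two (tractable) alchemical mutation legs,
#' ddG_bind = dG_mut(unbound) - dG_mut(bound).  A positive value means the
#' mutant binds the substrate less strongly.
#'
#' @param dg_mut_unbound,dg_mut_bound Either plain numbers (kcal/mol) or
#'   [compose_windows()] results for the two legs.
#' @return An object of class `cycle_result` with elements
#'   `dg_mut_unbound`, `dg_mut_bound`, `ddg_bind`, `stderr` (NA when the
#'   legs are plain numbers), `hysteresis` and `per_window` breakdowns
#'   when available.
#' @export
ddg_cycle <- function(dg_mut_unbound, dg_mut_bound) {
  leg <- function(x) {
    if (inherits(x, "fep_total"))
      list(dg = x$delta_g, se = x$stderr, hyst = x$hysteresis,
           per_window = x$per_window)
    else {
      stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
      list(dg = as.numeric(x), se = NA_real_, hyst = NA_real_,
           per_window = NULL)
    }
  }
  u <- leg(dg_mut_unbound); b <- leg(dg_mut_bound)
  se <- if (is.na(u$se) && is.na(b$se)) NA_real_
        else sqrt(sum(c(u$se, b$se)^2, na.rm = TRUE))
  structure(list(dg_mut_unbound = u$dg, dg_mut_bound = b$dg,
                 ddg_bind = u$dg - b$dg, stderr = se,
                 hysteresis = c(unbound = u$hyst, bound = b$hyst),
                 per_window = list(unbound = u$per_window,
                                   bound = b$per_window)),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("Thermodynamic-cycle relative binding free energy\n")
  cat(sprintf("  dG_mut (unbound): %8.3f kcal/mol\n", x$dg_mut_unbound))
  cat(sprintf("  dG_mut (bound):   %8.3f kcal/mol\n", x$dg_mut_bound))
  cat(sprintf("  ddG_bind:         %8.3f kcal/mol%s\n", x$ddg_bind,
              if (is.finite(x$stderr) && !is.na(x$stderr))
                sprintf(" +/- %.3f", x$stderr) else ""))
  if (x$ddg_bind > 0)
    cat("  (positive: the mutant binds the substrate less strongly)\n")
  invisible(x)
}

# volume of the unit d-ball times r^d
ball_volume <- function(r, d) pi^(d / 2) / gamma(d / 2 + 1) * r^d

#' k-nearest-neighbor endpoint density correction
#'
#' When a set of degrees of freedom is frozen during an alchemical
#' transformation, each endpoint's free energy must be corrected by the
#' configurational probability density of the unfrozen ensemble at the
#' frozen reference structure.  Given scalar distances of sampled
#' configurations from the reference (an RMSD-like metric computed
#' upstream), the density is estimated as rho = k / (n V_d(r_k)), with
#' r_k the k-th smallest distance and V_d the volume of the d-ball of
#' radius r_k in the effective configurational dimension d.  The pairwise
#' correction applied to a leg is -kT log(rho_a / rho_b).
#'
#' @param endpoint_a_distances,endpoint_b_distances Nonnegative distances
#'   of samples from each endpoint's frozen reference; each must contain
#'   more than `k` samples.
#' @param k Neighbor rank (default 4, the rank used for the final
#'   corrections).
#' @param dimension Effective dimension d of the frozen configurational
#'   space (required; it is a modelling input, not a guessable constant).
#' @param temperature Temperature in K.
#' @return An object of class `knn_correction` with elements `k`,
#'   `dimension`, `density_a`, `density_b`, `correction` (kcal/mol).
#' @export
knn_correction <- function(endpoint_a_distances, endpoint_b_distances,
                           k = 4L, dimension, temperature = 310) {
  stopifnot(k >= 1L, is.numeric(dimension), dimension >= 1)
  dens <- function(d) {
    n <- length(d)
    if (n <= k)
      stop(sprintf("need more than k = %d samples (got %d)", k, n),
           call. = FALSE)
    if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
    r_k <- sort(d, partial = k)[k]
    if (r_k == 0)
      stop("k-th neighbor distance is 0 (duplicate reference samples)",
           call. = FALSE)
    k / (n * ball_volume(r_k, dimension))
  }
  rho_a <- dens(endpoint_a_distances)
  rho_b <- dens(endpoint_b_distances)
  structure(list(k = as.integer(k), dimension = dimension,
                 density_a = rho_a, density_b = rho_b,
                 correction = -kT_kcal(temperature) * log(rho_a / rho_b)),
            class = "knn_correction")
}
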