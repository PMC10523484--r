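#' Recompute accumulated pulling work from the stiff-spring rule
#'
#' Validates an engine-reported work column by re-accumulating
#' W_i = W_(i-1) + k (c_i - x_(i-1)) (c_i - c_(i-1)) from the recorded
#' restraint centers and coordinates.  At full recording cadence this is
#' exactly the engine bookkeeping; at a coarser cadence it is a quadrature
#' approximation.  If the recomputed endpoint deviates from the stored one
#' by more than 2% (relative to the larger magnitude), the returned trace
#' carries attribute `work_deviation = TRUE`.
#'
#' @param trace A [work_trace].
#' @param spring_k Restraint force constant in kcal/mol/A^2.
#' @return A [work_trace] with the recomputed `accumulated_work`, plus
#'   attributes `work_deviation` (logical) and `endpoint_rel_dev`.
#' @export
recompute_work <- function(trace, spring_k) {
  stopifnot(inherits(trace, "work_trace"), spring_k >= 0)
  if (any(diff(trace$restraint_center) < 0))
    stop("restraint-center schedule is not monotone", call. = FALSE)
  n <- nrow(trace)
  dc <- diff(trace$restraint_center)
  inc <- spring_k * (trace$restraint_center[-1L] - trace$coordinate[-n]) * dc
  w <- c(0, cumsum(inc))
  stored_end <- trace$accumulated_work[n]
  scale <- max(abs(stored_end), abs(w[n]), .Machine$double.eps)
  rel <- abs(w[n] - stored_end) / scale
  out <- work_trace(attr(trace, "traj_id"), trace$time,
                    trace$restraint_center, trace$coordinate, w)
  attr(out, "work_deviation") <- rel > 0.02
  attr(out, "endpoint_rel_dev") <- rel
  out
}

#' Binned work / free-energy profile from an ensemble of pulls
#'
#' Bins each trajectory's accumulated work by the restraint center (the
#' protocol coordinate, so every trajectory contributes to every bin) and
#' reports three estimators per bin, each anchored to 0 at the first bin:
#'
#' * `mean_work`: the ensemble mean work, with its standard error;
#' * `jarzynski`: -kT log < exp(-W/kT) >, the nonequilibrium free-energy
#'   estimate (computed with a log-sum-exp guard);
#' * `cumulant2`: < W > - Var(W) / (2 kT), the second-order cumulant
#'   expansion, exact for Gaussian work distributions.
#'
#' Jensen's inequality guarantees `jarzynski <= mean_work` at every bin.
#'
#' @param traces List of [work_trace] objects sharing a pulling direction.
#' @param bin_width Bin width in Angstrom (default 0.1).
#' @param temperature Temperature in K for the kT columns and the
#'   Jarzynski average.
#' @return A data frame of class `pmf_profile` with columns `bin_center`,
#'   `n_contributing`, `mean_work`, `se_mean`, `jarzynski`, `cumulant2`
#'   (kcal/mol) and `mean_work_kt`, `jarzynski_kt`, `cumulant2_kt`;
#'   attributes `temperature` and `bin_width`.
#' @export
work_profile <- function(traces, bin_width = 0.1, temperature = 310) {
  stopifnot(length(traces) >= 1L, bin_width > 0)
  lapply(traces, function(tr) stopifnot(inherits(tr, "work_trace")))
  kT <- kT_kcal(temperature)
  lo <- max(vapply(traces, function(tr) min(tr$restraint_center), numeric(1)))
  hi <- min(vapply(traces, function(tr) max(tr$restraint_center), numeric(1)))
  if (hi - lo < bin_width)
    stop("traces share too little restraint-center range to bin",
         call. = FALSE)
  # recording gaps wider than two bins would silently interpolate a hole
  for (tr in traces) {
    jump <- diff(tr$restraint_center)
    if (any(jump > 2 * bin_width)) {
      g <- which(jump > 2 * bin_width)[1L]
      stop(sprintf(
        "trace '%s' leaves empty bins between %.3f and %.3f A",
        attr(tr, "traj_id"), tr$restraint_center[g],
        tr$restraint_center[g + 1L]), call. = FALSE)
    }
  }
  centers <- seq(lo, hi, by = bin_width)
  Wmat <- vapply(traces, function(tr) {
    stats::approx(tr$restraint_center, tr$accumulated_work, xout = centers,
                  ties = mean, rule = 2)$y
  }, numeric(length(centers)))
  Wmat <- matrix(Wmat, nrow = length(centers))
  n <- ncol(Wmat)
  mean_w <- rowMeans(Wmat)
  var_w <- if (n > 1L) apply(Wmat, 1L, stats::var) else rep(0, length(centers))
  se <- sqrt(var_w / n)
  jar <- -kT * apply(-Wmat / kT, 1L, logmeanexp)
  cum2 <- mean_w - var_w / (2 * kT)
  # anchor every estimator at the first bin: only differences are physical
  prof <- data.frame(bin_center = centers, n_contributing = n,
                     mean_work = mean_w - mean_w[1L], se_mean = se,
                     jarzynski = jar - jar[1L],
                     cumulant2 = cum2 - cum2[1L])
  prof$mean_work_kt <- prof$mean_work / kT
  prof$jarzynski_kt <- prof$jarzynski / kT
  prof$cumulant2_kt <- prof$cumulant2 / kT
  attr(prof, "temperature") <- temperature
  attr(prof, "bin_width") <- bin_width
  class(prof) <- c("pmf_profile", "data.frame")
  prof
}

#' Barrier-height difference between two work profiles
#'
#' Computes the work span (max - min of the chosen estimator) of each
#' profile over a common interval of the pulling coordinate and returns
#' the difference span(b) - span(a), in kcal/mol and in kT.  A positive
#' value means system b opposes the pull more than system a over that
#' stretch (e.g. the mutant channel versus wild type).
#'
#' @param profile_a,profile_b [work_profile()] outputs (a = reference).
#' @param interval Numeric `c(z_lo, z_hi)` in Angstrom, inside both
#'   profiles.
#' @param estimator `"mean_work"` (default), `"jarzynski"` or
#'   `"cumulant2"`.
#' @param kt_temperature Temperature used only for the kT report; defaults
#'   to the profiles' simulation temperature.  Set 298 to quote barriers
#'   in room-temperature kT.
#' @return An object of class `barrier_estimate` with elements `interval`,
#'   `delta_w` (kcal/mol), `delta_w_kt`, `estimator`, `kt_temperature`.
#' @export
barrier_delta <- function(profile_a, profile_b, interval,
                          estimator = c("mean_work", "jarzynski",
                                        "cumulant2"),
                          kt_temperature = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(profile_a, "pmf_profile"),
            inherits(profile_b, "pmf_profile"),
            length(interval) == 2L, interval[1L] < interval[2L])
  if (is.null(kt_temperature))
    kt_temperature <- attr(profile_a, "temperature")
  span <- function(prof) {
    i <- prof$bin_center >= interval[1L] & prof$bin_center <= interval[2L]
    if (!any(i))
      stop(sprintf("interval [%g, %g] lies outside the profile range",
                   interval[1L], interval[2L]), call. = FALSE)
    v <- prof[[estimator]][i]
    max(v) - min(v)
  }
  dw <- span(profile_b) - span(profile_a)
  structure(list(interval = interval, delta_w = dw,
                 delta_w_kt = dw / kT_kcal(kt_temperature),
                 estimator = estimator, kt_temperature = kt_temperature),
            class = "barrier_estimate")
}

#' Boltzmann rate-slowdown factor for a barrier-height difference
#'
#' An extra barrier of height dW (in units of kT) multiplies a thermally
#' activated escape rate by exp(-dW).  A 20 kT extra barrier gives
#' 2.06e-9, i.e. diffusion out of the channel about 2e-9 times the
#' reference rate; 50 kT gives 1.9e-22.
#'
#' @param delta_barrier_kt Barrier-height difference in kT (dimensionless).
#' @return The multiplicative rate factor exp(-delta_barrier_kt).
#' @export
rate_slowdown <- function(delta_barrier_kt) {
  stopifnot(is.numeric(delta_barrier_kt), all(is.finite(delta_barrier_kt)))
  exp(-delta_barrier_kt)
}
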