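---
title: "Methods: work, free-energy and tunneling analysis for quinone channel trapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: work, free-energy and tunneling analysis for quinone channel trapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtrap)
```

# Scope

`qtrap` implements the inference chain that sits *downstream* of
all-atom molecular dynamics in studies of substrate trapping in the
ubiquinone (CoQ10) binding channel of respiratory complex I — the kind
of study that asks how a single channel-lining point mutation (such as
the A52T substitution in the ND1 subunit associated with Leber's
hereditary optic neuropathy) changes substrate binding, egress kinetics
and electron-transfer rates.  The package does not run molecular
dynamics.  Its inputs are the tables an MD engine leaves behind —
steered-MD (SMD) work traces, per-window alchemical energy differences,
and donor–acceptor distance time series — and its outputs are free-energy
profiles, relative binding free energies, barrier-derived rate factors
and tunneling-rate ratios.

Because the engine-scale data sets for such systems require
cluster-scale simulation, every estimator here is paired with a
synthetic generator that produces desk-scale inputs with the *same
statistical structure* and a known ground truth.  All quantitative
claims made by the test suite and the acceptance script are recoveries
of those ground truths, not reproductions of any published all-atom
result.

# The estimators

## Pulling work and the Jarzynski profile (`work_profile`)

An SMD pull drags a harmonic restraint of stiffness $k$ (default
2 kcal/mol/Å²) along a schedule $c(t)$ from 10 Å to 58 Å and records,
every 500 fs, the restraint center, the measured coordinate $x$ and the
accumulated external work
$$W = \sum k\,(c - x)\,\Delta c,$$
the stiff-spring bookkeeping convention used by MD engines.
`recompute_work()` re-accumulates this sum from the recorded columns
and flags a trace whose stored endpoint deviates by more than 2 %.

`work_profile()` bins an ensemble of traces by the *restraint center*
(0.1 Å bins by default).  Binning by the protocol coordinate rather
than the instantaneous coordinate means every trajectory contributes to
every bin and the profile is a function of the protocol, which is the
reproducible choice.  Three per-bin estimators are reported, each
anchored to 0 at the first bin because only differences are physical:

* the mean work $\langle W \rangle$ with its standard error,
* the Jarzynski estimate $-k_BT \ln \langle e^{-W/k_BT} \rangle$
  (log-sum-exp guarded), and
* the second-order cumulant $\langle W \rangle - \mathrm{Var}(W)/2k_BT$,
  exact for Gaussian work distributions.

Jensen's inequality guarantees `jarzynski <= mean_work` bin-wise; the
cumulant estimator is only ordered between the two for near-Gaussian
work distributions, so the test suite asserts the three-way ordering
only on a harmonic (linear-response, hence exactly Gaussian) ensemble.

What the center-binned Jarzynski profile converges to is the
equilibrium free energy of the *combined* system
$U(x) + \tfrac{k}{2}(x - c)^2$ as a function of $c$ — not the bare
potential of mean force.  `restrained_free_energy()` computes that
reference by numerical quadrature and is the ground truth used in the
recovery tests.  At the default spring stiffness the thermal spring
width is $\sqrt{k_BT/k} \approx 0.55$ Å at 310 K, so the convolution
matters on the scale of the 0.1 Å bins and glossing over it would
misstate the target of the estimator.

`barrier_delta()` subtracts work spans (max − min of a chosen estimator
over a stated interval) between two profiles and reports the result in
kcal/mol and in kT.  The kT temperature defaults to the profile's
simulation temperature (310 K) with an option for 298 K, since barrier
heights are conventionally quoted in room-temperature kT.
`rate_slowdown()` converts an extra barrier $\Delta\Delta W$ (in kT)
into the Boltzmann factor $e^{-\Delta\Delta W}$: 20 kT gives
$2.06\times10^{-9}$, 50 kT gives $1.9\times10^{-22}$.  Both conversions
are provided because which barrier (a full-pull work difference or a
headgroup-passage segment) enters a rate estimate is a modelling
decision for the caller, not something the package can decide.

## Alchemical free energies (`bar_dg`, `compose_windows`, `ddg_cycle`)

A free-energy-perturbation (FEP) calculation introduces the mutation
alchemically through a coupling parameter $\lambda$ (0 = alanine,
1 = threonine) split into windows.  The default schedule is the
11-value, endpoint-concentrated list
`r paste(default_lambda_schedule(), collapse = ", ")`, whose ten
intervals are the windows; "10 windows" always means these intervals.

The package fixes one sign convention throughout:
$\Delta U = U(\lambda_{to}) - U(\lambda_{from})$ in *whichever* endpoint
ensemble sampled it.  This removes the classic Bennett-acceptance-ratio
(BAR) sign ambiguity at the cost of one explicit rule in the file
formats (engine "reverse" runs are sign-flipped on input by
`read_fep_samples`).

`bar_dg()` solves the self-consistent Bennett equation
$$\sum_F f\!\big(\beta(\Delta U_i - C)\big) =
  \sum_R f\!\big(\beta(C - \Delta U_j)\big), \qquad
  C = \Delta G + k_BT\ln(n_F/n_R),$$
with $f$ the Fermi function, by bisection on a bracket expanded
geometrically from the two one-sided Zwanzig estimates.  The residual is
monotone in $\Delta G$, so bisection is derivative-free and guaranteed;
the default tolerance is $10^{-8}$ kcal/mol.  The standard error is the
asymptotic Bennett variance from the relative fluctuations of the two
Fermi-weight sums; when the forward/reverse sample overlap is so poor
that this variance diverges the estimate is returned with
`converged = FALSE` and a warning rather than a silent number.
`zwanzig_dg()` ($-k_BT\ln\langle e^{-\beta\Delta U}\rangle$, log-sum-exp
guarded) is retained as the one-sided baseline and cross-check; on
Crooks-consistent Gaussian suites BAR beats it in RMSE, which the test
suite checks over 50 replicates.

`compose_windows()` verifies that the windows tile $[0,1]$ without gaps
or overlaps, sums the per-window estimates, propagates errors in
quadrature, and reports the forward/reverse hysteresis of the two
one-sided compositions as a sampling diagnostic.  `ddg_cycle()` closes
the thermodynamic cycle
$$\Delta\Delta G_{bind} = \Delta G_{mut}^{unbound} -
  \Delta G_{mut}^{bound},$$
with the sign convention that a positive value means the mutant binds
the substrate less strongly.

When sidechains are frozen during the transformation, each endpoint
needs a configurational-density correction.  `knn_correction()`
estimates the density at the frozen reference from the $k$-th
nearest-neighbor distance among sampled configurations,
$\hat\rho = k / (n V_d(r_k))$ with $V_d$ the volume of the $d$-ball,
and returns the pairwise correction
$-k_BT\ln(\hat\rho_a/\hat\rho_b)$.  The neighbor rank defaults to
$k = 4$.  Two inputs are deliberately the caller's: the scalar
distance metric (an RMSD-like distance computed upstream; the package
does no 3-D geometry) and the effective dimension $d$, which is a
modelling statement about the frozen configurational space, not a
constant the package could guess.  Corrections are applied as matched
endpoint pairs, one pair per leg, entering that leg's $\Delta G$
additively.

## Distance modes and tunneling ratios (`find_modes`, `rate_ratio_*`)

Equilibrium simulations of the two channel variants are summarised by
the distribution of the headgroup-center-to-N2-center distance $R$.
`find_modes()` estimates the density with a Gaussian kernel on a
0.01 Å grid (Silverman's rule bandwidth by default, requiring at least
100 samples), takes strict local maxima, merges modes closer than one
bandwidth (keeping the higher) and orders them by descending height, so
the first mode is the most prominent — mirroring how one reads peak
positions off a plotted distribution.  KDE was chosen over a
two-component EM fit as the primary path precisely because it mirrors
the plotted density; a mixture fit answers a subtly different question
(component means, not density peaks).

Nonadiabatic electron-transfer theory makes the coupling decay
exponentially with donor–acceptor distance, $|H|^2 \propto e^{-\beta R}$.
`rate_ratio_peaks(d_ref, d_alt, beta)` returns
$e^{\beta(d_{ref}-d_{alt})}$; `rate_ratio_ensemble()` averages
$e^{-\beta R}$ over two sampled ensembles instead of using single peak
positions, and is bounded above by the peak ratio when the alternative
ensemble's shortest mode dominates.  `marcus_rate()` supplies the full
nonadiabatic expression
$$k \propto |H(R)|^2 (4\pi\lambda k_BT)^{-1/2}
  e^{-(\Delta G^0+\lambda)^2/4\lambda k_BT},
  \qquad H(R) = H_0 e^{-\beta(R-R_0)/2},$$
up to the $\hbar$ prefactor, so only ratios are meaningful.

The decay constant defaults to $\beta = 1.8$ Å⁻¹, a generic value for
tunneling through protein media.  At the two peak distances 14.1 Å and
13.5 Å it gives $e^{1.08} \approx 2.9$, i.e. a factor of 3 to one
significant figure.  $\beta$ is an exposed parameter, not a fitted
constant: reported ratios should always state the $\beta$ they used.

# The synthetic generators

The generators define the study conditions for every recovery test.

**`simulate_pulling`** integrates *overdamped* Langevin dynamics (no
inertia) on a 1-D model potential under the moving restraint, with the
Euler–Maruyama update
$x \leftarrow x - \Delta t\,(U'(x) + k(x-c))/\gamma +
\sqrt{2k_BT\Delta t/\gamma}\,\xi$.  Overdamped dynamics is the right
stand-in because the analysis layer consumes only work traces, and the
quasi-static limit — where estimator biases vanish and closed-form
checks exist — is reachable in seconds.  The simulator refuses to run
if $\Delta t \ge 0.1\,\gamma/k_{\mathrm{eff}}$, where $k_{\mathrm{eff}}$
adds the restraint stiffness to the largest potential curvature probed
over the schedule range padded by two thermal spring widths (the region
the particle actually visits).  The particle is equilibrated at the
fixed starting center for about 30 relaxation times before pulling, so
traces start from the restrained equilibrium with $W = 0$.

The recovery tests use a symmetric quartic double well (minima at
$12 \pm 1.5$ Å, barrier 3 kT) pulled from 10 to 14 Å with
$\gamma = 0.05$ kcal·ns/mol/Å², $\Delta t = 10^{-4}$ ns, 200
trajectories, and a 5 ns "slow" versus 0.5 ns "fast" schedule — the
same 10× protocol contrast used in engine-scale extraction studies,
scaled to a desk problem.  These sizes (≈ 5×10⁴ steps × 200
trajectories) keep the full suite under ten seconds while leaving the
slow schedule close enough to quasi-static that the Jarzynski profile
recovers the quadrature reference to a small fraction of kT.

**`generate_fep_samples`** draws forward samples from
$\mathcal N(\Delta G + \sigma^2/2k_BT, \sigma^2)$ and reverse samples
from $\mathcal N(\Delta G - \sigma^2/2k_BT, \sigma^2)$.  This pair
satisfies the Crooks fluctuation relation exactly, so BAR is
asymptotically unbiased for $\Delta G$ — making the generator a real
ground truth rather than a convenience.  The cycle-recovery conditions
are $\sigma = 1$ kcal/mol and $n = 4000$ samples per direction per
window (2 ns of acquisition at 500 fs cadence), with true legs of 10
and 6 kcal/mol so the recoverable $\Delta\Delta G$ is 4 kcal/mol — the
magnitude scale of a binding-affinity-shifting point mutation.

**`generate_distance_mixture`** draws from a Gaussian mixture and keeps
each sample's generating component.  The wild-type stand-in is a single
component at 14.1 Å (sd 0.2 Å); the mutant stand-in is 60 % at 13.5 Å
plus 40 % at 14.1 Å (sd 0.15 Å), i.e. a bimodal distribution whose
*more prominent* peak is the proximal one.

What the generators do **not** emulate: correlated noise and slow
conformational relaxation (samples are i.i.d. within a window; real MD
time series are autocorrelated, so real-data error bars need an
effective sample size), anharmonic and multimodal work distributions
beyond what the model potentials produce, fat-tailed energy
differences from soft-core endpoints, and any 3-D geometry.  Passing
the recovery tests therefore demonstrates estimator correctness under
the stated statistical assumptions — not that engine-scale results are
reproduced, which requires the deposited trajectories and cluster-scale
reruns that the IO dialects exist to accept.

# Numerical choices and degenerate inputs

* All internal units are kcal/mol, Å, ns, K; kT conversions are
  reported alongside ($k_B = 0.0019872041$ kcal/mol/K, default
  $T = 310$ K).
* Exponential averages (`zwanzig_dg`, the Jarzynski bin average,
  `rate_ratio_ensemble`) all go through one log-sum-exp helper.
* `bar_dg` on a degenerate window (identical one-sided estimates, e.g.
  $\sigma = 0$) short-circuits to the common value instead of calling
  the root finder on an empty bracket; windows with no reverse samples
  raise an error that names `zwanzig_dg` as the one-sided fallback.
* `work_profile` errors if any trace's recording leaves a gap wider
  than two bins (silent interpolation over a hole would fabricate
  data); profile interpolation at bin centers uses mean-collapsed ties.
* `find_modes` errors on (numerically) constant series and falls back
  to the global maximum for strictly monotone densities, so
  nondegenerate input always yields at least one mode.
* Seeds: every generator takes an explicit integer seed; the CLI
  expands one global seed into per-subcommand streams by a fixed
  affine rule so the streams are independent but reproducible, and
  JSON outputs are byte-identical across reruns (no timestamps in the
  provenance header).

# Command-line interface

The analysis functions are the primary interface.  For shell use, a
thin launcher (`inst/cli/qtrap`) dispatches the subcommands
`simulate-pulling`, `simulate-fep`, `simulate-distances`,
`analyze-smd`, `analyze-fep`, `cycle`, `tunneling` and `demo` through
`qtrap_main()`; simulation parameters come from a YAML config, and
every JSON result carries a provenance header (package version, seed,
config hash).

# Known limitations

* No WHAM/MBAR umbrella or multistate estimation; BAR per window plus
  composition is the supported path.
* The work-profile comparison treats the mean-work profile as the
  default estimator for cross-system comparison; whether a published
  profile shows mean work or a Jarzynski estimate is often unstated,
  so `barrier_delta` lets the caller choose.
* The kNN correction assumes the supplied scalar distances are a
  faithful metric of the frozen configurational space and that the
  effective dimension is known; both are modelling inputs.
* `rate_ratio_ensemble` weights proximal excursions exponentially and
  is therefore sensitive to the sampled tail; with few samples it is
  noisier than the peak-based ratio.
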