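# qtrap

Post-simulation inference for molecular-dynamics studies of substrate
trapping in the ubiquinone (CoQ10) channel of respiratory complex I.

## The problem

Channel-lining point mutations in the ND1 subunit of complex I — such
as the alanine→threonine substitution associated with Leber's
hereditary optic neuropathy — can change three things at once: how
strongly the channel binds its CoQ10 substrate, how fast the substrate
can leave, and how fast electrons tunnel from the terminal
iron–sulfur cluster (N2) to the quinone headgroup.  Molecular dynamics
produces the raw evidence for all three, but as large tables that still
need careful statistical inference:

* **Steered-MD work traces** → binned work/free-energy profiles.
  `work_profile()` reports the mean work, the Jarzynski estimator
  −kT ln⟨e^(−W/kT)⟩ and the second-order cumulant per 0.1 Å bin of the
  restraint center; `barrier_delta()` subtracts barrier spans between
  two systems and `rate_slowdown()` converts the difference ΔΔW (in kT)
  into the Boltzmann factor e^(−ΔΔW) by which escape slows.
* **Alchemical (FEP) energy differences** → a relative binding free
  energy.  `bar_dg()` solves the self-consistent Bennett
  acceptance-ratio equation per λ window, `compose_windows()` sums the
  windows across the schedule, `ddg_cycle()` closes the thermodynamic
  cycle ΔΔG_bind = ΔG_mut(unbound) − ΔG_mut(bound), and
  `knn_correction()` supplies k-nearest-neighbor density corrections
  for frozen-sidechain endpoints.
* **Donor–acceptor distance series** → density modes and tunneling-rate
  ratios.  `find_modes()` reads peak positions off a kernel density
  estimate; `rate_ratio_peaks()` and `rate_ratio_ensemble()` apply the
  exponential coupling decay |H|² ∝ e^(−βR); `marcus_rate()` gives the
  full nonadiabatic rate expression.

Every estimator is paired with a synthetic generator
(`simulate_pulling()` — overdamped Langevin pulling on model
potentials, `generate_fep_samples()` — Crooks-consistent Gaussian
windows, `generate_distance_mixture()` — Gaussian distance mixtures)
so the whole chain is testable at desk scale against known ground
truth.  Readers for plain TSV plus MD-engine `SMD`-log and `fepout`
dialects connect the same chain to engine-scale data.

## Worked example

Recover a 4 kcal/mol relative binding free energy from a synthetic
thermodynamic cycle (two legs with true totals 10 and 6 kcal/mol,
Gaussian ΔU noise σ = 1 kcal/mol, 4000 samples per direction per
window, 10 windows per leg), then analyse a bimodal mutant-like
distance distribution:

```r
library(qtrap)

cyc <- generate_cycle_dataset(10, 6, sigma = 1, n = 4000, seed = 1)
leg <- function(ws) compose_windows(lapply(ws, bar_dg), ws)
ddg_cycle(leg(cyc$unbound), leg(cyc$bound))
#> Thermodynamic-cycle relative binding free energy
#>   dG_mut (unbound):    9.976 kcal/mol
#>   dG_mut (bound):      6.046 kcal/mol
#>   ddG_bind:            3.930 kcal/mol +/- 0.053
#>   (positive: the mutant binds the substrate less strongly)

mut <- generate_distance_mixture(
  mixture_spec(data.frame(weight = c(0.6, 0.4), mean = c(13.5, 14.1),
                          sd = c(0.15, 0.15)), n = 1e5, seed = 12), "A52T")
modes <- find_modes(mut)
round(as.data.frame(modes), 3)
#>   position height
#> 1   13.493  1.547
#> 2   14.102  1.056

rate_ratio_peaks(14.1, modes$position[1])   # beta = 1.8 per Angstrom
#> [1] 2.982
rate_slowdown(20)                           # 20 kT extra escape barrier
#> [1] 2.061154e-09
```

The cycle estimate lands within its propagated error of the true
4 kcal/mol; the mode detector recovers both mixture components
prominence-ordered; shortening the donor–acceptor distance from
14.1 Å to the 13.5 Å mode speeds tunneling by about a factor of 3;
and a 20 kT extra barrier slows escape by about 2 × 10⁻⁹.

A thin command-line launcher (`inst/cli/qtrap`) exposes the same chain
as subcommands (`simulate-pulling`, `simulate-fep`,
`simulate-distances`, `analyze-smd`, `analyze-fep`, `cycle`,
`tunneling`, `demo`); see the methods vignette
(`vignettes/quinone-trapping-analysis.Rmd`) for the model details,
parameter choices and limitations.

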