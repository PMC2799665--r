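# looplab

End-to-end loop-closure kinetics of unfolded polypeptide chains, from
contact-quenching fluorescence-style signals and coarse-grained chain
simulations.

## What it does, and for whom

Attaching a fluorophore to one end of a flexible peptide and a quencher
(tryptophan) to the other turns end-to-end contact formation into a
blinking signal: bright while the loop is open, dark while it is closed.
For experimentalists and simulators working on such systems, `looplab`
provides the complete analysis chain:

- **State assignment** - end-to-end minimum distances from trajectories,
  binarized at a fixed or free-energy-derived cutoff
  (`min_distance_series`, `binarize`, `select_cutoff`).
- **Correlation analysis** - the second-order fluorescence
  autocorrelation G(tau) and the hydrogen-bond existence autocorrelation
  C(t), with exact brute-force-verified fast paths
  (`fluorescence_autocorrelation`, `hbond_existence_autocorrelation`).
- **Kinetic fitting** - the two-state model
  `G(tau) = 1 + (1/K) exp(-tau/tau_r)` with conversion to closing and
  opening times `tau_c = tau_r (1 + K)`, `tau_o = tau_r (1 + K)/K`;
  stretched + multi-exponential fits for sub-nanosecond dynamics;
  hydrogen-bond lifetimes; power-law scaling `k ~ n^gamma` of closure
  rates with chain length (`fit_two_state`, `derive_times`,
  `fit_multiexp`, `fit_hbond_lifetime`, `fit_powerlaw`).
- **Free-energy profiles** - `F(r) = -kB T ln p(r)` along the end-to-end
  distance, with barrier location and automatic open/closed cutoff
  selection (`fe_profile`, `find_barrier`).
- **Structural analysis** - backbone hydrogen bonds by geometric or
  Kabsch-Sander energy criteria, beta-segment ladders, Ramachandran
  region occupancies, open-state structure statistics (`detect_hbonds`,
  `beta_segments`, `phi_psi`, `open_state_structure_stats`).
- **Synthetic data** - telegraph processes with exact exponential dwell
  sampling, an overdamped bead-spring chain simulator with an optional
  hydrogen-bond-like short-range attraction, independent on/off bond
  records, and ideal peptide geometries including a refined beta hairpin
  (`gen_telegraph`, `gen_chain_trajectory`, `gen_hbond_series`,
  `build_ideal_geometry`).
- **Orchestration** - `run_pipeline()` for config-driven end-to-end runs
  with provenance, and `scaling_study()` for closure-rate scaling over
  chain lengths.

## Worked example

Simulate a 100 microsecond open/closed record with mean closing time
50 ns and opening time 80 ns, correlate it, and fit the two-state model
over the 6-300 ns window:

```r
library(looplab)
s  <- gen_telegraph(k_close = 1/50, k_open = 1/80, dt = 0.1,
                    n_steps = 1e6, seed = 1)
cv <- fluorescence_autocorrelation(s, max_lag = 300)
fit_two_state(cv, window = c(6, 300), series = s)
#> <two-state fit> K = 0.612, tau_r = 30.37 ns, tau_c = 48.95 ns,
#>                 tau_o = 79.98 ns, open 38.0% (r = 0.9997)
```

The fit recovers the generator's time constants within ~2%: `K` is the
open/closed equilibrium constant (the fitted amplitude is 1/K), `tau_r`
the relaxation time, and the closing/opening times follow from the
two-state algebra. `open 38.0%` is the equilibrium open fraction
K/(1+K); with `series` supplied the report also carries split-half
one-sigma errors.

Scaling of experimental closure rates with chain length, using the
packaged reference table of time constants for labelled GS peptides:

```r
tab <- gs_closure_table()
fit_powerlaw(tab$n, 1 / tab$tau_c_exp_ns, n_min = 10)
#> <power-law fit> k ~ n^gamma, gamma = -1.446 +/- 0.046 (5 points)
```

The exponent of about -1.4 for chains with more than 10 peptide bonds is
consistent with Gaussian-chain predictions (between -1.5 and -2.1 in the
ideal regime; shorter chains roll over to slower, length-independent
kinetics).

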