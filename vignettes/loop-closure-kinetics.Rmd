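---
title: "Loop-closure kinetics of unfolded peptides: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop-closure kinetics of unfolded peptides: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(looplab)
```

## The problem

When the two ends of an unfolded polypeptide chain meet, a loop closes.
The rate of this elementary event bounds how fast a protein can begin to
fold, and its dependence on chain length discriminates between polymer
models of the unfolded state. Experimentally, loop closure is observed by
attaching a fluorophore to one chain end and a quencher (tryptophan) to
the other: van der Waals contact switches the fluorescence off, so the
fluctuating intensity I(t) is a telegraph-like record of open (bright)
and closed (dark) states, and its second-order autocorrelation G(tau)
carries the closing and opening kinetics. `looplab` implements the full
analysis chain for such signals - state assignment, autocorrelation,
kinetic fitting, scaling analysis, free-energy profiling, and backbone
hydrogen-bond / beta-segment structural statistics - together with
synthetic generators that produce inputs with exactly the statistical
structure the analysis assumes.

## The two-state model

For an all-or-none equilibrium between a fluorescent open state and a
quenched closed state, the normalized autocorrelation of a binary signal
is

  G(tau) = < I(t) I(t + tau) > / < I >^2 = 1 + (1/K) exp(-tau / tau_r),

where `K = [open]/[closed]` and `tau_r` is the mean relaxation time,
`1/tau_r = 1/tau_c + 1/tau_o`. The mean closing time `tau_c` (the dwell
in the open state) and opening time `tau_o` follow algebraically:

  tau_c = tau_r (1 + K),  tau_o = tau_r (1 + K) / K,
  fraction open = K / (1 + K).

`fit_two_state()` fits the exponential over a lag window (6-300 ns by
default, the window imposed by the time resolution of nanosecond FCS) and
`derive_times()` applies the conversion. The amplitude convention `1/K`
is fixed by internal consistency: with it, the open fractions implied by
the printed closing/opening times of flexible GS peptides fall in the
expected ~30-40% band, reflecting stacked dye/quencher geometries that
stabilise the closed state. The reciprocal convention is available as a
documented switch (`k_convention`).

```{r twostate}
s <- gen_telegraph(k_close = 1 / 50, k_open = 1 / 80, dt = 0.1,
                   n_steps = 1e6, seed = 1)
cv <- fluorescence_autocorrelation(s, max_lag = 300)
fit_two_state(cv, window = c(6, 300))
```

Sub-nanosecond dynamics are non-exponential; `fit_multiexp()` fits
`baseline + A exp[-(t/tau_1)^beta] + sum_i B_i exp(-t/T_i)` beyond a 3 ps
start, with one or two nanosecond exponentials chosen by a small-sample
corrected information criterion when requested. Fits with correlation
coefficient at or below 0.95 are flagged, not rejected - desk-scale
synthetic records may legitimately sit below a gate meant for
microsecond data.

## State assignment and cutoffs

`binarize()` assigns closed to frames whose end-to-end minimum distance
is at or below a cutoff (the tie at exact equality goes to closed; the
choice is measure-zero but determinism requires pinning it). Cutoffs are
not free parameters: `fe_profile()` builds the probability-density-based
free-energy profile `F(r) = -kB T ln p(r)` along the distance and
`select_cutoff()` returns the barrier position for escaping the
short-distance global minimum. The conventional values for dye-labelled
(0.45 nm) and unlabelled (0.58 nm) GS peptides ship as `gs_cutoffs`.

Numerical choices, made here because the procedure itself does not
prescribe them: bins of 0.02 nm; barrier detection on a 3-bin
moving-average smoothing with ties broken toward smaller r; bins with
fewer than 10 samples masked as unresolved; a candidate barrier must rise
at least 0.5 kJ/mol (about 0.2 kT at 293 K) above both flanking minima,
since sub-thermal wiggles in sparse tails are sampling noise. The
minimum locator refines the argmin with a local parabola because with
10^6 samples the raw argmin of a flat-bottomed profile wanders by ~5% of
its position while the refined one stays within ~2%. The Jacobian
correction (p(r)/r^2) exists behind a flag and is off by default: the
plain probability density is the quantity whose barrier defines the
open/closed boundary.

## Hydrogen bonds and beta segments

Backbone hydrogen bonds are detected either geometrically (N...O at most
0.35 nm and H-N...O at most 30 degrees, a common MD-analysis default) or
by the Kabsch-Sander electrostatic energy

  E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol,

with a bond below -0.5 kcal/mol (the DSSP default). Amide hydrogens
absent from united-atom inputs are reconstructed in the peptide plane,
0.101 nm from N, anti to the preceding carbonyl. Partners closer than
two residues in sequence are excluded.

A beta segment is a ladder of at least two consecutive inter-strand
hydrogen bonds. The implementation replaces full DSSP ladder/bridge
bookkeeping with the minimal register rule: antiparallel ladders conserve
the donor + acceptor residue-index sum, parallel ladders the difference,
and consecutive rungs sit within two residues of each other; bonds fewer
than three residues apart cannot span two strands. This is exactly the
operational "two to six consecutive inter-strand hydrogen bonds"
definition, without helix classes or bulge handling.

The existence autocorrelation `C(t)` of a bond - the probability that a
bond intact at a starting time is intact a lag t later - uses the
intermittent convention by default (transient breaking tolerated), with
the strictly non-increasing continuous convention available for
sensitivity analysis. `fit_hbond_lifetime()` models C(t) as a plateau
plus a stretched picosecond component and a single nanosecond
exponential whose relaxation time is reported as the mean bond lifetime;
the stretched and exponential relaxation times are bounded to lie on
opposite sides of a 1 ns split, which keeps the two otherwise
exchangeable components identifiable.

## Synthetic data: what it emulates, what it does not

The generators are the package's test bed and define its study
conditions.

**Telegraph processes** (`gen_telegraph`) draw exact exponential dwell
times per state and then point-sample the process on the dt grid, so
short-dwell statistics stay unbiased even when mean dwells approach dt -
per-step Bernoulli flipping would distort exactly the picosecond regime
where multi-exponential fits operate. Rates of order 1/20 to 1/100 per
ns, sampling at 0.1 ns, and records of 10^6-10^7 steps mirror the
regime of the nanosecond experiments.

**The bead-spring chain** (`gen_chain_trajectory`) runs overdamped
Brownian dynamics of one bead per residue in nm / ps / kJ/mol units
(kB = 0.0083145), bond length 0.38 nm (the CA-CA virtual bond), stiff
harmonic bonds (8000 kJ/mol/nm^2, keeping bond-length fluctuations ~1%
of the freely jointed reference), optional bending stiffness, soft-core
excluded volume, and a smooth, non-directional short-range attraction
between beads at least three apart in sequence - the minimal surrogate
for intra-backbone hydrogen bonding. Friction 500/ps on unit-mass beads
and dt = 0.01 ps are stability-driven artifact choices: the surrogate's
absolute time scale is arbitrary, and no parameter derives from any
atomistic force field. All of this is echoed into generated metadata.
What the surrogate deliberately lacks: solvent, electrostatics,
directional hydrogen bonds, side chains, and the dye/quencher - so
passing tests demonstrate correctness of the analysis chain on data
obeying its assumptions, not fidelity of the surrogate to real peptides.

**Closure rates from the chain** (`scaling_study`) default to the
equilibrium-averaged mean first-passage time to a 0.45 nm contact
(`mfpt_closure_time`): from every open sample of a long equilibrium
record, the time until the ends next touch, averaged over all origins.
This is the quantity whose chain-length scaling polymer closure theory
describes, it uses the whole record (a few percent statistical error at
the sizes used here), and a first passage is unambiguous under rapid
recrossings of the contact boundary. Two alternatives exist for
comparison and have documented pathologies on this surrogate: raw
interior open dwells (`method = "dwell"`) count every sub-picosecond
boundary recrossing as a closure, flattening the apparent exponent to
about -1.4, and the fluorescence-pipeline route (`method = "two_state"`,
binarize / correlate / windowed fit) is unbiased but noisy for long
chains whose correlation amplitude 1/K drops below 1%. With the
first-passage route the exponent of closure rate vs number of bonds is
stable near -2 for 8-24 beads, inside the Gaussian-chain band (-2.1 to
-1.5); longer chains get proportionally longer records because
first-passage means converge slowly.

**Ideal geometries** (`build_ideal_geometry`) are constructed from
standard covalent internal coordinates by sequential frame extension.
The beta hairpin starts from ideal antiparallel-strand dihedrals
(-139, 135) and a type-I' two-residue turn and then refines the six
turn-flank dihedrals numerically against the Kabsch-Sander energies of
the intended in-register rungs (clipped from below: the raw 1/r energy
is unbounded and would reward atom collapse), with a soft steric guard.
The result is guaranteed to carry an antiparallel ladder detectable by
both criteria.

Seeds: one user-facing seed per call; independent streams (bonds,
replicas) receive child seeds drawn deterministically from it, and the
chain integrator runs its own seeded generator stream, so identical
seeds give identical records on one platform.

## Error convention

One-sigma errors on fitted quantities follow the record-splitting
convention: the analysis is applied to each half of the record and the
two-point sample standard deviation `|a - b| / sqrt(2)` is reported
(`split_half_errors`), alongside covariance-based errors from the fits.
A half-record that loses the relaxation downgrades the split-half
estimate to NA with a warning rather than invalidating the full fit.

## Problem sizes used in the test suite

The suite simulates at sizes where sampling error sits well inside each
tolerance: telegraph recovery uses 1 ms records at 0.1 ns sampling
(10^7 points, ~10^4 transitions, ~1-2% statistical error against a 10%
tolerance, 20 replicas per rate pair); chain statistics use 10^7-step
runs (about 2% standard error on <R^2> against a 5% band); the scaling
study uses 8-24 beads with 2-3 replicas each; the free-energy oracle
uses 10^6 draws. These are the package's chosen study conditions, stated
here so that results are reproducible at the same sizes.

## Known limitations

- The chain surrogate's time scale is arbitrary; only dimensionless
  comparisons (ratios, exponents, orderings) transfer to real peptides.
- The attraction-free phantom chain has a single-welled, purely entropic
  end-to-end free-energy profile, so barrier-based cutoff selection
  applies only to chains with attractive interactions; the pipeline
  falls back to the fixed unlabelled cutoff in that case.
- Beta-ladder logic ignores bulges (register is conserved exactly) and
  assigns no helix or turn classes.
- The multi-exponential family is fitted per curve; no global multi-curve
  fitting, and no Bayesian uncertainty beyond covariance and
  record-splitting.
- Periodic images are ignored in minimum distances; trajectories from
  periodic simulations must be pre-imaged.
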