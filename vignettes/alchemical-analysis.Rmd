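---
title: "Methods: thermodynamic integration, uncertainty and benchmarking for alchemical mutation scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic integration, uncertainty and benchmarking for alchemical mutation scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchemr)
```

## The model

A point mutation's effect on a protein–protein binding affinity is
computed from a thermodynamic cycle: the residue is alchemically
transformed from wild type to mutant once in the bound complex and once
in the unbound (apo) protein, and

$$\Delta\Delta G_b = \Delta G_{\mathrm{complex}} - \Delta G_{\mathrm{apo}},$$

exploiting path independence of the free energy. Each leg is estimated by
thermodynamic integration over the coupling parameter $\lambda$:

$$\Delta G = \int_0^1 \left\langle \frac{\partial V}{\partial \lambda}
\right\rangle_\lambda d\lambda \approx \sum_{i=1}^{n} w_i
\left\langle \frac{\partial V}{\partial \lambda} \right\rangle_{\lambda_i},$$

where the nodes and weights are an $n$-point Gauss–Legendre rule mapped
to $(0,1)$. `gauss_legendre_schedule(12)` reproduces the conventional
12-window scheme (first nodes 0.00922, 0.04794, 0.11505; first weights
0.02359, 0.05347, 0.08004, mirrored about $\lambda = 1/2$ and summing to
one). The rule is exact for polynomial integrands up to degree $2n-1$ and
never evaluates the endpoints, which suits softcore-protected
transformations where the endpoint integrand may be stiff. We compute
nodes and weights through `pracma`'s Golub–Welsch eigen recurrence and
verify them against the printed five-decimal values in the test suite.

The estimator deliberately consumes only per-window *means*
(`ti_integrate()`) and per-window *standard errors* (`ti_error()`,
$\sigma_{\Delta G}^2 = \sum_i w_i^2 \sigma_i^2$). All time-series
handling lives upstream in `window_stats()`, so the quadrature layer
stays free of resampling policy.

## Uncertainty of autocorrelated windows

MD-derived $\partial V/\partial\lambda$ series are autocorrelated, so a
naive $\sigma/\sqrt{N}$ underestimates the error. Per window we:

1. discard the first `equilibration_fraction` of samples (default 0.1,
   the common discard convention; the floor rule removes exactly
   $\lfloor f N \rfloor$ frames, each window independently);
2. estimate the statistical inefficiency $g = 1 + 2\sum_t C(t)$, summing
   the normalized autocovariance until its first non-positive value.
   This truncation is simple and robust at window lengths of
   $10^3$–$10^6$ samples; fancier windowed estimators matter mostly for
   very short series. $g$ is clamped to $\geq 1$, and for an AR(1)
   process with coefficient $\phi$ it approaches $(1+\phi)/(1-\phi)$
   (the test suite checks $\phi \in \{0.5, 0.8, 0.9\}$ at $N = 10^6$
   within 10%);
3. subsample at integer stride $\lceil g \rceil$ starting from the first
   retained frame and compute the SEM from the subsample's $n-1$
   variance over its count. The mean is taken over *all* retained
   frames — subsampling only enters the error. The alternative
   convention (inflating the full-sample variance by $g$) agrees
   asymptotically; the subsample convention was adopted as the more
   literal reading of "resample, then compute variances".

A window with exactly zero variance (a null transformation,
$\partial V/\partial\lambda \equiv 0$) is reported with SEM 0 and
$g = 1$ rather than as an error, so control legs pass through the
pipeline. `statistical_inefficiency()` itself still rejects constant
input, since $C(t)$ is undefined there.

Convergence is monitored with `convergence_profile()`: the cycle
$\Delta\Delta G_b$ recomputed on cumulative prefixes (forward) and
suffixes (reverse) of every window. For stationary data the two profiles
agree within combined errors as the fraction approaches one; a
persistent gap flags unequilibrated sampling.

## Thermodynamic cycle and charge bookkeeping

`compute_cycle()` runs the whole pipeline from a manifest (YAML on disk,
or an in-memory list): read schedule and windows per leg, per-window
statistics, TI per leg, difference and combined error
$\sigma^2 = \sigma^2_{\mathrm{complex}} + \sigma^2_{\mathrm{apo}}$.
Legs with different schedules are allowed with a warning, since each
leg's $\Delta G$ is schedule-local.

Charge-changing mutations would leave a charged simulation box, so the
cycle attaches an alchemical co-ion plan: annealing a negative charge
(ASP→ALA) or creating a positive one (TYR→LYS) converts a Na⁺ ion to a
water molecule; the opposite change (LYS→GLN) converts a water to Na⁺.
Formal charges follow the standard pH-7 convention (ASP/GLU −1, LYS/ARG
+1, histidine neutral — no charged mutation in the benchmark set
involves His). Only $|\Delta q| \leq 1$ is supported; larger deltas do
not arise for single mutations at fixed protonation and are rejected.
The plan is bookkeeping for simulation setup, validated as a rule; no
electrostatic finite-size correction is computed (a known limitation for
quantitative charge-change work).

## Atom mapping

A single-residue transformation needs a partition of both end-state
residues into a common core (transformed linearly) and unique atoms
(softcore). Residue topologies for the 20 standard amino acids are
embedded with AMBER-style atom names.

- `default_mapping()` pairs the backbone and softcores *every* sidechain
  atom — the conservative scheme. Glycine's surplus α-hydrogen pairs
  HA2↔HA and leaves HA3 unique.
- `mcs_mapping()` grows a maximal common connected subgraph outward from
  the backbone along both bond graphs, pairing atoms of equal element
  only when the new pair is bond-consistent with every previous pair.
  Ties are deterministic: heavy atoms before hydrogens, then
  lexicographic atom name. Hydrogen-count mismatches on a paired heavy
  atom (THR CB carries one H, SER CB two) pair in lexicographic order
  and leave the surplus unique — this is what yields the single unique
  serine β-hydrogen. Ring-symmetric choices (PHE/TYR CD1/CD2) are
  equivalent by symmetry, so lexicographic resolution suffices.

With these rules THR→SER keeps the −CβHOH group common (unique sets:
{CG2, HG21, HG22, HG23} vs {HB3}) and PHE→TYR keeps the full ring common
({HZ} vs {OH, HH}) — the refined schemes that preserve a hydroxyl–ion
coordination or an aromatic stacking contact during the transformation.
The MCS scheme is advisory: for chemically dissimilar pairs (ASP→ALA)
the default scheme remains the sensible choice, and nothing forces MCS.
`validate_mapping()` audits any mapping — including hand-written ones —
for partition, element and bond-isomorphism violations, reporting rather
than throwing.

## Conformational-state selection

Before transforming a residue it matters which conformational state the
starting structure comes from. `histogram_states()` takes a scalar
descriptor series (a distance in Å, or a dihedral in degrees with
periodic wrap), histograms it, and treats each maximal run of occupied
bins as a state; states below `min_occupancy` (default 0.01) merge into
the nearest mode. Defaults: 72 bins for periodic descriptors (5° bins),
0.2-unit bin width otherwise. This is intentionally a 1-D histogram
method, not KDE or k-means: the distributions involved are
well-separated unimodal lobes, and empty-bin separation keeps every
frame assigned to exactly one state with occupancies summing to one.
`representative_frame()` returns the member frame nearest the state's
mode (earliest on ties) — the natural choice of starting structure from
the dominant state; `dominant_state()` breaks exact occupancy ties
toward the lower mode.

The method requires a genuinely empty histogram gap between states; two
lobes that overlap at the chosen bin width merge into one state. That is
the main known limitation, shared with any unsmoothed 1-D approach.

## Experimental benchmark

Experimental $\Delta\Delta G_b$ derives from dissociation constants:
$\Delta G_b = RT \ln K_d$, hence
$\Delta\Delta G_b = RT\ln(K_d^{mut}/K_d^{wt})$ with
$R = 1.9872 \times 10^{-3}$ kcal/(mol·K). Design choices, each encoded
in `run_benchmark()` and its tests:

- **Temperature 298.15 K by default.** This reproduces the published
  experimental column to the printed two decimals (e.g. D38E → 1.96);
  a simulation temperature of 303 K does not. Both are reachable via the
  `temperature` argument.
- **Error convention** $RT\,\sigma_{K_d}/K_d$ of the variant only, no
  wild-type contribution. This was inferred by reproducing the printed
  uncertainty column entry by entry (0.12, 0.17, 0.20, 0.33, 0.08, …)
  and is documented as inferred. One entry (V36A, printed 0.03 vs
  computed 0.035) sits on a rounding boundary and is not asserted.
- **Lower-bound $K_d$ rows** ("> x") convert at the bound, are flagged,
  and enter the MAE as point values.
- **The wild-type control row** is excluded from MAE/r by default
  (`include_wildtype = TRUE` reverses this); it is always present in the
  per-record table.
- **One documented inconsistency:** the L174A printed experimental value
  (0.54 ± 0.11) does not follow from its printed $K_d$ (250 ± 9 nM →
  ≈1.50 ± 0.02 at 298.15 K). The packaged table stores both; statistics
  use the printed column, which is what the published summary statistics
  are built from. When a table carries no printed column, the
  $K_d$-derived values are used throughout.

Statistics carry full precision in the returned tibble; printed-style
rounding (one decimal for MAE, two for r) appears only in the `print()`
summary line. The packaged table also stores the four superseded initial
estimates (T35S −1.6, F28Y 1.4, Y32F −1.5, V33N −1.3) in a separate
column so the initial-accuracy summary can be recomputed via
`comp = coalesce(ddg_comp_initial, ddg_comp_kcal)`.

## Synthetic data: what it emulates, and what it does not

The generators stand in for MD output with known ground truth:

- `gen_dvdl_profile()`: polynomial mean profile $m(\lambda)$ (exact
  $\Delta G = \int_0^1 m$), stationary AR(1) noise (default $\phi = 0.9$,
  $g \approx 19$ — a realistic stress level for the uncertainty module),
  and an exponential equilibration transient confined to the first 10%
  of each window (time constant $fN/5$, so it has decayed to under 1% at
  the discard boundary and the discard step is exercised meaningfully).
- `toy_harmonic_sim()`: Metropolis sampling under
  $V(x;\lambda) = \frac12[(1-\lambda)k_0 + \lambda k_1]x^2$, recording
  $\partial V/\partial\lambda = \frac12(k_1 - k_0)x^2$; exact
  $\Delta G = (k_BT/2)\ln(k_1/k_0)$. The proposal width is tuned toward
  ~40% acceptance during a discarded burn-in.
- `toy_softcore_lj()`: one particle pair in a spherical volume under the
  separation-shifted softcore form
  $V(r;\lambda) = 4\epsilon\lambda[(\alpha(1-\lambda)+(r/\sigma)^6)^{-2}
  - (\alpha(1-\lambda)+(r/\sigma)^6)^{-1}]$ with $\alpha = 0.5$. This
  one-parameter form is the standard separation-shifted choice; only
  self-consistency against the independent quadrature oracle
  $\Delta G = -k_BT\ln(Z_1/Z_0)$, $Z(\lambda) = \int_0^R r^2
  e^{-V(r;\lambda)/k_BT}dr$, is claimed — not equality with any MD
  engine's softcore.
- `gen_twostate_series()`: hidden two-state Markov chain with stationary
  occupancies equal to the requested weights (transition matrix
  $\phi I + (1-\phi)\mathbf{1}w^T$, default $\phi = 0.5$ so a
  $10^4$-frame series pins occupancies to about ±0.01) and Gaussian
  emissions.

All randomness flows from one explicit seed; equal seeds give
bit-identical output (and bit-identical files, since windows are written
with 17 significant digits).

What the synthetic data does *not* capture: slow conformational
transitions coupled to $\lambda$, non-stationary drift, force-field
specifics, finite-size electrostatics, or multi-dimensional order
parameters. Passing the recovery suites therefore validates the
*analysis* — estimator, error model, bookkeeping — not the adequacy of
any particular MD protocol.

## Problem sizes and numerical conventions

Test and validation runs use sizes chosen to make stochastic assertions
sharp at interactive runtimes: 12-window schedules with $8{,}000$–$20{,}000$
Metropolis steps per window for the toy simulators (20 seeded replicates
for the coverage checks, expecting ≥ 18/20 within $3\sigma$), AR(1)
series of $10^6$ samples for the inefficiency benchmark, and $10^4$
frames for state-occupancy recovery (±0.02). Schedule weights must sum
to 1 within $10^{-4}$; readers reject malformed input rather than
repairing it; JSON result documents round-trip numeric fields to at
least 10 significant digits; en-dash/minus variants in CSV input are
normalized to ASCII minus on read. Energies are kcal/mol, distances Å,
temperatures K everywhere on disk, with no unit autodetection.

## Interface conventions

Every analysis function takes its data first and returns a tibble or a
small S3 object with `tidy()`, `glance()` and `autoplot()` methods, so
pipelines compose with the pipe. The on-disk dialects (schedule TSV,
`# lambda=` window files, YAML manifests, JSON results) are repository
conventions chosen for hand-editability and engine-agnosticism — MD
engines do not share a common layout, and the `DV/DL` log extractor
(`extract_dvdl_from_engine_log()`, with a user-supplied trailing-summary
skip count, default 0) is the pragmatic bridge for engine logs. The
`exec/alchemr` script exposes the same operations as shell subcommands
for use in batch workflows.
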