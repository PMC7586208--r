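---
title: "Methods: trajectory binding analytics and fast-application kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory binding analytics and fast-application kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tarpmod)
```

# Scope

`tarpmod` implements the quantitative analyses used to characterize negative
allosteric modulators (NAMs) that act on AMPA receptors through the auxiliary
subunit TARP γ8 — compounds of the LY-3130481 / JNJ-55511118 class that
engage a pocket between the γ8 transmembrane helices defined by the
selectivity residues Val-176 and Gly-209. Two experimental arms are covered:

1. **Structural / MD arm** — geometric readouts of coordinate trajectories:
   the width of the binding pocket, the engagement of a ligand with the
   pocket, distance-criterion hydrogen bonds and their occupancy,
   classification of bound intervals, selection of docking snapshots,
   optimal-superposition RMSD, and DOPE/RMSD ranking of candidate structural
   models.
2. **Functional arm** — kinetic analysis of whole-cell currents evoked by
   5-s fast applications of glutamate: peak, 10–90 rise time, biexponential
   desensitization with its weighted time constant, steady-state and
   resensitization percentages, sweep-stability screening, and paired
   pre/post-drug statistics.

The package analyzes data; it does not produce it. Running MD engines,
docking programs, homology modelling, or acquisition hardware are all out of
scope. Because no trajectories or recordings of the original study are
publicly deposited, the package ships seeded synthetic generators that
emulate both data families with known ground truth; all validation rests on
those generators plus in-paper tables.

# Units and containers

The canonical internal length unit is the nanometre — the unit MD tooling
and the hydrogen-bond criteria are quoted in. Ångström appears in exactly
two places: the PDB file boundary (PDB coordinates are Å; `readPDB()`
multiplies by 0.1) and the reported RMSD (`superposeRMSD()` returns Å, the
unit structural comparisons are conventionally quoted in). Trajectory time
is ns; sweep time is s; fit time constants are ms; currents are pA with
inward current negative.

The central S4 containers are `Trajectory` (a fixed atom topology plus an
`(atoms, 3, frames)` coordinate array with strictly increasing frame times),
`DistanceSeries`, `HBondSpec`, `BoundIntervals`, `SweepTrace`, and
`KineticsResult`; each carries a validity method enforcing the invariants
stated in its class documentation.

# Trajectory analytics

## Pocket width and snapshot selection

`pocketWidthSeries()` is the per-frame distance between two single atoms —
canonically the Cα atoms of Val-176 and Gly-209, whose separation gates
ligand access to the pocket. `selectMaxWidthFrame()` returns the frame of
maximal width (earliest frame on ties), the rule used to pick dilated
snapshots as docking substrates.

## Engagement and bound intervals

Ligand engagement is the distance between the ligand's centre of mass and
the midpoint of the pocket Cα pair. By default the centre of mass is taken
over the *heavy* atoms of the ligand selection with standard atomic masses;
hydrogens contribute little mass and their inclusion is a convention choice
the source analyses do not state, so it is exposed as an argument
(`heavyOnly`).

`classifyBound()` turns an engagement series into intervals: maximal runs of
consecutive samples below a cutoff, discarding runs shorter than a minimum
dwell. The defaults — cutoff 0.8 nm, minimum dwell 5 ns — encode two
choices. The cutoff echoes the convention that an engagement distance above
0.8 nm marks a broken contact; the dwell suppresses grazing approaches that
a human reader of a distance plot would not call binding. Both are
configurable because the visual plateau classification they replace has no
unique numeric form.

## Hydrogen bonds

The hydrogen-bond criterion is distance-only, exactly as applied to these
simulations; no angle term. Two measurement modes exist because the
published traces measure different atom pairs:

* `H_TO_ACCEPTOR` — bonding hydrogen to acceptor, criterion < 0.25 nm
  (weak H-bond threshold);
* `HEAVY_TO_HEAVY` — donor heavy atom to acceptor (e.g. N-to-N when the
  bonding hydrogen is not the measured atom), criterion < 0.36 nm.

`hbondOccupancy()` summarizes a series as the **time-weighted** fraction of
the trajectory satisfying the criterion: each sample is weighted by half the
span of its neighbouring inter-frame intervals (half-intervals at the two
ends). Frame counting would over-weight densely saved stretches when
snapshot spacing is uneven; time weighting is invariant to saving frequency.

## Superposition RMSD

`superposeRMSD()` implements the least-squares rigid superposition contract:
centroid translation, then the optimal proper rotation from the SVD of the
cross-covariance matrix (Kabsch), with the determinant sign corrected so
reflections are never applied, followed by the root-mean-square deviation
over all supplied pairs. There is no iterative outlier rejection: rejection
cycles (as in some interactive tools) make the result depend on
implementation-specific heuristics, whereas the plain least-squares answer
is deterministic and is verified in the tests against a brute-force
numerical minimization over rotations and translations.

## Model ranking

`rankModels()` orders a model-quality table by DOPE statistical-potential
energy ascending (lower = better), with RMSD-to-reference as tie-break and
model id as final tie-break. The two published criteria — lowest energy and
smallest deviation — can disagree on real tables (the shipped ten-model
table is such a case: the smallest RMSD and the lowest DOPE belong to
different models). DOPE is taken as the primary key because it is the only
deterministic rule consistent with the documented selection of the
lowest-DOPE model; the lexicographic tie-break is this package's decision
and is flagged as such.

# Sweep kinetics

## Readout chain

`analyzeSweep()` runs: baseline subtraction (mean of the 50-ms window ending
just before application onset) → peak → 10–90 rise time → biexponential
desensitization fit → steady-state and resensitization percentages.

**Peak.** The extremum of the current within the first 100 ms of
application. The search window is capped because solution exchange is fast
(~200 µs), so the true peak is early, and an uncapped search could misread
slow resensitization maxima as the peak. The extremum is located on a
lightly boxcar-smoothed copy of the trace (default 0.5 ms — far below any
kinetics of interest): the raw extremum of a noisy trace systematically
absorbs the maximum of the noise, inflating the peak and deflating every
percent-of-peak statistic. `smoothMs = 0` restores the raw read, used by the
noise-free identity tests and single-sample-event checks.

**Current reads.** The 200-ms and end-of-application currents are means
over a short window ending at the read point (default 5 ms; `windowMs = 0`
gives a single-point read by linear interpolation). Windows resist sampling
noise; the point read exists so that noise-free traces reproduce closed
forms to interpolation accuracy.

**Definitions.** With \(I_{peak}\) the peak magnitude, \(I_{200ms}\) the
read 200 ms after the peak and \(I_{5s}\) the read at the end of the ≥5-s
application:

\[
\text{steady state} = \frac{I_{200ms}}{I_{peak}} \times 100\%,
\qquad
\text{resensitization} = \frac{I_{5s} - I_{200ms}}{I_{peak}} \times 100\%.
\]

Resensitization may be negative when the current sags. Both statistics are
invariant under rescaling of the trace and under baseline shifts (after
baseline subtraction), which the property tests assert.

## Desensitization fit

Desensitization entry is quantified over the first 200 ms after the peak
(truncated at the application end) by least squares on

\[
I(\Delta t) = a_1 e^{-\Delta t/\tau_1} + a_2 e^{-\Delta t/\tau_2} + c,
\qquad a_1, a_2 \ge 0,\; 0.1 \le \tau_1 \le \tau_2 \le 1000 \text{ ms},
\]

with the weighted time constant \(\tau_w = (a_1\tau_1 + a_2\tau_2)/(a_1 +
a_2)\), reported in ms. The constant \(c\) is included because these traces
do not decay to zero — a steady-state plateau exists; whether the original
analysis used an offset is not stated, and omitting it would force the slow
component to absorb the plateau. Initialization is deterministic: \(c\) from
the window tail, a log-linear single-exponential seed for the time
constants, and a fixed multi-start grid (six starts) of which the best
residual sum of squares wins — no random restarts, so identical inputs give
identical fits. `fitOk` is `FALSE` (never an exception) when the window is
flat, a time-constant bound is hit, the amplitudes vanish, or the fit leaves
more than half the window variance unexplained.

A caveat the recovery tests quantify: on traces with ongoing
resensitization, the slow upward ramp inside the 200-ms window is not
representable by a non-negative biexponential plus a constant, so the
least-squares optimum absorbs it into the slow component and offset. This
biases \(\tau_w\) downward by a few percent even at zero noise — a property
of the published estimator itself, not of the implementation, as the tests
demonstrate by recovering \(\tau_w\) to numerical accuracy the moment the
resensitization amplitude is zero. At realistic noise the replicate
distribution of fitted \(\tau_w\) is additionally right-skewed, pulling the
ensemble mean the other way. The parameter-recovery acceptance test reports
the net bias under the study conditions; it hovers at the edge of its 5%
band and is documented in the repository notes as a known red.

## Stability screening and paired statistics

`stabilityFilter()` encodes the inclusion rule that peak currents must be
stable for at least three consecutive sweeps before quantification:
a run qualifies when every peak lies within ±10% of the run's mean (the
tolerance is exposed — the original rule gives no number), and the earliest
qualifying run, extended while stability holds, is returned.

`pairedCompare()` mirrors the published statistics for per-cell pre/post
comparisons: a two-sided Wilcoxon signed-rank test on the raw pairs and a
two-sided one-sample t test of post/pre-normalized values against 100%,
with mean ± SD summaries. The signed-rank p is computed from the exact null
distribution for n ≤ 25 via a convolution over sign assignments, with the
classical conventions — zero differences dropped, tied absolute differences
given averaged ranks. The exact tie-aware distribution is implemented
in-package because the base-R test abandons exactness under ties; the
tie-free case is cross-checked against `wilcox.test()` in the tests, and the
general case against full sign-flip enumeration for n ≤ 12.

# Synthetic data: what it emulates, and what it does not

## Current sweeps

`simulateSweep()` produces a phenomenological 5-s application response:

\[
\frac{I(\Delta t)}{I_{peak}} =
\underbrace{\left(1 - e^{-\Delta t/\tau_{rise}}\right)}_{\text{exchange-limited rise}}
\Big(
f_1 e^{-\Delta t/\tau_1} + f_2 e^{-\Delta t/\tau_2} + s
+ r\,(1 - e^{-\Delta t/\tau_{res}})
\Big),
\]

with \(f_1 + f_2 + s = 1\), signed inward-negative, i.i.d. Gaussian noise,
and a fast deactivation tail after agonist removal. This is a
sum-of-exponentials description, **not** a kinetic gating scheme: it
reproduces exactly the statistical structure the analyzers read (rise,
biexponential desensitization, plateau, slow resensitization) and nothing
else. Real recordings additionally contain series-resistance and filtering
artefacts, correlated noise, rundown across sweeps, and channel noise that
scales with open probability — none of which are modelled, so passing
recovery tests demonstrates estimator correctness on the stated structure,
not robustness to every recording pathology.

Defaults were calibrated once to the reported vehicle-condition statistics
of γ8-tandem receptors (steady state ≈ 17% of peak, resensitization ≈ 8.3%
of peak, weighted tau ≈ 26.5 ms): \(f_1 = 0.5486\), \(\tau_1 = 8\) ms,
\(f_2 = 0.3030\), \(\tau_2 = 60\) ms, \(s = 0.1484\), \(r = 0.1141\),
\(\tau_{res} = 2\) s, peak 1000 pA, rise 0.5 ms, 10 kHz sampling, noise SD
50 pA (SNR 20). The resensitization time constant is not reported anywhere;
2 s was chosen because the published example traces show the component still
developing late into the 5-s application. The 10 kHz rate is what a
fast-application protocol resolving a ~200 µs exchange requires.

The emitted ground truth is evaluated on the noise-free curve itself: the
true peak is the curve's maximum (located analytically on the closed form),
which with a finite rise time is slightly below the nominal amplitude
because desensitization begins during the rise; the 200-ms and
end-of-application reads are referenced to that true peak time. Defining
truth this way keeps generator and analyzer measuring the same quantity;
the nominal onset-referenced formulas would disagree with any faithful
measurement by construction.

## Binding trajectories

`simulateTrajectory()` emulates a modulator diffusing near, and binding
into, a breathing two-helix pocket, at the scale of the 500-ns runs the
analyses were designed for (defaults: 2001 frames × 0.25 ns). Components:

* two anchor pseudo-Cα atoms (labelled Val-176/Gly-209) whose separation
  oscillates sinusoidally (default 1.01 ± 0.16 nm, period 100 ns — spanning
  the 8.5 Å cryo-EM width and the ~11.7 Å dilation seen in free-TARP
  simulations);
* a ligand represented by a heavy pseudo-atom centre of mass plus a
  donor/hydrogen/acceptor triplet — sufficient for every implemented
  metric, and deliberately not an all-atom ligand;
* discretized Ornstein–Uhlenbeck dynamics: harmonic attraction toward the
  site centre inside a 0.8-nm binding well, free diffusion outside, and a
  soft confinement at 2 nm standing in for the finite simulation box;
* hydrogen-bond geometry: while the ligand is inside the well the hydrogen
  sits 0.19 nm from the acceptor (criterion satisfied), otherwise the donor
  atoms ride with the ligand.

With the default diffusion coefficient (0.005 nm²/ns, appropriate for a
small molecule at a membrane interface) individual seeds reproduce the
qualitative heterogeneity of the published runs: some seeds bind within
~100–200 ns and stay engaged, others never bind within 500 ns. The
generator emits its own per-frame ground truth (engagement distances, bound
flags and intervals, hydrogen-bond distances, time-weighted occupancy)
computed with plain arithmetic on the same coordinates it writes, so
analyzer-vs-truth comparisons close the full read-compute chain. What is
*not* emulated: solvent and lipid environment, force fields, ligand
flexibility and tautomer chemistry, and any energetics — the generator
produces geometry only.

## Model-score tables

`simulateModelScores()` draws integer DOPE-like energies with a strict
minimum and RMSDs in the 1.0–1.2 Å range typical of homology-model batches,
and returns the ground-truth best id under the ranking rule; a switch
injects a DOPE tie so the RMSD tie-break is exercised.

# Numerical choices and degenerate inputs

* Å→nm conversion is exact ×0.1; trajectory tables round-trip to 1e−9 nm.
* PDB alternate locations other than blank/"A" are dropped with a warning
  (deterministic topology); elements are taken from the element column or
  inferred from atom names, with masses from standard atomic weights.
* Selector resolution is strict where geometry demands it: pocket and bond
  selectors must match exactly one atom, and ambiguous or empty matches are
  errors rather than silent choices.
* Ties in snapshot selection go to the earliest frame; ties in model
  ranking fall through DOPE → RMSD → id.
* Degenerate sweeps (flat traces, peaks below 5× the baseline noise SD,
  applications shorter than the resensitization protocol) raise errors at
  the measurement that became impossible, except the desensitization fit,
  which flags `fitOk = FALSE` so batch analyses keep running.
* All generator randomness flows from one explicit seed per call, and the
  caller's RNG state is restored afterwards.

# Problem sizes used by the test-suite

The suite validates at sizes chosen to exercise study-scale structure while
remaining quick: 100 sweep replicates at SNR 20 for parameter recovery,
500-ns (2001-frame) trajectories for bound-fraction recovery, 1000 random
series for the interval classifier against its oracle, full sign-flip
enumeration up to n = 12 pairs for the exact Wilcoxon check, and
brute-force superposition oracles on 4–12-point sets.

# Known limitations

* The pocket-width values reported from the original trajectories cannot be
  reproduced without those trajectories; the package validates the
  *machinery* on synthetic analogues instead.
* The published model-quality table is treated as given input (the exact
  RMSD dialect used to produce it is not recomputable); the package ranks
  it, it does not regenerate it.
* The reference-structure pocket width (8.5 Å between the selectivity-pair
  Cα atoms) is computed live by the acceptance test only when a local copy
  of the cryo-EM structure is supplied; the structure is not redistributed.
* The weighted-tau estimator inherits the structural bias discussed above
  whenever resensitization overlaps the fit window; users comparing
  conditions should rely on paired within-cell contrasts, which cancel the
  shared bias, rather than absolute tau values.
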