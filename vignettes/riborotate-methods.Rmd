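---
title: "Methods: reactivity discretization, rotation scoring and companion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactivity discretization, rotation scoring and companion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riborotate)
```

## The problem

During translation elongation the 80S ribosome transits between two extreme
conformations, the classical (non-rotated) and the ratcheted (rotated)
state. Where a given ribosome population sits on this continuum can be read
out chemically: flexible, solvent-accessible nucleotides react with probing
reagents such as 1M7 (SHAPE chemistry, 2'-OH acylation) or kethoxal
(unpaired G), and a small set of landmark bases in the intersubunit bridges
(B7a, B2a), the aa-tRNA accommodation corridor (AC) and the sarcin-ricin
loop (SRL) change accessibility characteristically upon rotation. The B3
bridge is the pivot of rotation and does not change; its bases serve as an
internal control.

`riborotate` implements the quantitative chain from integrated
capillary-electrophoresis peak areas to a position on the rotational
continuum, together with the companion biochemical analyses used to
corroborate such assignments: equilibrium ligand binding under ligand
depletion, single-turnover peptidyltransfer kinetics, and dual-luciferase
translational-fidelity statistics. Because raw traces for these experiments
are not publicly deposited, the package ships a synthetic-data generator
with known ground truth; every analysis is exercised end-to-end against it.

## Reactivity pipeline

The pipeline is three steps, each a pure function of its input table.

**Control subtraction.** `net_reactivity()` computes
`net = plus_area - minus_area`, floored at zero: a base cannot be
negatively reactive, and positions where the reagent-free control exceeds
the treated channel are read as unreactive.

**Region-median normalization.** Each primer region is normalized by the
median of its *strictly positive* net values
(`normalize_by_region_median()`). Zero-floored positions are excluded from
the normalizer because they would deflate it and inflate every other
reactivity; they remain in the trace. `include_zeros = TRUE` flips to the
plain median for comparison. The per-trace summary statistics that drive
discretization -- median, mean and sample SD (n−1; the traces are finite
samples) -- are computed over *all* positions of the normalized trace,
landmarks included, and stored with it.

**Five-level discretization.** `discretize()` assigns integer codes from
the trace's own statistics: 0 below the median, 1 from the median to the
mean, 2 from the mean to one SD above it, 3 from one to two SDs above the
mean, and 4 beyond. Two conventions make this a total, deterministic
function:

* *Boundary ties.* Bins are lower-inclusive: a value exactly equal to a
  threshold takes the higher code.
* *Degenerate thresholds.* The rule presumes right-skewed data
  (median < mean). If a trace is left-skewed or constant, thresholds can
  invert or coincide; affected bins then collapse into the lower code (with
  a warning), so a constant trace codes uniformly as 1 and no input errors
  out.

Because every threshold is a statistic of the trace itself, the codes are
invariant under rescaling of the raw areas; whether discretization is
applied before or after median normalization is therefore immaterial, and
the package applies it after.

```{r}
net <- tibble::tibble(position = 1:6, net = c(0.1, 0.2, 0.3, 0.4, 1.0, 2.5))
trace <- normalize_by_region_median(net, "demo")
discretize(trace)$code
```

## Rotation scoring

`landmark_panel()` packages the 15 landmark bases with their reference
codes in the non-rotated and rotated control complexes. Eleven bases are
*informative*: they are not B3 controls and their reference codes differ
between the end states. For each informative base the observed code is
mapped to a clipped normalized position

\[
p_i = \mathrm{clip}\!\left(\frac{c_i - r_i^{NR}}{r_i^{R} - r_i^{NR}},\ 0,\ 1\right),
\]

and the **rotation score** is the mean of the \(p_i\) over available bases.
The formula is this package's construction -- the underlying experiments
establish the ordering of states qualitatively -- chosen as the simplest
statistic that is exactly 0/1-calibrated on the reference columns
themselves. Direction handling is automatic: bases that are *more* reactive
in the non-rotated state (the AC gate bases and the SRL) invert with their
reference codes, so no special-casing is needed. Bases whose reference
codes coincide carry no information and are excluded; B3 bases are excluded
by policy and used only by `b3_control_check()`, which passes when every B3
base deviates from its non-rotated reference by at most one level.
`classify_rotation()` labels scores below 1/3 non-rotated-shifted, above
2/3 rotated-shifted, otherwise intermediate; the thresholds are plain
arguments.

`difference_map()` subtracts two normalized traces position-wise and bins
each difference in SD steps, `bin = sign(δ)·min(4, floor(|δ|/σ))`, for
coloring secondary-structure diagrams. The SD unit σ defaults to the pooled
sample SD of the two traces; since it is not obvious whose SD "one standard
deviation" steps should use, a per-trace alternative sits behind the
`sigma` argument. The map is antisymmetric under operand swap by
construction.

## Synthetic traces

`simulate_peak_table()` emulates one primer region. Design choices:

* **Background distribution.** Net reactivities are log-normal
  (`background_log_mean = -1`, `background_log_sd = 1`). Empirical SHAPE
  reactivity distributions are right-skewed; log-normality is an
  *assumption* (the source electropherograms are not available to check),
  but it guarantees median < mean, which is exactly the condition for all
  five code bins to be realizable. A generation-time check warns if a
  realized background violates the skew.
* **Landmark placement.** Each targeted base is set to the midpoint of its
  intended code's bin, computed from the realized trace statistics *with
  the landmarks included* (per-trace statistics make no exclusions).
  Placement perturbs those statistics, so the generator verifies the codes
  after recomputation and re-places once before erroring. The invariant
  `landmarks ≤ 0.1 × n_positions` keeps the perturbation weak. With the
  packaged profiles and defaults, the full pipeline recovers 100% of
  intended codes deterministically at any seed.
* **Control channel.** Simulated as multiplicative noise around 5% of the
  background mean; the real reagent-free controls are subtracted but not
  otherwise characterized, so a low flat level is the neutral choice.
* **Vacant wild type.** The observed states provide codes for the two
  controls and two mutants only; vacant wild-type ribosomes show
  intermediate reactivities but no full panel of codes. The packaged vacant
  profile interpolates each base as the rounded midpoint of the two
  reference codes, half-integer ties rounded toward the non-rotated code
  (the conservative direction). It is synthetic by construction and
  labelled as such.

The five packaged profiles yield, through the full pipeline, scores of 0,
5/33, 3/11, 10/11 and 1 -- reproducing the continuum ordering non-rotated <
A106R < vacant < S104D < rotated:

```{r}
simulate_cohort(seed = 1)[, c("state", "score", "classification")]
```

What passing this shows, and what it does not: the pipeline is
self-consistent (codes in, codes out) and the score behaves monotonically;
it does not show that real electropherograms are log-normal, that real
landmark reactivities sit at bin midpoints, or anything about trace
alignment and signal decay, which are upstream of this package's inputs.

## Ligand binding with depletion

In filter-binding assays the bound ligand is a sizeable fraction of the
total, so the hyperbolic approximation fails. With total capacity
\(B_{max}\), total ligand \(L\) and dissociation constant \(K_d\) (all in
pmol per fixed reaction volume, matching how such assays are reported;
a volume converts to molar if needed), the bound amount is the smaller
root of \((B_{max}-B)(L-B)/B = K_d\):

\[
B = \frac{S - \sqrt{S^2 - 4B_{max}L}}{2},\qquad S = B_{max}+L+K_d .
\]

`bound_closed_form()` evaluates the rationalized form
\(2B_{max}L/(S+\sqrt{S^2-4B_{max}L})\), which avoids catastrophic
cancellation in the stoichiometric limit \(K_d \to 0\); it agrees with a
numeric equilibrium root to 1e−9 over six decades of each parameter.

`fit_binding()` fits this curve by Levenberg-Marquardt least squares
(`minpack.lm`), in bound-measured mode or unbound-measured mode (signal =
total − bound, as when unbound factor is what is counted). Depletion
likelihoods are shallow at low doses, so the fit is multistarted (Kd from
the dose-range minimum, geometric mean and maximum × Bmax at 1 and 1.5
times the largest observed bound value) and the best RSS wins. Replicates
are fitted jointly rather than dose-averaged, preserving the error
structure behind the Jacobian-based standard errors. Stoichiometry is fixed
at one site (the Scatchard analyses support a single site); the
`stoichiometry` knob exists but defaults locked. Non-convergence and
boundary-pinned parameters warn rather than error, and are flagged in the
result.

The default simulated dose series is eight 2-fold serial dilutions of a
62.5 pmol top dose (62.5 down to ≈0.5 pmol) against 5 pmol of ribosomes --
the serial-dilution design of the emulated assays -- with CV-5%
multiplicative log-normal noise (scintillation counting is
heteroscedastic; kinetics noise, by contrast, is small additive Gaussian).
Absolute Kd values are not printed in the source experiments, only
fold-changes; the wild-type truth of 4 pmol (Bmax 5 pmol) is a documented
stand-in at realistic occupancy, and the recovery experiments measure
*ratios*, which are insensitive to it.

`scatchard()` is the classical OLS of bound/free on bound (slope −1/Kd,
x-intercept Bmax), excluding saturated points with free ≤ 0 with a
warning. `competition_profile()` decides stimulation/inhibition by a
distribution-free Spearman trend test at α = 0.05 (the emulated experiments
report direction, not a mechanism) and fits a four-parameter logistic for
the half-effect dose when a trend spans at least a two-fold range.

## Kinetics and fidelity

`fit_single_turnover()` fits \(P(t) = A(1-e^{-k_{app}t})\) with zero
intercept: single-turnover design justifies the minimal model (no burst, no
offset); an offset term sits behind `offset = TRUE`. A warning fires when
`max(t)·kapp < 2`, where rate and amplitude become collinear.
`relative_activity()` reports `100·kapp_mut/kapp_wt` with first-order
error propagation; an initial-slope variant (`kapp·A` ratio) is available
by argument.

`recoding_percent()` uses the ratio-of-means convention,
`100·mean(F/R)_test / mean(F/R)_control`: replicates are independent
cultures, not paired wells, so averaging before the ratio is the
appropriate default; a paired mean-of-ratios variant is available.  The SEM
propagates the two means' SEMs on the ratio scale and then rescales --
whether uncertainty should be propagated on ratios or percentages is
conventionally ambiguous, and this is the choice documented here.
`compare_strains()` applies the pooled-variance two-sample Student's t-test
(two-sided) on per-replicate recoding values, Welch by flag; no
multiple-testing correction is applied by default since per-reporter
p-values are reported individually (Holm is one `p.adjust()` away on the
output).

## Problem sizes and reproducibility

Every generator is a pure function of an integer seed. The recovery
studies (`kd_ratio_study()`, `relative_activity_study()`) use 100 simulated
assay pairs at the design points above -- large enough that the median
fitted fold-change is stable to a few percent, small enough to run in
seconds on one core; the property suites use 1,000 random traces for the
discretization oracle and a 343-point grid for the equilibrium root. The
`run_pipeline()` bundle stamps every written artifact with the package
version, seed and configuration hash, so any output can be regenerated from
its header.

## Known limitations

* Everything upstream of integrated peak areas (trace alignment, mobility
  shift, signal-decay correction) is out of scope; the pipeline trusts its
  input tables.
* The generator models one trace per region; replicate-averaged reactivity
  codes, and error models across replicates, are not implemented.
* The rotation score treats informative bases as exchangeable; it does not
  weight by bridge, reagent or measurement confidence.
* Binding analyses assume a single site class at equilibrium; kinetic
  (on/off-rate) and cooperative models are out of scope.
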