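---
title: "Models and methods behind synaptoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoquant)
```

# Scope

synaptoquant quantifies ROI-level fluorescence time series from three
genetically encoded sensors — synaptopHluorin (vesicle exocytosis and
lumenal pH), iGluSnFR (released glutamate) and GCaMP (neuronal calcium) —
and worm-tracking / chemotaxis data from CO₂-avoidance behavior assays.
It starts at extracted traces and track tables: ROI selection, image
registration and worm segmentation are upstream of this package.

# The pHluorin calibration model

## Physics

Superecliptic pHluorin is a pH-sensitive GFP whose fluorescent
(deprotonated) fraction follows a titration curve with apparent
`pK = 7.18`:

$$f(\mathrm{pH}) = \frac{1}{1 + 10^{pK - \mathrm{pH}}}.$$

A punctum's probe population splits into a surface fraction SF exposed
to the external solution (pH 7.2) and a vesicular fraction `1 − SF` at
the resting lumenal pH. Two calibration manoeuvres give two independent
constraints:

* **NH₄Cl** (40 s pulse) equilibrates the vesicle lumen with the
  external pH; the fractional fluorescence increase is γ.
* **MES** (60 s acidic pulse, pH 5.5) quenches the surface-exposed
  probe; the fractional decrease is ε.

Writing `A(pH)` and `C(pH)` for the protonation terms (see the README or
`?sf_from_gamma`), each measurement expresses SF as a function of the
candidate lumenal pH:

$$\mathrm{SF}_\gamma(\mathrm{pH}) = \frac{A - \gamma}{A(\gamma + 1)},
\qquad
\mathrm{SF}_\varepsilon(\mathrm{pH}) =
  \frac{\varepsilon}{1 - C + (1 - \varepsilon) A}.$$

The punctum's `(pH, SF)` is the intersection of the two curves. The
forward map `forward_calibration()` is the exact algebraic inverse of
both branches (`γ = A(1−SF)/(1+A·SF)`, `ε = SF(1−C+A)/(1+SF·A)`), which
the test suite exploits for round-trip checks: over the grid
pH ∈ [5.2, 7.0] × SF ∈ [0.05, 0.9] the solver recovers the generating
values to better than 10⁻⁴.

## The pK discrepancy

The source material for this model states the probe's pK both as 7.18
(calibration equations) and as 6.18 (in the exocytosis-factor
paragraph). Direct evaluation settles the question: only pK = 7.18
reproduces the published adjustment factors (1.145 → printed 1.15, and
0.975 → printed 0.98), while pK = 6.18 gives 1.27. The package therefore
uses pK = 7.18 in every equation, treats 6.18 as a typographical slip,
and records the choice in the pipeline run log so analyses stay
auditable. `ph_constants(pK = ...)` overrides it.

## Solver numerics

`solve_ph_sf()` evaluates
`SF_γ(pH) − SF_ε(pH)` on a 10⁻³-pH grid across the bracket (default
4.5 to 7.2 − 10⁻⁶), refines every sign change by bisection
(`uniroot`, pH tolerance 10⁻¹²), and discards crossings whose residual
does not vanish — those are the MES branch's pole, not intersections.
If several genuine intersections remain, the smallest-residual root is
returned with a warning; the model is expected to have a unique
intersection for physiological inputs. A solution is `converged` when
its residual `|SF_γ − SF_ε|` is below `tol` (default 10⁻⁹).

The bracket deliberately extends below the dynamic-range floor: a
punctum whose intersection lies at pH < 5.0 is *solved* and then flagged
`excluded` (`below_dynamic_range`) rather than failing silently, which
mirrors how out-of-range puncta are counted and reported in practice.
Inputs admitting no intersection at all (e.g. a negative γ, impossible
for a vesicle more acidic than the bath) return `no_intersection`.

## The exocytosis correction δ

A fusion event raises one vesicle's lumen from its resting pH to 7.2;
the resulting fractional signal δ (see `?delta_factor`) is strictly
decreasing in the resting pH: alkaline vesicles "use up" part of their
dynamic range at rest. To compare evoked responses across genotypes
whose resting pH differs, mutant signals are multiplied by
`δ(pH_ref, SF_mut) / δ(pH_mut, SF_mut)`.

Both factors use the *mutant's* surface fraction; only the resting pH is
swapped. The defining prose of the correction ("everything else stays
the same, the resting pH shifts to the reference") is ambiguous about
which SF enters the numerator; among the four candidate pairings, this
is the only one that reproduces both published factors, so it is the one
implemented. Evaluating at the published genotype means:

```{r}
delta_ratio(6.22, 6.33, 0.310)  # alkaline mutant, published as 1.15
delta_ratio(6.22, 6.20, 0.239)  # acidic mutant, published as 0.98
```

The second ratio computes to 0.975 from the printed (rounded) means; the
0.005 residual against the printed 0.98 is consistent with the original
factors having been computed from unrounded means. The vesicle-count
assumption is inherited as stated — the correction presumes genotypes do
not differ in the number of fusing vesicles — and is documented, not
modelled.

# Trace quantification rules

All trace windows are **half-open** `[start, end)` in seconds, so
adjacent windows (baseline 0–10 s, stimulus 10–20 s) partition samples
without double counting; endpoint handling is not specified by the
source conventions, and half-open is the self-consistent choice. The
behavior module instead uses closed windows (see below).

* **ΔF/F**: per-sample background subtraction first, then
  `(F′ − F₀)/F₀` with F₀ the baseline-window mean. A non-positive F₀ is
  a degenerate baseline and errors out rather than producing signed
  nonsense.
* **Moving average**: centered boxcar; the tap count is
  `floor(width/dt)` forced odd so the filter is symmetric, shrinking at
  the trace edges. Three widths matter: 1 s for responder gating, 0.5 s
  for calcium pre-stimulus screening, 5 s for calibration amplitudes
  (γ, ε), where high-frequency noise would otherwise bias a max/min
  estimator upward.
* **SD** is always the sample standard deviation (n − 1).
* **Responder rule**: smoothed response-window extremum against smoothed
  baseline `mean ± 3 SD`. The SD is taken from the *filtered* trace —
  the filter is stated as part of the rule, and applying it consistently
  to both threshold and signal keeps the rule scale-free. The acid
  (MES) direction mirrors the rule with the sign flipped.
* **Background gate**: a trace is excluded when its baseline mean is
  `≤ mean + 3 SD` of the background ROI — equality excludes, matching
  the exclusion inequality as stated.
* **Baseline mode**: for calcium traces the baseline is the *mode*
  (histogram bin of width 0.01 ΔF/F, ties to the lowest bin), because a
  pre-stimulus movement transient inflates mean and SD but not the mode.
  The same reasoning pools the SD across a genotype's recordings (mean
  of per-trace smoothed baseline SDs) before applying the
  `mode + 5 SD` exclusion.
* **AUC** uses the trapezoid rule on the raw, unfiltered ΔF/F:
  quantification and classification deliberately see different versions
  of the trace. Note that a half-open window `[10, 20)` spans 9.9 s of
  samples at 0.1 s; to integrate a full 10 s the window must include the
  closing sample (e.g. `[10, 20.05)`).

## The realized false-positive rate of the 3-SD rule

The 3-SD responder rule is *not* a 0.13% test. The maximum is taken over
~100 smoothed (hence correlated) samples, and the baseline SD is
estimated from only ~11 effectively independent samples, so the realized
null responder rate is in the 10–20% range. The acceptance test measures
the rule's nominal rate by Monte Carlo with an independent naive
re-implementation on white noise and checks the package agrees —  it
does not pretend the rule is tighter than it is.

# Behavior kinematics

* Speeds are Euclidean displacements over one sampling step, assigned to
  the later sample, scaled by 32.607 µm/px (derived from the stated
  equivalence 1.17 px/s = 38.15 µm/s; configurable).
* Headings are displacement-vector angles; zero-displacement steps
  (pauses) inherit the previous heading; changes are wrapped to
  [0°, 180°] and divided by the step duration. High-angle turns are
  `≥ 50°/s`, inclusive at the boundary.
* Track QC keeps tracks lasting ≥ 30 s with **mean** speed
  ≥ 1.17 px/s. Reading the criterion as a minimum *instantaneous* speed
  would discard nearly every real worm, since worms pause; the
  mean-speed reading is logged by the pipeline as an interpretation
  flag.
* Quantification windows are closed `[t* − 15, t* + 17]` s around the
  population-series extremum within a stimulus window (ties to the
  earliest point); a track must span the whole window to contribute, and
  per-sample inclusion is closed at both ends. The asymmetric ±15/+17
  geometry is taken verbatim from the protocol this package implements.
* Turn events are per-sample flags at the track's sampling rate; no
  debouncing of consecutive flagged samples is applied, as only the
  instantaneous criterion is defined.
* Population statistics use QC-filtered tracks only, matched to the
  requested time grid within half a grid step.

# Group statistics

`kruskal_dunn()` delegates the omnibus H (tie-corrected) to
`stats::kruskal.test` and implements Dunn's pairwise z-statistics with
the standard tie correction. The p-adjustment is Bonferroni over the
*requested* comparisons (two-sided); the adjustment family is otherwise
unspecified in the protocols this mirrors, and Bonferroni is the
conservative default. With every observation identical the statistic is
defined as H = 0, p = 1 (the tie correction is formally 0/0 there).
`anova_dunnett()` uses `stats::aov` and multcomp's single-step Dunnett
adjustment. The test suite cross-checks Dunn against an exact
permutation enumeration at small n, and Dunnett's single-contrast limit
against the pooled-variance t-test.

# Synthetic data: what it emulates and what it does not

The generators provide every pipeline input with known ground truth:

* `gen_calibration_experiment()` — raw-F traces whose ΔF/F plateaus are
  the forward model's γ and −ε at the requested (pH, SF), approached
  with first-order kinetics (τ = 1 s by default; the plateau-based
  estimators are insensitive to the exact kinetics) plus i.i.d. Gaussian
  noise, default SD 0.02 ΔF/F — chosen to make 3-SD gating nontrivial.
  The NH₄Cl (20–60 s) and MES (80–140 s) pulses share one trace for
  convenience; real calibrations are separate recordings, which is why
  all measurement windows are arguments.
* `gen_response_trace()` — evoked-response ΔF/F traces with optional
  Gaussian pre-stimulus transients for exercising the calcium artifact
  gate.
* `gen_tracks()` — correlated random walks: per-step speeds around the
  active regime's target, diffusing headings, Poisson turn events with
  ≥ 60° jumps, staggered starts/ends to exercise spanning rules, and a
  per-worm speed offset (SD 10 µm/s) reflecting genuine between-animal
  variability. During the stimulus the speed target follows a shallow
  quadratic bowl (+15 µm/s at the window edges relative to the 60 µm/s
  center) so the population minimum is identifiable mid-window; a flat
  profile would let sampling noise place the extremum at the stimulus
  boundary, where the asymmetric quantification window would straddle
  the regime switch.
* `gen_chemotaxis_counts()` — binomial per-trial counts with expected
  AI = 2·p_air − 1.

Every generator is deterministic given its seed and restores the
caller's RNG state. What passing tests show: the estimators, gates,
solver and window logic implement their definitions correctly, and
parameter recovery works at realistic noise levels. What they do not
show: robustness to bleaching and drift, correlated (non-white) noise,
perfusion artifacts, tracker identity switches or collisions — none of
which the generators emulate.

# Test design notes

* Problem sizes: the solver round-trip grid is 37 × 18 (pH × SF); the
  responder Monte Carlo uses 200 seeded traces per condition and a
  400-trace oracle; kinematics recovery uses cohorts of 50 tracks over
  240 s at 1 Hz; the rank-test type-I check uses 5 000 simulated
  datasets (3 × 15 observations). The full suite runs in well under a
  minute.
* The "population mean within 2 SE of the generating value" property is
  itself a stochastic event that fails for roughly one cohort in twenty
  by construction (it is a ~95% coverage interval, and the between-worm
  offset mean fluctuates on exactly the SE scale). The suite therefore
  evaluates it over five independent cohorts and requires a majority to
  pass — a binomial test of the coverage property that is reliable under
  any fixed seed — rather than hoping a single cohort lands inside its
  own interval.
* Calibration examples were verified with independent hand evaluations
  (A = 4.39640 and C = 0.21591 at pH 6.2) frozen into the tests, and
  smoothing against a naive per-sample boxcar oracle.

# Known limitations

* The solver assumes a unique curve intersection; heavily corrupted
  (γ, ε) pairs can in principle produce multiple intersections, which
  are reported with a warning rather than resolved.
* γ has no imposed upper bound; near-background baselines can inflate
  it, and only the upstream responder/background gates defend against
  that, as in the protocol.
* Vesicular acidification biophysics (pump/counterion models) and pK
  estimation from data are out of scope; the pK is a constant.
* The behavior module trusts the tracker's identity assignments; it
  performs no collision resolution or posture analysis.
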