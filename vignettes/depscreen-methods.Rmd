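---
title: "Methods: modelling and classifying DEP spectra"
author: "depscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling and classifying DEP spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscreen)
```

## The forward model

A cell in a dielectrophoresis (DEP) experiment is idealised as a
single-shell sphere: a homogeneous conductive cytoplasm wrapped in a thin,
poorly conducting membrane. Rather than carrying an unmeasurable membrane
thickness, the membrane is parameterised by its specific (per-area)
capacitance $C_m$ (F/m²) and conductance $G_m$ (S/m²) — the quantities DEP
experiments actually resolve. Writing the membrane's complex specific
capacitance $C_m^* = C_m - jG_m/\omega$ and the cytoplasm's absolute
complex permittivity
$\varepsilon^*_{cyt} = \varepsilon_0\varepsilon_{cyt} - j\sigma_{cyt}/\omega$,
the thin-shell limit of the shelled-sphere mixing formula collapses the
cell to an equivalent homogeneous sphere:

$$\varepsilon^*_{eff} = \frac{r\,C_m^*\,\varepsilon^*_{cyt}}
{r\,C_m^* + \varepsilon^*_{cyt}}.$$

This is a series combination: at low frequency with an insulating membrane
it reduces to the whole-cell capacitance $rC_m$, at high frequency the
membrane becomes transparent and the cytoplasm shows through. The measured
response is proportional to the real part of the Clausius–Mossotti factor
against the suspending medium,
$Re[(\varepsilon^*_{eff}-\varepsilon^*_{med})/(\varepsilon^*_{eff}+2\varepsilon^*_{med})]$,
bounded in $[-0.5, 1]$ for any sphere. The test suite checks the thin-shell
formula against an independent finite-thickness two-layer computation
(membrane thickness 5–10 nm, radius ≥ 5 µm); the two agree to well under
1% because the neglected terms are $O(d/r) \sim 10^{-3}$.

**Assumptions.** One shell only (no nucleus or organelles), no membrane
permittivity dispersion beyond $G_m$ (not identifiable from a 20-point
real-part spectrum), spherical cells, dilute suspension (no
particle–particle interaction), and $\varepsilon_0 = 8.854\times10^{-12}$
F/m with all frequencies in Hz (angular conversion internal).

### Crossover frequency

`crossoverFrequency()` scans the requested band on a 400-point log grid
from the low end, takes the first sign-change interval and refines it by
bisection (`uniroot`) to a relative tolerance of $10^{-6}$. If further
sign changes exist, the lowest-frequency root is returned and flagged
(`multiple = TRUE`); if none exist the result says so rather than
throwing. In the regime $G_m = 0$ and $\sigma_{cyt} \gg \sigma_{med}$ the
root agrees with the closed form
$f_{xo} = \sqrt{2}\,\sigma_{med}/(2\pi r C_m)$ to a few percent; at
$\sigma_{cyt}$ only ~6× the medium conductivity the closed form itself is
~5% off the true root, which is why the closed-form comparisons in the
tests use a strongly conductive cytoplasm (1.0 S/m).

### Parameter fitting

`fitShellParams()` minimises the sum of squared residuals between an
observed spectrum and $g\cdot Re[CM](f;\theta)$ with Levenberg–Marquardt
(`minpack.lm::nls.lm`, `ftol = ptol = 1e-12`, 200 iterations max). Free
parameters are log-transformed, which enforces positivity without box
constraints and makes steps multiplicative — natural for quantities
spanning decades. The instrument gain $g$ is fixed at 1 unless explicitly
freed: gain and the overall spectrum scale are nearly confounded, so
absolute calibration is not attempted. Masked points are dropped before
fitting; non-convergence is returned as a flag and warning, never
silently. On noise-free 20-point spectra the fit inverts the forward model
to optimizer tolerance from initialisations 2× off in every free
parameter; under additive noise of SD 0.05 the median relative error of
the recovered membrane capacitance is about 5% (100 replicates in the
acceptance script).

## The synthetic cohort generator

The generator emulates the structure of a small two-arm voided-urine
screening study measured on a 20-well DEP cytometer, so the whole pipeline
is testable without any data download. Defaults, all overridable through
`cohortConfig()`:

| quantity | default | rationale |
|---|---|---|
| samples | 8 cancer + 8 control | pilot-study arm sizes |
| technical repeats | 3–5, uniform | "at least three, four or five if cells sufficed" |
| grid | 20 log-spaced points, 10 kHz–45 MHz | the cytometer's sweep |
| arm parameters | see below | two-state contrast |
| between-participant CV | 0.15, log-normal | positivity-preserving; magnitude a design choice |
| noise | iid Gaussian, SD 0.05 per point per repeat | simplest model consistent with visibly noisy spectra |
| dead wells | 1 per cohort, fixed position | a single faulty instrument connection |
| low-cell samples | 3, cancer arm | voided urine yields few cells; the study's main failure mode |
| gain | 2 | see below |

Arm centres: control $r=10\,\mu m$, $C_m = 0.01$ F/m², $G_m = 2000$ S/m²,
$\varepsilon_{cyt} = 60$, $\sigma_{cyt} = 0.25$ S/m; cancer identical
except $G_m = 200$ S/m² and $\sigma_{cyt} = 0.5$ S/m; medium
$\varepsilon = 78$, $\sigma = 0.043$ S/m. The contrast is carried entirely
by membrane conductance (low-frequency behaviour) and cytoplasm
conductivity (high-frequency behaviour): cancer-like spectra are more
negative below the crossover and more positive above ~100 kHz.

**The gain.** A well-plate DEP cytometer records a light-intensity change
proportional to $Re[CM]$ with an instrument-dependent scale. The package
uses a default gain of 2 so that simulated spectra live on the scale the
published instrument-unit constants assume: at that scale a normal
sample's spectrum SD across frequencies is ≈ 0.5–0.9 while a low-cell
(noise-only) sample's is ≈ the noise SD, so the conventional exclusion
cutoff of 0.4 separates the two populations cleanly. At gain 1 a noise-free
healthy spectrum has SD ≈ 0.32 and the same cutoff would reject healthy
samples — i.e. the cutoff is meaningful only on the instrument's scale.

**Artefacts.** A dead connection is an instrument fault at a fixed well:
its near-zero values (Gaussian, SD = noise/10) appear at the same
frequency in every sample and repeat. A per-sample per-point probabilistic
mode (`deadPointProb`) exists for stress-testing the detector. Low-cell
samples replace the underlying curve by zero for the whole sample — noise
without a DEP spectrum — and are drawn as a fixed per-arm count (default 3
cancer-arm) plus an optional per-sample probability.

**What the generator does not emulate:** mixed cell populations within a
sample (e.g. squamous contamination), correlated noise between repeats
sharing a well-plate loading, sex- or age-dependent effects, drift within
an acquisition. Passing tests on synthetic cohorts therefore demonstrate
the pipeline's correctness and its behaviour under the modelled artefact
types, not clinical performance on real urine samples.

## Spectrum processing

Technical repeats are collapsed to a per-frequency median (even counts:
midpoint of the central pair) — robust against single-repeat outliers.
Dead points are detected on the median spectrum by a magnitude rule: a
point is flagged when its absolute value is below `deadThreshold`
(default 0.05) while the spectrum's overall median absolute value is at
least twice that, i.e. a near-zero outlier relative to a real curve. A
uniformly near-zero spectrum is deliberately left unflagged — whole-sample
quality is the exclusion filter's job. Masking never alters stored
values.

Because a DEP spectrum genuinely passes through zero at its crossover
frequencies, a magnitude-only rule will occasionally flag
crossover-adjacent grid points too. `maskDeadPoints()` therefore caps
masking at `maxMasked = 2` points per sample, keeping the candidates with
the smallest absolute values (true dead connections sit an order of
magnitude closer to zero than crossover-adjacent points). The cap
guarantees the 9+9-point band statistic below always has the 18 valid
points it needs on a 20-point grid; masking a point whose value is near
zero anyway moves the band means negligibly. The rolling average
(window 2, consecutive valid points, $n-1$ output points) exists for
plotting trendlines only and never feeds the statistic. Arm averages are
means over per-sample medians, omitting masked points per frequency.

## The MDV statistic and exclusion filter

For each sample the Mean Difference Value is

$$\mathrm{MDV} = \underbrace{\mathrm{mean}(\text{9 lowest-frequency valid
points})}_{\text{low band}} -
\underbrace{\mathrm{mean}(\text{9 highest-frequency valid
points})}_{\text{high band}},$$

and a sample is called cancerous when MDV is strictly below the threshold.
Design choices, each a config switch:

- **Sign convention** `low_minus_high`: the only orientation under which
  "call cancer when MDV is below the threshold" assigns the arm with the
  more negative low band and more positive high band to the smaller MDV.
- **Band selection** `by_frequency` (default): "lowest 9 points" is read
  positionally, since the bands sit below and above the crossover; a
  `by_value` mode (9 smallest / 9 largest values) is provided because the
  phrase is genuinely ambiguous.
- **Exclusion**: a sample is excluded when its spectrum SD (sample SD,
  $n-1$ denominator, valid points only) is *strictly below* `sdMin`
  (default 0.4). Low cell counts collapse the wide low/high plateaux and
  hence this SD.
- **Threshold**: default 0.65, the conventional instrument-unit
  discriminator. On raw $Re[CM]$-scale simulations the MDV of every
  sample is negative, so `runFullAnalysis(thresholdMode = "sweep")`
  calibrates the threshold at the Youden optimum of the unfiltered cohort
  and applies the same value to both passes; the sign and scale that make
  0.65 optimal on a particular instrument cannot be recovered without
  that instrument's raw data.

Fewer than 18 valid points is a domain error naming the sample; the
pipeline propagates it rather than silently shrinking bands.

## Diagnostics

Cancer is the positive class throughout; excluded samples are counted
separately and never enter the confusion matrix. The between-arm test on
MDVs is the classic pooled-variance Student t-test (two-tailed), with
Welch as an option; the degenerate all-constant case returns $t = 0$,
$p = 1$. The threshold sweep evaluates sensitivity/specificity on the
candidate grid of midpoints between consecutive sorted MDVs (plus one
point beyond each extreme — the operating point is a step function that
changes only at observed values), maximises the Youden index
$J = se + sp - 1$, and reports both the optimal threshold (midpoint of the
tying interval; with several tying intervals, the widest, first on ties)
and the full interval, since any threshold inside it performs
identically. The sweep is calibration on the same data, not validated
inference: no confidence intervals, multiple-testing control or
cross-validation are attempted, and reported operating characteristics
are optimistic in the way all resubstitution estimates are.

`runFullAnalysis()` runs processing → MDV → classification → diagnostics
twice, with the exclusion filter off and on, reporting both — the
pre-/post-exclusion comparison is the scientifically interesting
quantity, since it shows how much performance is lost to low-cell samples
rather than to the statistic itself.

## Problem sizes and determinism

The test suite and acceptance script use 16-sample cohorts (the study
structure) and replicate counts of 40–100 seeds for distributional
properties, 100 fits for noisy parameter recovery, and 50 cohorts for
pipeline operating characteristics; these sizes give stable Monte-Carlo
estimates while keeping a full run in tens of seconds. All randomness
flows from a single integer seed; `simulateCohort()` restores the caller's
RNG state, and identical config + seed reproduce byte-identical cohort
files and analysis reports.

## Known limitations

- The single-shell model cannot represent nucleated-cell dispersions or
  electrorotation spectra; fits to real spectra absorb such structure
  into biased shell parameters.
- Gain and spectrum scale are confounded; all MDV thresholds are
  instrument-scale quantities and must be recalibrated per instrument.
- The dead-point rule is magnitude-based and cannot distinguish a dead
  connection at a crossover-adjacent well from the curve itself (harmless
  for the band means, but the flag is not trustworthy there).
- Diagnostic numbers from 8+8-sample cohorts carry large sampling
  variance; the package reports them without uncertainty intervals.
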