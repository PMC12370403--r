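---
title: "Model-based diagnostic reference levels for mammography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based diagnostic reference levels for mammography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammodrl)
```

## The problem

Mammography screening delivers ionizing radiation to one of the most
radiosensitive tissues in the body, so national programs monitor the
average glandular dose (AGD) each facility delivers. The standard
monitoring instrument is the diagnostic reference level (DRL): the 75th
percentile of the distribution of per-facility *median* AGD. A facility
whose median dose sits above the national DRL investigates its technique.

AGD rises steeply with compressed breast thickness (CBT), so a single DRL
is only meaningful at a stated thickness. Three reporting conventions are
in use, and `mammodrl` implements all three on the same estimator core:

1. **Typical-window ("simplest") DRL** — one number computed from breasts
   in a single window, conventionally 50 ± 5 mm
   (`simplest_drl()`).
2. **Range-based DRL** — one DRL per 10-mm CBT bin from 20 to 100 mm
   (`binned_drl_table()`).
3. **Continuous DRL curve** — the per-bin DRLs at their bin centers are
   fitted with a parametric model of DRL versus CBT, yielding a reference
   value at *any* thickness (`fit_all()`, `evaluate_curve()`). Model
   families: linear `a + b t`, one/two-term power `a t^b (+ c)`, and
   mono/bi-exponential `a e^{bt} (+ c e^{dt})`. The bi-exponential is
   reported in time-constant form `a e^{t/τ₁} + c e^{t/τ₂}`.

The continuous form matters operationally: it serves patients far from any
bin center, supports comparison against guideline acceptable/achievable
limit curves (which are themselves continuous in thickness), and could be
consumed directly by an automatic exposure control system.

## Estimator conventions

Several conventions materially affect a DRL computed from only a handful
of centers; each is explicit, configurable, and recorded in every
serialized output and in the pipeline manifest.

* **Percentile convention.** `drl_percentile()` defaults to linear
  interpolation between closest ranks (type 7, the common
  scientific-software default); a nearest-rank alternative is available.
  With nine centers the 75th percentile under type 7 is exactly the 7th
  order statistic of the center medians.
* **Binning.** Bins are half-open `[b, b+10)` with the last bin closed at
  100 mm, so a breast of exactly 50 mm falls in the 50–60 bin and 100 mm
  is retained. The representative thickness for fitting is the nominal
  integer midpoint (25, 35, …, 95 mm); the per-bin mean CBT is available
  as an alternative. Sparse edge bins can be merged
  (`bin_scheme(merge_edges=)`), the standard mitigation when extreme
  thicknesses are rare.
* **Laterality.** Left and right views are pooled per projection (CC,
  MLO), as dose surveys conventionally do.
* **Median confidence intervals.** Per-bin 95% CIs for the pooled median
  AGD use the distribution-free order-statistic (binomial-rank) method:
  exact, deterministic, and assumption-free. Below n = 6 no nondegenerate
  95% interval exists and the full data range is returned with a
  `small_n` flag. A bootstrap cross-check appears in the test suite, not
  in the estimator.

## Exclusion rules

`apply_exclusions()` removes, at the examination level (all four views go
together), exams with: compression force of 0 N or above 200 N; tube
loading in [0, 10) mAs; 0 kVp; CBT above 100 mm; or a breast implant.
Non-standard projections (anything but CC/MLO) are dropped record-wise
first. Boundary choices — 10 mAs itself kept, 100 mm itself kept, 200 N
itself kept — follow the plausible reading of survey practice (reported
center minima of exactly 11 mAs and CBT ranges ending exactly at 100 mm);
all thresholds are configurable. Implant exclusion is a defensible default
rather than a universal rule, so it has its own switch. Every removal is
attributed to the *first* rule that triggered, in fixed order, which makes
the report an exact account: `n_out = n_in − Σ removed`.

## Fitting policy

Nonlinear families are fitted by Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`), a trust-region-radius scheme. Reproducibility
requires an explicit starting-value policy, so `fit_model()` uses
data-driven heuristic starts (log-linear regression for the exponential
and power families; classic curve peeling — slow component from the
low-thickness half, fast component from the log of the high-thickness
residuals — for the bi-exponential) plus 20 randomized restarts under the
caller's seed, keeping the best sum of squared errors. The nested families
(`exp2` over `exp1`, `power2` over `power1`) additionally start from the
nested optimum, which guarantees the nested-model SSE inequality up to
optimizer tolerance (1e-10 on gradient, step and relative SSE; at most
10⁴ evaluations per start). A best candidate that stopped on the
iteration cap is re-polished from its own endpoint before the convergence
flag is set. No positivity constraints are imposed, but a fitted curve
that goes non-positive inside its domain is flagged invalid for DRL use.

The bi-exponential is fitted in rate form `a e^{bt} + c e^{dt}` (better
conditioned than time constants) with the canonical ordering `b ≤ d` to
resolve the term-swap symmetry; serialization carries both
parameterizations, because rounding the printed coefficients of such
curves can shift predicted values by ~0.01–0.02 mGy at large thickness.

Goodness of fit follows nonlinear-regression-toolbox conventions:
`rmse = sqrt(sse/(n − p))` on residual degrees of freedom and
`adj R² = 1 − (1 − R²)(n − 1)/(n − p)`. Ranking is by ascending SSE, ties
broken by higher adjusted R² then fewer parameters, with non-converged
fits last regardless of SSE.

## Comparing the approaches

`compare_equation_vs_ranges()` evaluates the fitted curve and the per-bin
step function on an integer-mm grid (20–100 by default) and reports
`|range − equation| / equation × 100` pointwise — the equation value is
the denominator. Discussion-level comparisons against the typical-window
DRL (`compare_to_simplest()`) use the *simplest* DRL as denominator; the
two conventions coexist in practice and each is bound to its reporting
context here.

The signed differences (range minus equation) are tested with a two-sided
Wilcoxon signed-rank test implemented in-package: zeros dropped, ties
mid-ranked, and the exact null distribution computed by convolution over
the (possibly tied) rank values for up to 25 pairs — `stats::wilcox.test`
abandons exactness under ties, which integer-grid step-function
differences produce routinely. Above 25 pairs a tie-corrected normal
approximation with continuity correction is used. An all-zero difference
vector is reported as degenerate with p = 1 rather than an error.

`classify_against_limits()` places a DRL curve against user-supplied
acceptable/achievable guideline tables (piecewise-linearly interpolated).
Boundaries are inclusive downward: a curve exactly on a limit belongs to
the category below it. Grid points outside a table's span are flagged
`uncovered`, never silently classified. The packaged example limit tables
(`inst/extdata/limits_*_synthetic.csv`) are synthetic shapes for
demonstration and tests, not transcriptions of any guideline.

## The synthetic cohort generator

No patient-level mammography dose dataset is distributable, so
`generate_cohort()` provides the test bed: a nine-center survey with the
volume profile of a national screening program (six high-volume centers,
three small ones), CBT drawn truncated-normal 58 ± 12 mm on [13, 100] mm,
age 50 ± 8 y on [30, 90], four records per examination (CC/MLO × L/R)
with one CBT draw per breast shared by its two views.

Dose is generated as `truth(view, cbt) × center factor × lognormal
record noise`, with the ground-truth median curve a bi-exponential with
published-reference-curve shape (amplitudes 0.94 and 7.3e-4 mGy, time
constants 118.65 and 15.85 mm), MLO a constant ×1.12 above CC, center
factors lognormal with log-sd 0.10 (the real center-to-center spread is
unpublished; this is a labelled placeholder), and record noise log-sd
0.25. Because the noise is multiplicative with median 1, the per-center
median dose at thickness t is *exactly* `truth(t) × factor`, so the
implied DRL curve has the closed form `truth(t) × Q₇₅(factors)`
(`analytic_drl()`) and end-to-end recovery is checkable against an
analytic target rather than another simulation. A configurable fraction
of examinations (default 1%) receives one rule-violating record, drawn
uniformly over the exclusion-rule types, to exercise the filter
accounting.

What the generator does **not** emulate: the physics of AGD (no
target/filter or kVp dependence of dose — vendor differences enter only
as center factors), per-view thickness differences, repeat/rejected
exposures, and real centers' heterogeneous CBT distributions. Passing
recovery tests therefore demonstrates the estimator and fitting machinery,
not dosimetric realism.

## Problem sizes and what the tests show

The test suite runs the full pipeline on cohorts of roughly 500–10,000
examinations and the convergence checks on one ~100,000-exam cohort;
twenty replicate surveys at ~9,400 exams verify end-to-end curve recovery
(median absolute relative deviation of the fitted curve from the analytic
DRL over 25–95 mm, required ≤ 5%).

One empirical finding from those replicates is worth stating as a known
limitation: at the ~10⁴-exam scale, raw-SSE discrimination *between the
bi-exponential and the 2-term power family* is noise-limited. The 2-term
power family can approximate the true bi-exponential reference curve over
25–95 mm to within a residual far smaller than the sampling noise that
small centers contribute to per-bin DRLs at that scale, so the selected
family alternates between the two (the fitted *values* remain accurate —
curve recovery is unaffected). Only at multi-hundred-thousand-exam scale,
where per-bin medians stabilize, is the bi-exponential selected
essentially always. Practically: with modest surveys, report the fitted
values and the ranking table rather than treating the winning family name
as a finding, and expect the top two families to have very close
goodness of fit.

## A worked example

```{r example, eval = FALSE}
library(mammodrl)

g <- generate_cohort(synth_config(seed = 8))       # ~9.4k exams
fl <- apply_exclusions(g$cohort)                   # survey exclusions
print(fl$report)

b <- binned_drl_table(fl$cohort, "CC")             # 10-mm-bin DRLs
fa <- fit_all(b, seed = 8)                         # 5 families, ranked
print(fa$curve)                                    # the selected curve

s <- simplest_drl(fl$cohort, "CC")                 # 50 +/- 5 mm window
comp <- compare_equation_vs_ranges(fa$curve, b, simplest = s)
print(comp)

# or the whole thing, with figures and a manifest:
run_pipeline(run_config(seed = 8, output_dir = "drl_run"))
```

## Known limitations

* The DRL percentile convention is consequential with few centers (with 9
  centers the type-7 75th percentile is one single center's median); the
  package records the convention everywhere but cannot remove the
  sensitivity.
* Bi-exponential parameters are weakly identified from 8 points even when
  the curve is well determined: very different `(c, τ₂)` pairs give nearly
  identical curves inside the fitted domain. Trust curve values, not
  individual coefficients, and be cautious extrapolating beyond the
  fitted domain (evaluation outside is flagged).
* The DICOM reader is a minimal Part-10 explicit-VR little-endian header
  parser sufficient for dose-survey attributes; implicit-VR files and
  sequence-valued attributes are out of scope. Organ Dose (0040,0316) is
  converted dGy→mGy by default, with the stored unit declarable per
  source, since vendors disagree and a silent unit error would be
  catastrophic for a dose survey.
* Examination grouping relies on accession/study identifiers; when absent,
  an exam key is synthesized from center, patient and study date.
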