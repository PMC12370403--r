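# mammodrl

Diagnostic reference levels (DRLs) are the standard instrument for keeping
mammographic radiation dose under control: a national program collects the
average glandular dose (AGD, mGy) reported by each unit, takes the
**median per center**, and sets the DRL at the **75th percentile of those
center medians**. A facility whose median dose exceeds the DRL reviews its
technique.

Because AGD rises steeply with compressed breast thickness (CBT), a DRL is
only meaningful at a stated thickness. `mammodrl` computes the three
reporting flavours from the same estimator core and quantifies how much
they disagree:

1. **Typical-window DRL** — one value for breasts of 50 ± 5 mm
   (`simplest_drl()`);
2. **Range-based DRLs** — one value per 10-mm CBT bin, 20–100 mm, with
   per-bin distribution-free 95% CIs for the median AGD
   (`binned_drl_table()`);
3. **A continuous DRL curve** — the per-bin DRLs at their bin centers,
   fitted by trust-region nonlinear least squares over five model families
   (linear; one/two-term power `a·t^b (+ c)`; mono/bi-exponential
   `a·e^{bt} (+ c·e^{dt})`), ranked by SSE and reported in time-constant
   form, e.g.

   DRL(CBT) [mGy] = a·exp(CBT/τ₁) + c·exp(CBT/τ₂)

   giving a reference value for *any* thickness (`fit_all()`,
   `evaluate_curve()`).

Around that core: DICOM-header / CSV ingestion with a configurable column
dialect (`extract_from_dicom()`, `read_cohort_csv()`), examination-level
survey exclusions with exact accounting (`apply_exclusions()`), approach
comparison with an exact Wilcoxon signed-rank test
(`compare_equation_vs_ranges()`), classification against guideline
acceptable/achievable limit curves (`classify_against_limits()`), a
multi-center synthetic cohort generator with an analytically known DRL
surface (`generate_cohort()`, `analytic_drl()`), and an end-to-end
pipeline with figures and a conventions manifest (`run_pipeline()`, plus
a CLI at `inst/cli/mammodrl`).

## Worked example

A synthetic nine-center survey of ~9,400 examinations (37,540 records),
filtered, binned, fitted and compared:

```r
library(mammodrl)

g  <- generate_cohort(synth_config(seed = 8))
fl <- apply_exclusions(g$cohort)
print(fl$report)
#> <filter_report> 37540 records in, 37152 out (examination-level rules)
#>   non_standard_view       0 records      0 exams
#>   compression_force     164 records     41 exams
#>   low_mas                92 records     23 exams
#>   zero_kvp               84 records     21 exams
#>   cbt_above_max          48 records     12 exams
#>   implant_present         0 records      0 exams

b <- binned_drl_table(fl$cohort, "CC")
round(b$drl, 3)
#> [1] 1.168 1.353 1.428 1.512 1.714 1.856 2.069 2.799

fa <- fit_all(b, seed = 8)
print(fa$curve)
#> <drl_curve> DRL_CC(CBT) [mGy] = 0.96*exp(CBT/114) + 2.94e-11*exp(CBT/4)
#>   domain [20, 100] mm; family exp2

simplest_drl(fl$cohort, "CC")
#> [1] 1.511

comp <- compare_equation_vs_ranges(fa$curve, b, simplest = 1.511)
print(comp)
#> <drl_comparison> view CC, 81 grid points
#>   |range - equation|/equation: median 2.8%, max 36.0%
#>   Wilcoxon signed-rank: W = 1505, p = 0.466 (normal approximation with
#>   tie correction, n = 81)
```

Reading the numbers: the per-bin DRLs rise from 1.17 mGy (20–30 mm
breasts) to 2.80 mGy (90–100 mm); the fitted bi-exponential reproduces the
generative curve's slow component (0.96·e^{CBT/114} against a ground truth
of 0.94·e^{CBT/118.65} times the center-factor percentile); and while the
step function and the curve agree to a median 2.8% across thicknesses,
they diverge by up to 36% at thicknesses far from a bin center — which is
the argument for reporting the equation rather than the steps. The whole
run, with figures (per-bin bars, CBT histogram with its modal 10-mm
window, step-vs-curve overlay) and a machine-readable manifest of every
convention, is `run_pipeline(run_config(seed = 8))`.

The methods vignette (`vignettes/drl-methodology.Rmd`) documents the
estimator conventions, the fitting policy, the generator's design and its
limits, and the known weak-identifiability caveats of bi-exponential
coefficients.

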