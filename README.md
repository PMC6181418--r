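# tilscore

Tumor-infiltrating lymphocyte (TIL) density scoring, outcome-based cutpoint
optimization, and I0–I4 Immunoscore survival analysis.

## The problem

In muscle-invasive bladder cancer treated with radical cystectomy, the
density of CD3⁺ and CD8⁺ TILs — counted separately in the tumor core (CT)
and the invasive margin (IM) — is prognostic, and the four
marker–compartment measurements can be summarized into a single
**Immunoscore**: the number of compartments in which the density is "high",

```
I = #{ c in {CD3_CT, CD3_IM, CD8_CT, CD8_IM} : d_c > cutoff_c },  I ∈ {0,…,4}.
```

Cutoffs are usually not known a priori; the field's practice is
outcome-based **minimum-p-value** optimization: scan every admissible
observed density value `v`, compute the two-group log-rank statistic
comparing `{d ≤ v}` against `{d > v}`, and keep the cutoff with maximal
chi-square (minimal p). Because the cutoff is chosen to minimize the
p-value, the raw p is anti-conservative; the package therefore always
reports a corrected p alongside it, using either the Miller–Siegmund
approximation for maximally selected statistics,

```
p_cor = φ(z)(z − 1/z) · log[ (1−ε_l)ε_h / (ε_l(1−ε_h)) ] + 4φ(z)/z,
z = Φ⁻¹(1 − p_min/2),
```

or a permutation reference distribution of the whole scan. Downstream, the
package provides Kaplan–Meier curves, k-group and trend log-rank tests,
univariable/multivariable Cox proportional-hazards tables (Efron ties), a
responder-vs-non-responder density comparison, and a two-group
differential-expression stage with Benjamini–Hochberg FDR control for
luminal-vs-basal style contrasts. A seeded synthetic-cohort generator
(correlated log-normal densities, Weibull proportional-hazards outcomes)
makes the whole pipeline testable end to end. The methods vignette
(`vignettes/immunoscore-methods.Rmd`) documents every modelling choice.

This package is for biostatisticians and computational pathology /
immuno-oncology analysts who need a transparent, scriptable implementation
of this workflow rather than a GUI tool.

## Worked example

```r
library(tilscore)

# a seeded 67-patient synthetic cohort with the default study conditions
cohort <- generate_cohort(sim_config(seed = 42, n_patients = 67))

# optimize the CD8(IM) cutoff against overall survival
cp <- optimize_cutpoint(cohort$cd8_im, cohort$os_months, cohort$os_event,
                        compartment = "cd8_im", endpoint = "os")
print(cp)
#> Outcome-based cutpoint optimization
#>   compartment: cd8_im
#>   endpoint:    os
#>   cutoff: 52.6592 cells/mm^2 (low n=14, high n=53)
#>   log-rank chi-square: 20.592 over 54 candidates
#>   raw p: 5.682e-06; corrected p (miller_siegmund): 0.0002617
```

The scan found 54 admissible candidate cutoffs, selected 52.7 cells/mm²
(the true simulated threshold is 70, with a strongly protective high-CD8-IM
hazard ratio of 0.35), and the Miller–Siegmund correction inflates the raw
minimum p by a factor of ~46 to account for the scan.

```r
# score the cohort at fixed cutoffs and grade every patient
scored <- score_cohort(cohort, c(cd3_ct = 490, cd3_im = 290,
                                 cd8_ct = 116, cd8_im = 70))
table(scored$immunoscore)
#>  0  1  2  3  4
#> 12 12 16 17 10

assign_immunoscore(c(cd3_ct = "high", cd3_im = "low",
                     cd8_ct = "high", cd8_im = "high"))
#> Immunoscore: I3
```

Three of four compartments are high, so the grade is I3; the grade is
always the count of high calls, and any missing call leaves it undefined
rather than imputed.

The full pipeline (cutpoints → scoring → KM/log-rank exports → Cox tables →
responder comparison → optional DE stage, plus a checksummed run manifest)
runs with:

```r
res <- run_pipeline(pipeline_config(
  out_dir = "results/run1",
  sim = sim_config(seed = 42, n_patients = 120),
  cutoffs = c(cd3_ct = 490, cd3_im = 290, cd8_ct = 116, cd8_im = 70),
  expression = expression_sim_config(seed = 42),
  seed = 42))
```

or from a shell via `inst/scripts/run_pipeline.R`.

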