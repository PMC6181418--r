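---
title: "Methods: TIL density scoring, outcome-based cutpoints and Immunoscore survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIL density scoring, outcome-based cutpoints and Immunoscore survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilscore)
```

## The analysis problem

In muscle-invasive bladder cancer (and other solid tumors), the density and
spatial distribution of tumor-infiltrating lymphocytes (TILs) carry
prognostic information beyond TNM staging. The workflow this package
implements quantifies CD3+ (pan T cell) and CD8+ (cytotoxic T cell)
densities separately in the tumor core (CT) and the invasive margin (IM),
dichotomizes each of the four marker-compartment densities at a cutoff,
sums the "high" calls into the I0-I4 Immunoscore, and relates both the
individual calls and the Immunoscore to overall survival (OS) and
disease-free survival (DFS).

## Density quantification

`compute_density()` turns per-area lymphocyte counts into cells/mm^2 by
averaging the per-area densities (count_i / area_i) over the selected
fields (three non-contiguous high-density areas by convention). We average
per-area densities rather than pooling counts over pooled area; the two
coincide for equal areas, and the per-area mean is the natural estimator
when each field is scored independently. Fields with fewer than the
expected number of areas are averaged over what exists, with a warning,
since incomplete sampling should be visible but not fatal.

`dichotomize()` uses the strict-greater convention: a density is "high" iff
it strictly exceeds the cutoff, "low" at or below it. This convention is
fixed by the published group compositions (low defined by "<= cutoff", high
by "> cutoff") and is applied consistently everywhere, including candidate
enumeration in the cutpoint scan. Missing densities yield missing calls and
are never imputed; patients with a missing call have an undefined
Immunoscore and are excluded from score-based survival analyses
(complete-case handling).

## Outcome-based minimum-p-value cutpoints

When no external cutoff exists, the field's common practice (X-Tile-style)
is to scan candidate cutoffs and pick the one minimizing the two-group
log-rank p-value. `optimize_cutpoint()` re-implements this transparently:

* **Candidates** are the distinct observed densities `v` such that both
  groups (`<= v` and `> v`) hold at least `ceiling(min_group_frac * n)`
  patients. Candidates sit at observed values (not midpoints) so the
  strict-greater convention reproduces the realized group sizes exactly.
  The default `min_group_frac = 0.10` is the X-Tile-like floor; published
  Immunoscore splits are comfortably above it.
* **Scan**: for each candidate, the standard two-group log-rank chi-square
  (df = 1) with tie-corrected hypergeometric variance. Internally the scan
  is vectorized: the at-risk and event-indicator matrices over distinct
  event times are built once, and each candidate split (and each
  permutation) costs two matrix products. Tests verify the scan against
  both `survival::survdiff()` and an independent brute-force implementation
  of the hypergeometric sums.
* **Selection**: the candidate with maximal chi-square; exact ties are
  broken toward the smallest cutoff, a deterministic and reproducible rule.

The minimum p-value over many correlated tests is strongly
anti-conservative, so the result always carries a corrected p-value next to
the raw one:

* `miller_siegmund_correct()` implements the asymptotic tail approximation
  for maximally selected statistics,
  `p_cor = phi(z) (z - 1/z) log[((1-e_l) e_h)/(e_l (1-e_h))] + 4 phi(z)/z`
  with `z` the upper-tail normal quantile of `p_min / 2`, clamped to
  `[p_min, 1]`. Inside `optimize_cutpoint()` the epsilons are the achieved
  low-group-fraction range over the admissible candidates — the split range
  the scan actually explored.
* `permutation_correct()` re-runs the full scan on permutations of the
  density labels against the (time, event) pairs and reports
  `(1 + #{permuted min-p <= observed}) / (n_perm + 1)`; it is exact up to
  Monte-Carlo error under exchangeability and is the calibration reference
  in the test suite.

The default correction is Miller-Siegmund (deterministic and fast);
permutation is available when exact calibration matters. Both the raw and
the corrected p-value are reported because downstream survival analyses
conventionally quote the raw log-rank p at the chosen cutoff. The endpoint
used for optimization is configurable and defaults to OS; published
analyses of this design print a single cutoff per compartment without
stating the optimized endpoint, so the choice is left to the user rather
than guessed.

## The Immunoscore

`assign_immunoscore()` formalizes the published worked examples (all four
calls high gives I4; one marker low in one compartment gives I3; all low
gives I0) as *grade = number of high calls among CD3-CT, CD3-IM, CD8-CT,
CD8-IM*, the standard Galon counting rule; it is consistent with every
printed example and makes the grade permutation-symmetric in the four
calls and monotone in each density. Any missing call leaves the grade
undefined with an explicit flag.

## Survival statistics

Kaplan-Meier estimation, the k-group log-rank test, and Cox
proportional-hazards models are delegated to the `survival` package
(`survfit`, `survdiff`, `coxph`) behind thin, validated wrappers that
return plain tables; the package's own tests re-derive each statistic from
first principles on small datasets. Choices worth stating:

* **Ties**: Cox models default to Efron's approximation (less biased than
  Breslow under heavy ties); Breslow is selectable and the method used is
  recorded in the output.
* **Wald inference**: per-covariate 95% CIs are `exp(log HR +/- z_{0.975}
  SE)`; coverage of this interval is verified by simulation.
* **Trend test**: for ordered Immunoscore grades a df = 1 trend log-rank
  with integer scores 0..k-1 is implemented in-package (it is not available
  in `survdiff`); with two groups it reduces exactly to the ordinary
  log-rank test. The pipeline reports both the heterogeneity (df = k-1)
  and the trend statistic, since either may be wanted for a monotone dose-
  response question.
* **Multivariable models**: one model per immune marker — the adjustment
  set (organ-confined, surgical margin, LVI, intravesical therapy,
  perioperative chemotherapy) plus that single marker, with the Immunoscore
  entered as grade indicators against the lowest observed grade. Markers
  are never entered jointly: the four calls are strongly correlated by
  construction, and the reporting convention this mirrors is marker-wise.
* **Two-group density comparisons** (e.g. CD8-IM in chemotherapy responders
  versus non-responders) default to the Wilcoxon rank-sum test because
  density distributions are right-skewed; a Welch t-test is available.
* All tests are two-sided with alpha = 0.05 by default.

## Differential expression stage

`de_two_group()` performs a per-gene two-sided Welch test on log-scale
expression between basal and luminal samples, with Benjamini-Hochberg
q-values across all tested genes (`bh_adjust()`, validated against a
literal step-up implementation). A plain unequal-variance location test was
chosen deliberately: the stage's role is a transparent, fully specified
two-group comparison on already-normalized log-scale values, not a
moderated-variance RNA-seq pipeline. Genes with zero variance in both
groups get p = 1 with a warning. `geneset_summary()` counts gene-set
members significant at the q threshold, split by direction, and exports the
matrix slice for heatmap rendering elsewhere (rendering itself is out of
scope).

## The synthetic cohort generator

No patient-level cohort of this design is publicly deposited, so
`generate_cohort()` produces seeded cohorts with the statistical structure
the analysis assumes. It is first-class, tested code, and its defaults are
fixed once as the study conditions:

* **Densities**: correlated log-normals — strictly positive, right-skewed,
  as counts per mm^2 are — with default cross-compartment correlation 0.5
  (TIL subsets co-infiltrate). Default locations place the true cutoffs
  (490/290/116/70 cells/mm^2 for CD3-CT/CD3-IM/CD8-CT/CD8-IM) near the
  observed high/low split proportions of the motivating cohort (about 73%
  high for CD8-IM, 27% high for CD3-IM, and a median split for the CT
  compartments), with sdlog 0.9 throughout.
* **Survival**: Weibull proportional hazards, shape 1.2, linear predictor =
  sum of per-compartment log HRs applied when density strictly exceeds its
  true cutoff, plus covariate log HRs. The linear predictor is centred at
  its configuration-implied mean so the baseline scale keeps its
  interpretation; the default scale puts median survival at 36 months for
  the average patient, giving roughly half the cohort an OS event within
  3 years. Default effects: log HR -1.05 for high CD8-IM (HR 0.35, the
  strongly protective invasive-margin effect), milder protection for the
  other compartments (-0.25, -0.5, -0.6), and covariate effects of the
  magnitude reported in univariable analyses of this design (LVI +1.19,
  margin +0.93, non-organ-confined disease via organ-confined -1.5,
  chemotherapy -0.97, intravesical therapy 0).
* **Covariates**: independent Bernoulli draws at prevalences 70.1% (LVI),
  10.4% (margin), 26.1% (intravesical), 40% (perioperative chemotherapy,
  neoadjuvant and/or adjuvant combined), 22% (organ-confined).
* **Censoring**: administrative at 60 months plus a 10% uniform early
  dropout fraction.
* **DFS**: every patient's latent DFS time equals the OS time unless they
  recur, in which case it is the OS time scaled by a Beta(5, 2) factor;
  recurrence probability follows a logistic link in the centred linear
  predictor (base rate 0.6, slope `dfs_coupling = 0.8`). This guarantees
  DFS <= OS row-wise and the expected event-count ordering.
* **Chemotherapy response**: simulated only for chemotherapy-treated
  patients, with response probability logistic in log CD8-IM density
  centred at its cutoff (slope 1), so responders are enriched for high
  marginal CD8 infiltration.
* **Missingness**: an optional per-column masking fraction (default 0).

A single integer seed drives every draw, so identical configurations give
bit-identical cohorts.

What the generator does *not* emulate: real staining and image-analysis
noise, spatial correlation within a slide, informative censoring,
covariate-density dependence (covariates are independent of densities by
construction), age or stage as continuous variables, or cure fractions.
Passing tests on these cohorts therefore demonstrate that the statistical
machinery is correct and calibrated under the stated model, not that any
particular clinical effect size generalizes.

The expression generator likewise produces Gaussian log-scale matrices
(default 121 luminal + 68 basal samples, 113 designated cytotoxicity genes
shifted by the effect size in basal), not RNA-seq counts; subtype calling
is reduced to a binary label.

## Numerical choices and degenerate inputs

* Log-rank variance terms at event times with one patient at risk are 0 by
  convention; a scan split with zero variance reports chi-square 0.
* `optimize_cutpoint()` ties on the chi-square go to the smallest cutoff.
* Cutpoint scans exclude patients with missing density from that
  compartment's optimization only.
* Cox fits flag (and warn on) suspected monotone likelihood — any
  coefficient with |log HR| > 15 or a convergence warning from the
  underlying fitter — rather than silently returning; constant covariates
  are an error naming the column.
* `miller_siegmund_correct()` clamps to `[p_min, 1]`, which both enforces
  corrected >= raw and handles the approximation's breakdown for large
  `p_min`; `p_min >= 1` returns 1 exactly.
* The permutation correction compares permuted and observed scans on the
  chi-square scale with a 1e-12 slack so that exact ties (the same split
  re-drawn) count as at-least-as-extreme.
* `bh_adjust()` requires p-values in (0, 1] and refuses zeros rather than
  silently producing q = 0.

## Problem sizes used by the test suite

The simulation-based checks use sizes chosen to keep Monte-Carlo error
well inside the asserted bands: marginal and independence checks at
n = 10,000; cutpoint recovery over 200 cohorts of n = 400; selection-effect
calibration over 1,000 null cohorts of n = 150 with 199 permutations each;
Cox recovery at n = 2,000 and Wald coverage over 500 cohorts of n = 300;
BH oracle agreement over 1,000 random p-vectors; differential-expression
power at the default 121 + 68 samples and calibration over repeated null
matrices.

## Known limitations

* The minimum-p cutpoint remains a data-dependent dichotomization; even
  corrected, it discards information relative to modelling density
  continuously, and recovered cutoffs on moderate cohorts are variable
  (the tests assert only that the median over replicates lands between the
  population deciles flanking the truth).
* The Miller-Siegmund correction is asymptotic and can be conservative for
  small n or coarse density ties; the permutation route is the calibrated
  reference.
* The Cox wrappers deliberately omit proportional-hazards diagnostics,
  time-varying covariates and competing risks.
* The DE stage assumes approximately Gaussian log-scale values and
  independent genes for its FDR guarantees; correlated genes make BH
  conservative on average but noisier per run.
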