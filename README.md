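# ccastab

Split-half stability assessment for canonical correlation analysis (CCA)
of two high-dimensional variable sets — typically brain-imaging measures
versus behavioral/demographic subject measures.

## The problem

CCA finds weight vectors *A1*, *B1* so that the canonical variables
*U1 = A1ᵀX* and *V1 = B1ᵀY* are maximally correlated; their Pearson
correlation is the first-mode canonical correlation coefficient (CCC), and
each variable's *loading* is its correlation with its set's canonical
variable.  Because imaging data have far more variables than subjects,
each set is PCA-reduced first, and the subject-to-variable ratio
(SVR = subjects / retained imaging dimensions) governs overfitting: as
SVR → 1 the sample CCC is forced toward 1 whatever the truth (exactly 1
once *k*<sub>x</sub> + *k*<sub>y</sub> ≥ *n*).  A big CCC alone therefore
proves nothing.

`ccastab` quantifies how trustworthy a CCA result is by resampling pairs
of subgroups from one pool (with an *exactly* controlled number of shared
subjects), running the full pipeline — z-score, PCA, re-standardized
scores, first-mode CCA, permutation test, loadings — independently in each
subgroup, and comparing the results over three assessments:

1. mean/SD of |CCC<sub>a</sub> − CCC<sub>b</sub>|,
2. percentage of pairs where both / neither / exactly one subgroup is
   significant (permutation *p* < .05),
3. mean/SD of the absolute correlation between the two subgroups' loading
   vectors (per set).

A synthetic-data generator with an analytically known population canonical
structure (shared latent modes; closed-form loading norms
*r*² = σ²ρ/(1−ρ); optional "dominant" variables and QC-defect fixtures)
makes the whole pipeline testable without any cohort download.  The
package is intended for methodologists and neuroimaging researchers who
want to check, before believing a brain–behavior CCA, whether it would
survive a change of subjects.

## Worked example

```r
library(ccastab)

# strong-correlation population: 160 subjects, 120 imaging-like variables,
# 26 subject measures of which 3 are dominant (gender/height/weight-like)
d <- generate_correlated_sets(generator_spec(
  n_subjects = 160, p_x = 120, p_y = 26, rho = 0.85, n_dominant = 3,
  seed = 42))

ref <- reference_fit(d$X, d$Y, dim_y = 8)   # SVR ~ 9 reference fit
ref$fit
#> First-mode CCA: ccc = 0.8361 (8 modes available)
round(sort(abs(ref$fit$loadings_y), decreasing = TRUE)[1:4], 2)
#> dominant_1 dominant_2 dominant_3     sm_014
#>       0.85       0.84       0.82       0.39

# moderate scenario: drop the three dominant subject measures
mod <- make_moderate_scenario(d$Y, ref$fit$loadings_y, "drop_top_k", k = 3)
mod$removed
#> [1] "dominant_1" "dominant_2" "dominant_3"
round(reference_fit(d$X, mod$table, dim_y = 8)$fit$ccc, 3)
#> [1] 0.521

# stability sweep: subgroups of 80, disjoint pairs, SVR 10 / 2 / 1.11
g <- grid_spec(dims_x = c(8, 40, 72), dim_y = 8, overlaps = 0,
               subgroup_size = 80, n_pairs = 50, n_perm = 100,
               master_seed = 7)
run_grid(d$X, d$Y, g, procedure = "main", scenario = "strong")
#>   dim_x   svr ccc_mean ccc_absdiff_mean pct_both_sig pct_mixed loadcorr_x_mean loadcorr_y_mean
#> 1     8 10.00    0.832         4.12e-02          100         0           0.754           0.832
#> 2    40  2.00    0.923         2.24e-02           56        42           0.705           0.749
#> 3    72  1.11    1.000         1.09e-15            0         0           0.281           0.265
```

Reading the sweep: at SVR 10 the CCC is honest (≈ the 0.85 population
value), every pair is significant in both halves, and loading vectors
correlate ≈ 0.8 across halves.  At SVR 2 the CCC is inflated to 0.92,
significance already disagrees within 42% of pairs, and at SVR 1.11 the
CCC saturates at exactly 1 while the loading correlation collapses to
≈ 0.27 — a perfectly reproducible CCC of 1 carried by a completely
unstable mode.  The moderate scenario (dominant measures removed) fails
the 0.65 reference-CCC floor, and `advise_stability()` says so:

```r
advise_stability(0.52, 9, dim_x = 18, dim_y = 8, sample_size = 160)
#> Guideline verdict (SVR = 8.889):
#>   weak_correlation:         TRUE
#>   dimensionality_too_high:  FALSE
#>   First-mode CCC 0.52 at SVR ~9 is below 0.65: the correlation is not
#>   strong enough for the CCA results to be stable; CCA is not recommended
#>   here. ...
```

Full-scale study presets (`grid_preset("tianjin")`, `grid_preset("hcp")`:
720 cells and 1.44 million CCA fits when crossed with two measures, two
scenarios, two procedures) and a thin CLI (`inst/cli/ccastab.R` with
`simulate`, `qc`, `run-grid`, `assess`, `advise` subcommands) are
included.  The methods vignette (`vignettes/cca-stability.Rmd`) documents
the model, the generator calibration and the numerical choices.

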