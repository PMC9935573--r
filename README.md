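# stenoscore

Automated quantification of posterior-circulation artery stenosis from 3D
TOF-MRA-like volumes, and the downstream association and risk-prediction
analysis linking that score — together with blood-pressure features — to
cognitive impairment (CI) in the elderly.

Narrowing of the basilar artery (BA) and the posterior cerebral arteries
(PCA) starves memory-critical territories (hippocampus, thalamus, posterior
cortex) of blood flow. The package measures that narrowing from bright-vessel
volumes with a fully automatic geometric chain, and evaluates it as a risk
marker with the standard epidemiological toolkit.

## The score

For an extracted artery with diameter profile `d(s)`,

    S = (1 - d_min / d_average) x 100%

where `d_min` is the minimum and `d_average` the mean diameter over the
retained cross-sections. `S` is in `[0, 100)` and is graded `<50%` vs
`>=50%`. The measurement chain behind it: isotropic resampling, Otsu +
watershed segmentation, topology-preserving 3D thinning, centerline graph
construction, anatomical-prior artery extraction, parallel-transport
straightening, and equivalent-circle diameter profiling.

Because no suitable data are publicly deposited, the package ships
ground-truthed synthetic generators as first-class, tested modules: vessel
phantoms whose analytic stenosis score is known exactly, and cohort
simulators whose logistic CI outcome has known effect sizes (pulse-pressure
OR 1.04 per mmHg, left-PCA score OR 1.021 per percent, positive history
effects).

## Worked example

Generate the default posterior-circulation phantom (BA trunk bifurcating
into the two PCAs) with a 50%-depth focal stenosis imposed on the left PCA,
and score it:

```r
library(stenoscore)

spec <- posterior_circulation_spec(
  stenoses = list(left_pca = data.frame(position = 0.5, depth = 0.5, width = 2)),
  noise_sd = 50, seed = 1)          # 5% of the 1000-unit vessel contrast
ph <- generate_phantom(spec)
ph$truth
#> <phantom_truth>
#>   ba         length   14.2 mm  radius 2.00-2.00 mm  score   0.00
#>   left_pca   length   17.6 mm  radius 0.80-1.60 mm  score  41.68
#>   right_pca  length   17.6 mm  radius 1.60-1.60 mm  score   0.00

score_posterior_circulation(ph$volume)
#> <stenosis_report> topology: endpoints 3, junctions 1, edges 3
#>   ba         S =   0.64%  (<50%)
#>   left_pca   S =  37.97%  (<50%)
#>   right_pca  S =   4.17%  (<50%)
```

The tree's topology is recovered exactly (one bifurcation, three endpoint
tips), and the imposed narrowing is recovered within 4 points of its
analytic truth while the untouched arteries stay near zero.

On the cohort side, simulate 2000 elderly subjects, derive BP features,
and fit the adjusted odds-ratio models:

```r
tab <- assemble_analysis_table(generate_cohort(cohort_spec(2000, seed = 1)))
fit_or_model(tab, "pp", adjust = c("bmi", "mi", "stroke"))[, c("or", "ci_low", "ci_high")]
#>         or   ci_low  ci_high
#> 1 1.032362 1.023828 1.040968   # generating value: 1.04 per mmHg
fit_or_model(tab, "lpca_ge50", adjust = c("bmi", "mi", "stroke"))[, c("or", "ci_low", "ci_high")]
#>         or   ci_low ci_high
#> 1 2.284898 1.790623 2.91561   # >=50% left-PCA stenosis carries excess risk
```

The numbered drivers under `analysis/` run the full study in order:
`01_simulate_phantoms.R` (phantom grid + tree), `02_score_vessels.R`
(pipeline vs truth), `03_simulate_cohort.R` (cohort + 1:1 sex/age-matched
case-control set), `04_cohort_analysis.R` (group comparisons, odds-ratio
table, Spearman screens), `05_risk_prediction.R` (four learners x three
nested feature sets, 5-fold CV, holdout ROC, DeLong tests). Each writes its
tables under `results/`.

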