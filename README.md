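# couplingprior

An R package for analysing partial sensory integration in cursor-control
experiments, aimed at researchers in sensorimotor control and multisensory
perception. It implements, as a tested and reusable pipeline, the analysis
of position-judgment experiments in which participants make out-and-back
hand movements under a small visuomotor rotation and then judge either the
hand or the cursor movement endpoint.

## The model and the measures

When hand and cursor endpoints disagree by a rotation-induced discrepancy,
judgments of each modality are attracted toward the other. Regressing the
trial-wise judgment error on the signed hand–cursor discrepancy yields the
bias weights: the slope in hand-judgment (*BiHand*) trials is the cursor
weight *w*<sub>C</sub>, the slope in cursor-judgment (*BiCursor*) trials is
the hand weight *w*<sub>H</sub>. Two scalar measures summarise them:

- **Integration strength** λ = *w*<sub>H</sub> + *w*<sub>C</sub>
  (1 = fusion, 0 = independence, in between = partial integration);
- **Coupling angle** α = atan(*w*<sub>H</sub>/*w*<sub>C</sub>)
  (45° = symmetric biases, 90° = pure bias toward the hand).

The coupling-prior model describes partial integration as optimal (MAP)
estimation under a zero-mean Gaussian prior on the difference of the two
position estimates. Given observed unimodal variances σ²<sub>H</sub>,
σ²<sub>C</sub> and the observed λ, the prior variance is

σ²<sub>prior</sub> = (1 − λ)/λ · (σ²<sub>C</sub> + σ²<sub>H</sub>),

from which the model predicts the bimodal weights
(*w*<sub>H</sub> = σ²<sub>C</sub>/T, *w*<sub>C</sub> = σ²<sub>H</sub>/T with
T = σ²<sub>C</sub> + σ²<sub>H</sub> + σ²<sub>prior</sub>), the bimodal
judgment variances, and the coupling angle
(α<sub>pred</sub> = atan(σ²<sub>C</sub>/σ²<sub>H</sub>)). A grid-search MAP
oracle with explicit precision-matrix inversion (`posterior_oracle()`)
verifies the closed forms numerically.

The package also provides the surrounding experimental machinery: the
factorial session design with its semi-randomized ordering constraint
(`build_session()`), a seeded synthetic-trial generator with known ground
truth (`simulate_cohort()`), the three outlier-screening criteria and the
dual-intercept response-hysteresis correction (`preprocess_trials()`),
per-participant estimation (`estimate_integration()`), and group-level
repeated-measures statistics (`paired_t()`, `rm_anova_2x3()`,
`pearson_cor()`).

## Worked example

Simulate a 12-participant cohort (3 visibility conditions × 320 trials
each) from the default ground truth — λ = 0.8 with the cursor visible
during the movement (*Dyn*, *DynEnd*), λ = 0.45 with endpoint-only
feedback (*End*) — and run the full analysis:

```r
library(couplingprior)
res <- run_pipeline(list(n_participants = 12, seed = 2026))
res$integration$per_condition
#>   condition mean_lambda sem_lambda  n
#> 1       Dyn       0.789     0.0158 12
#> 2    DynEnd      0.787     0.0150 12
#> 3       End       0.453     0.0195 12
res$integration$pairwise[, c("contrast", "t_value", "df", "p_value", "cohens_d")]
#>        contrast  t_value df  p_value cohens_d
#> 1    Dyn vs End  12.1679 11 1.01e-07   3.5126
#> 2 Dyn vs DynEnd   0.0824 11 9.36e-01   0.0238
#> 3 End vs DynEnd -13.4811 11 3.49e-08  -3.8917
```

The recovered integration strengths match the generating values, and the
End-vs-Dyn contrast shows the drop in integration when online causality
evidence (the correlated hand and cursor movements) is absent. Observed
bias weights sit on top of the coupling-prior predictions:

```r
res$biases$BiHand$means
#>   condition mean_obs sem_obs mean_pred sem_pred
#> 1       Dyn    0.631  0.0113     0.627   0.0164
#> 2    DynEnd   0.674  0.0138     0.668   0.0137
#> 3       End    0.378  0.0163     0.361   0.0163
```

`res$sds`, `res$angles` and `res$durations` hold the analogous
observed-vs-predicted comparisons for judgment variability (reported as
SDs in degrees), coupling angles (with the λ < 0.2 participant exclusion),
and movement durations. `res$filter_report` and `res$hysteresis` document
the preprocessing: with the default contamination rates roughly 1–2% of
trials are screened out per session, mirroring the per-criterion exclusion
fractions the screening rules were designed around.

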