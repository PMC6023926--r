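---
title: "Methods: coupling-prior analysis of hand-cursor integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupling-prior analysis of hand-cursor integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(couplingprior)
```

## The scientific problem

In a cursor-control task a participant moves an unseen hand on a tablet
while a cursor moves on a monitor. A small visuomotor rotation (here
±2.5° to ±17.5° in steps of 5°, mean 0) decouples the two movement
endpoints, and the participant then judges where either the hand or the
cursor ended. Because the brain treats hand and cursor position as
(partially) redundant, judgments of each modality are pulled toward the
other. This package quantifies that pull, summarises it as an
integration strength and a coupling angle, and compares both - together
with the judgment variabilities - against the predictions of an optimal
partial-integration model.

## The coupling-prior observer

The model assumes the observer receives two noisy measurements, $m_H
\sim \mathcal N(\theta_H, \sigma_H^2)$ and $m_C \sim \mathcal
N(\theta_C, \sigma_C^2)$, and holds a zero-mean Gaussian prior on the
*difference* of the latent positions, $\theta_H - \theta_C \sim
\mathcal N(0, \sigma^2_{prior})$. MAP estimation under this prior pulls
each estimate toward the other measurement by a fixed proportion of the
discrepancy. The mutual bias weights are

$$w_H = \frac{\sigma_C^2}{T}, \qquad w_C = \frac{\sigma_H^2}{T},
\qquad T = \sigma_C^2 + \sigma_H^2 + \sigma^2_{prior},$$

so the less reliable modality is biased more, and their sum
$\lambda = w_H + w_C$ measures integration strength: $\lambda = 1$ at
$\sigma^2_{prior}=0$ (fusion, the classic reliability-weighted average)
and $\lambda \to 0$ as $\sigma^2_{prior} \to \infty$ (independence).
Inverting the weight-sum identity turns an *observed* $\lambda$ into a
prior variance,

$$\sigma^2_{prior} = \frac{1-\lambda}{\lambda}
  \left(\sigma_C^2 + \sigma_H^2\right),$$

which is how `couple_predict()` maps observed unimodal variances and
observed integration strength to predicted bimodal weights, predicted
bimodal judgment variances (the marginal posterior variances), and the
predicted coupling angle $\alpha_{pred} = \arctan(\sigma_C^2 /
\sigma_H^2)$. The identification of the marginal posterior variance
with trial-to-trial judgment variance is taken as the model's
definition here; it is a modelling assumption, not a theorem about
behaviour.

Two independent numeric routes guard the algebra. `posterior_oracle()`
maximises the joint log-posterior by dense grid search (2001 points per
axis over the measurement interval ±6 likelihood SDs) followed by a
single two-dimensional Newton step whose gradient and Hessian are
finite differences of the objective - exact for a quadratic - and
computes marginal variances by explicit 2×2 precision-matrix
inversion. The test suite requires agreement with the closed forms to
1e-6, which the grid-plus-Newton construction exceeds comfortably.

## Estimation from trials

`fit_bias_regression()` regresses the trial-wise judgment error
(judged minus physical angle of the judged modality) on the signed
discrepancy, oriented so the slope is directly the weight toward the
*other* modality (for `BiHand` trials the regressor is cursor − hand;
for `BiCursor`, hand − cursor). An intercept is always included: the
start-side hysteresis correction removes the left/right offset, but a
global judgment offset may remain. The residual variance uses
denominator $n-2$ since slope and intercept are both estimated. For
unimodal trials the rotation is a dummy regressor: the slope is
computed but never interpreted, and the residual variance estimates
the unimodal judgment variance.

`summarize_integration()` forms $\lambda_{obs} = w_{H,obs} +
w_{C,obs}$ without clipping - the two weights are estimated
independently, so $\lambda_{obs}$ may leave $[0,1]$ - and the observed
coupling angle via the two-argument arctangent of $(w_H, w_C)$, which
stays defined for negative weights. Rows with $\lambda_{obs} \le 0$
carry a quality flag: the angle is geometrically meaningless there and
downstream consumers must honour the flag. When predictions are needed
for $\lambda_{obs} > 1$, `predict_integration()` clips to full fusion
and records the clip, since the prior variance would otherwise be
negative; the low-level `prior_variance()` instead raises unless
explicitly asked to clip.

Because the coupling angle is a ratio measure, it is noise-dominated
for weak integrators; `exclude_low_integrators()` therefore drops a
participant from the coupling-angle analysis (only) when their
$\lambda_{obs}$ falls below 0.2 in any condition, with the boundary
value retained. The reported degrees of freedom follow the retained
sample ($n_{retained} - 1$).

## Preprocessing

Trials are screened by three criteria, evaluated on raw per-trial
fields only (so the outcome is independent of row order), with each
removed trial tagged by the first criterion it matches: (1) hand
drifted more than 2.5° along the stopper ring before returning; (2)
outward direction deviated more than 35° from the instructed
direction; (3) judgment error exceeded 35° - twice the maximal
rotation. The per-trial kinematic scalars these criteria read
(`ring_drift_deg`, `direction_deviation_deg`) are taken as given
columns; trajectory processing is out of scope.

Judgments are then corrected for response hysteresis: the response
marker starts at the far left or far right of the semicircular track,
which induces a side-dependent offset. Per participant and condition
(all trial types pooled, 320 trials at the default design), judged
positions are regressed on physical positions with one shared slope
and two intercepts; half the right-minus-left intercept difference is
subtracted from right-start judgments and added to left-start ones, so
a refit on corrected data gives a zero difference up to round-off.
Screening runs before the hysteresis fit so gross errors cannot
corrupt it; whether the original analysis ordered these steps the same
way is not documented, and the package treats the order as its own
choice.

## The synthetic-data generator

`simulate_cohort()` exists to give the estimator data whose truth is
known. It instantiates exactly the statistical model the estimator
assumes: judged angle = own-modality endpoint + weight × discrepancy +
hysteresis term + Gaussian noise, with weights and bimodal SDs derived
from the ground-truth $(\sigma_H, \sigma_C, \lambda)$ through the
coupling model itself. Sampling judgments as MAP estimates of noisy
measurements would instead produce trial-to-trial variance different
from the marginal posterior variance; that behaviour is available only
inside `posterior_oracle()`, because parameter recovery must target
the quantities the estimator measures.

Defaults define the simulated study conditions:

* design: 12 participants × 3 visibility conditions × 4 trial types ×
  8 rotations × 10 repetitions (320 trials/session, 6 annotated
  blocks);
* unimodal SDs: $\sigma_H$ = 6° (7° in *DynEnd*), $\sigma_C$ = 3° -
  hand judgments roughly twice as variable as cursor judgments, with
  the hand variability slightly elevated in the condition with the
  longest feedback exposure;
* integration strength: 0.8 (*Dyn*), 0.45 (*End*), 0.8 (*DynEnd*) -
  strong integration with dynamic cursor feedback, partial integration
  with endpoint-only feedback;
* hysteresis offset: −1.75°, the midpoint of the −5.0° to 1.5° range
  such intercept differences span, applied as ±h/2 by start side with
  sides alternating deterministically (guaranteeing balance in small
  samples);
* movement durations: Gaussian around 1.26/1.20/1.29 s (outward) and
  0.45/0.63/0.53 s (endpoint dwell) for *Dyn*/*End*/*DynEnd*, SD = 10%
  of the mean, floored at zero - plausible covariates for the
  duration-versus-integration correlations, not a model of motor
  timing;
* contamination: criterion rates 0.8%/1.0%/0.3%, matching the scale of
  exclusions the screening rules were built around.

True hand endpoints are uniform within ±8° of the instructed direction
(ring frame), cursor endpoints add the rotation, and `UniCursor`
trials replay the endpoint angles of their source `BiCursor` slot (an
independent judgment draw; only endpoint angles matter downstream).
`inject_outliers()` modifies selected trials to violate exactly one
criterion each and records ground-truth flags so filter validation can
match removals against injections exactly.

What the generator does *not* emulate: continuous trajectories and
kinematic cross-correlations, reference-frame transformation noise
(observed bimodal variabilities in real data can exceed the model's
predictions - the generator is model-faithful by design, so passing
recovery tests show estimator correctness, not that real judgments
follow the model), attention or context effects, and inter-participant
heterogeneity unless requested via `lambda_by_participant`.

## Numerical choices and degenerate inputs

* Zero-noise limit: with both unimodal SDs zero the weight ratio is
  taken as 1/2 (equal reliabilities), so $w_H = w_C = \lambda/2$; with
  one SD zero the variance-ratio limit $w_C = \lambda\,\sigma_H^2 /
  (\sigma_H^2 + \sigma_C^2)$ applies. `predict_integration()` treats
  observed variances below 1e-12 deg² as zero, since residual
  variances of exactly linear data are pure round-off.
* The session shuffler repairs replay-constraint violations by
  swapping each offending `UniCursor` slot with a uniformly chosen
  later slot, re-shuffling after 50 fruitless sweeps. Any
  constraint-satisfying order is admissible; uniformity over
  admissible orders is not claimed.
* Degenerate ANOVA tables are flagged, not failed: zero effect sum of
  squares reports F = 0, a zero error stratum with a non-zero effect
  reports F = Inf with `degenerate = TRUE`.
* Pairwise t-tests are uncorrected for multiple comparisons, no
  sphericity correction is applied, and descriptives are mean ± SEM
  with variability reported as SDs (degrees), not variances. These
  conventions are recorded in the pipeline metadata.

## Verification scale

The test suite validates the pipeline at the following sizes, chosen
to make Monte-Carlo error small relative to the asserted tolerances:
the weight-sum identity on 10^4 random parameter sets; oracle
agreement on 25 random draws (plus precision-matrix variance checks on
all 10^4); design properties over 100 seeds; parameter recovery on 500
simulated participants at study scale for each $\lambda_{true} \in
\{0.3, 0.6, 0.9\}$, requiring mean bias of $\hat\lambda$ below 0.01
and weights/variances within 4 Monte-Carlo SEs; and type-I calibration
of the End-vs-Dyn contrast over 100 null cohorts, requiring the
rejection count inside the 99% binomial band around 5%.

## Known limitations

The pipeline analyses endpoint angles only; it cannot reproduce
analyses that need continuous trajectories. The generator's
model-faithfulness means recovery results certify the estimator, not
the model's adequacy for real behaviour. The coupling-prior
formulation is the only observer model implemented; no causal-
inference mixture over common/independent causes and no hierarchical
group-level fitting is provided.
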