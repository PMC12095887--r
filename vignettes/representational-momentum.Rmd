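---
title: "Measuring representational momentum for dynamic emotional faces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring representational momentum for dynamic emotional faces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmfaces)
```

## The phenomenon and the task

Representational momentum (RM) is the systematic forward displacement of the
remembered final state of a dynamic event: observers remember a moving or
changing stimulus as slightly further along its trajectory than it actually
ended. `rmfaces` implements an analysis pipeline for probe-judgement studies
of RM with dynamic facial expressions. An animation morphs an avatar face
from a fully angry (or fully happy) expression to an ambiguous 50/50 blend
over 11 frames; a static probe then shows either the same ambiguous endpoint
or an expression displaced by one, two, or three morph steps, and the
observer judges "equal"/"different" and rates confidence 1-4.

Two coordinates are used throughout. The *physical* continuum indexes the 21
morph images (1 = fully angry, 21 = fully happy, 11 = ambiguous). The
*motion-aligned* coordinate re-expresses probes relative to the animation's
direction of change: 11 is the endpoint and larger values lie further along
the motion, for both emotion conditions. The motion-aligned frame makes a
forward bias positive regardless of whether the animation descended or
ascended the physical continuum, so PSEs from the two emotions are directly
comparable; physical levels are used only for stimulus identity and the
staircase. `motion_to_physical()` converts between the two (identity for
angry-to-ambiguous, `22 - level` for happy-to-ambiguous).

Trials cross 2 Emotion x 2 Avatar Sex x 2 Avatar Identity x 7 Probe x 3
repetitions = 168 analysis trials, preceded by 5 flagged training trials
built from a held-out avatar (the composition of training trials is
unconstrained by the design, so any held-out stimuli work; analysis readers
drop the flag). Frame timing (200 ms endpoints, 80 ms intermediates, 250 ms
mask) and the fixation jitter are carried in the schedule for completeness
but play no role in the analysis.

## The synthetic observer

No generative model of the observer is prescribed by the task itself, so the
package adopts the minimal one that produces the bell-shaped
proportion-"equal" profiles seen empirically. On each trial the remembered
endpoint is `R = 11 + delta + e`, with `delta` the emotion-specific forward
displacement (frames) and `e ~ N(0, sigma^2)` memory noise; the observer
answers "equal" iff `|L - R| < c`, a symmetric interval criterion of
half-width `c`. With probability `lapse` the trial is an attentional lapse
that guesses "equal" with probability 0.5 and draws a uniform confidence
rating — lapses are thereby decoupled from metacognition. This mechanism
integrates in closed form:

p(equal | L) = (1 - lapse) [ Phi((L - mu + c)/sigma) - Phi((L - mu - c)/sigma) ] + lapse/2,

with `mu = 11 + delta`. `equal_probability()` is this expression and serves
as the analytic oracle against which `simulate_trials()` is tested; the
profile is symmetric about `mu` and peaks there, so a positive `delta`
shifts the empirical peak beyond the endpoint exactly as RM does.

Confidence is a cutpoint mapping of the evidence margin `||L - R| - c|`
(distance of the decision variable from the criterion boundary): three
increasing cutpoints (default 0.5, 1.25, 2.25 frames) give ratings 1-4 that
increase with distance from the boundary. RTs are shifted lognormal
(default shift 300 ms, median about 700 ms). Because the shift is above the
250 ms anticipatory cutoff, the synthetic data contain no excludable fast
trials; the exclusion stage is exercised by construction in tests. That is
one of several ways the generator is cleaner than real data — it has no
response biases, no learning or fatigue drift, no key-mapping errors — so
passing tests demonstrate the estimators' correctness under the model, not
robustness to every artefact of real observers.

Default displacements (`delta_happy = 0.35`, `delta_angry = 0.1`) and the
between-participant SD of 1 frame were fixed once from the magnitudes
reported for this paradigm (group PSE means near 11.36 and 11.09 with SE
about 0.11-0.14 at n = 95); `sigma = 1`, `c = 1.5` produce peak "equal"
proportions near 0.7-0.8 with the observed spread. Cohort-level questionnaire
scores are truncated discretised normals within each instrument's range
(SPQ endorsement propensities chosen so totals centre near 18 with SD near
9-10); SPQ item responses are simulated directly so the scorer runs end to
end, with totals bounded in 0..74 by construction.

## PSE and JND estimation

The first-order dependent variables are estimated by fitting a scaled
logistic probability density to the proportion of "equal" responses over
the seven motion-aligned probe levels:

f(L) = 4 A exp(-z) / (1 + exp(-z))^2,  z = (L - mu)/s.

The factor 4 normalises the kernel so the curve's peak equals `A` at
`L = mu`; this keeps `A` interpretable as the peak proportion and bounded in
(0, 1], which is markedly more stable than an unconstrained area parameter.
`mu` is the PSE; `s` the deviation. The loss is unweighted least squares on
the level-wise proportions — the level proportions are what the curve is
defined on — with a binomial-likelihood alternative deliberately left out of
scope. Fitting uses L-BFGS-B from three starts (`s0` in 0.5/1/2, `mu0` at
the empirical peak, `A0` at the max proportion) under bounds `mu` in
[4, 18], `s` in [0.05, 10], `A` in (0, 1]. The `mu` bounds sit three levels
beyond the probed 8..14 range on both sides so that the participant-level
exclusion rule (PSE < 5 or > 16 in either emotion excludes the participant
entirely) remains reachable at both tails. Flat or empty profiles return
`converged = FALSE` and are excluded by the same rule.

The JND derives from the fitted deviation. The default takes the curve's
half-width at half maximum: solving f(L) = A/2 gives
`jnd = s * log(3 + 2 sqrt(2))` (about 1.76 s). The exact published rule for
this derivation is not available, so the method is an explicit, documented
choice, and `jnd_from_fit(..., method = "scale")` reports the raw deviation
instead; every downstream statistic is agnostic to the choice since the two
differ by a constant factor.

`rm_exceeds_jnd()` flags participants whose forward bias `mu - 11` strictly
exceeds their own JND — anticipation beyond one's own discrimination
precision — feeding the 2x2 chi-square against group.

## The staircase

The ambiguity threshold task presents static morphs and asks angry/happy.
Each avatar gets two randomly interleaved transformed two-up/two-down
stairs, one from each pole (levels 1 and 21). The level moves only after two
successive identical responses, by 3 pictures before a stair's first
reversal and 1 afterwards, clamped to [1, 21]; a stair completes after at
least 4 reversals and 5 presentations. Two readings of the movement
direction are possible; the implemented default steps toward the pole
*opposite* the repeated response (two "angry" responses make the stimulus
happier), which is the boundary-seeking behaviour that makes an adaptive
procedure converge. The literal alternative (stepping toward the named
pole) runs away from the boundary and cannot terminate sensibly; it is
available behind `stair_config(literal = TRUE)` for comparison. A reversal
is a sign flip of the realised movement direction — the first movement sets
the direction without counting — and is tagged with the step size of the
movement that produced it, so the first reversal carries step 3 and later
ones step 1.

The threshold is the mean of the step-1 reversal levels pooled over the
avatar's two stairs; starting one stair at each pole symmetrises the
two-down rule's bias so the pooled mean tracks the 50% category boundary
(verified over boundaries 9-13 and categorizer noise 0.5-2 in the test
suite, to within half a level across 200 sessions). The staircase JND is
the sample SD of the same reversal levels — a documented stand-in, since
its published derivation is likewise unavailable.

## The statistical layer

Group splits are by median (scores above the median are "high"; ties at the
median go to "low" by default, configurable, since no tie rule is
prescribed) or by tertiles, where boundary ties resolve toward the discarded
middle group. The 2 x 2 mixed ANOVA (`mixed_anova_2x2()`) uses the classical
two-stratum decomposition: the group effect is tested on subject means
against the between-subject error, the within effect and interaction on
difference scores against the subject-by-condition error, with unweighted
(type III) marginal means so the unbalanced groups a median split produces
are handled as standard ANOVA software handles them. All three effects have
df (1, N - 2); partial eta-squared is SS_effect/(SS_effect + SS_error).
Sphericity machinery is omitted on purpose: a two-level within factor
satisfies sphericity trivially, so a correction can never trigger. Covariate
analyses (`rm_ancova_2level()`) mean-centre the covariate and test the
covariate-by-emotion interaction as the slope of the difference scores on
the centred covariate, the emotion effect as that regression's intercept,
and the covariate main effect on the subject means.

Tukey post hocs use the Tukey-Kramer studentized-range statistic against a
caller-supplied error mean square. The 2x2 chi-square is Pearson's without
continuity correction — the convention under which the published
contingency statistics (0.47 and 0.15) reproduce exactly. The KS normality
check standardises by the sample moments before comparing to the standard
normal; this is conservative and documented, with Lilliefors-style
corrections out of scope. Cronbach's alpha is the variance-ratio formula.
Confidence intervals for Cohen's d are out of scope; point estimates only.

The power module replicates the a priori simulation for the 2x2 mixed
design: each simulated experiment draws per-subject bivariate-normal
condition pairs per group, runs the same ANOVA, and counts rejections at
alpha. The planning cell means (0.45/-0.1 high, 0.2/0.1 low) are defaults;
the per-cell SD and within-subject correlation were part of unpublished
planning assumptions, so they are required inputs with documented defaults
(sd = 1, r = 0.5) and the published 81% figure is not treated as
reproducible — under the defaults the interaction power at 52 per group is
about 62%, and calibration under the null is verified to Monte-Carlo
accuracy instead.

## Problem sizes and numerical choices

The test suite and acceptance checks run at sizes chosen to keep Monte-Carlo
error well below the tolerances they assert: 10^6 draws for the single-point
analytic-vs-simulation check (3 binomial SEs), 8 x 10,000 trials per
displacement for parameter recovery (tolerance 0.1 frames), 1,000-2,000
simulated experiments for type-I calibration (3 MC SEs around alpha), and
200 sessions per staircase condition (tolerance 0.5 levels). The analysis
workflow under `analysis/` simulates 40 participants per group — comparable
to the 46/49 split analysed in this literature — and completes in well under
a minute. Optimiser tolerance (`factr = 1e4`) and the multi-start grid were
fixed once; on noiseless profiles the fit matches a dense grid search to
within its resolution, and the objective value never exceeds the grid
optimum.

## Known limitations

The generative observer is intentionally minimal: Gaussian memory noise, a
symmetric criterion, and cutpoint confidence omit response biases,
serial dependence, asymmetric criteria, and lapse-confidence coupling.
The pooled weighted-confidence aggregation is the default because it is the
direct reading of "proportion of errors times their mean confidence" over
the full trial set and stays on the interpretable 0-4 scale; the per-level
variant is available but the exact published aggregation is unknown. The scorer's SPQ key is synthetic (the published item-to-dimension
map is proprietary to the instrument); real scoring requires supplying the
real key map. None of the estimators are hierarchical: each participant is
fitted independently, which is faithful to the analysis being replicated
but less efficient than a multilevel treatment would be.
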