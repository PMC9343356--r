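---
title: "Methods: the betting game, its observer models, and the analysis battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the betting game, its observer models, and the analysis battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheelbets)
```

## The task and the scoring model

The paradigm probes whether observers can report a probability
distribution over a perceptual variable, not just a best guess.  The
stimulus space is a circular wheel of 360 shapes, one per integer degree,
on which angular distance tracks visual similarity.  On every trial the
observer places six ordered bets; each bet adds a Gaussian component
(sd 4° of wheel space) to a running *uncertainty profile*, and the trial
pays `500 × (profile height at the target)`, up to 200 points.

Two features make the profile a meaningful uncertainty report rather
than a click pattern:

1. **The first bet is twice as tall.**  It is worth double, so the best
   single guess goes first — its error is the natural measure of the
   trial's encoding precision.
2. **Stacking has diminishing returns.**  A component landing at `b` is
   scaled by `1 − y(b)^0.4`, where `y(b)` is the height already drawn at
   `b`.  Piling all bets on one shape is strictly dominated whenever the
   observer has any spread in their beliefs, so a reward-maximizing
   observer *should* draw something like their internal distribution.

### Numerical conventions of the engine

* **Grid.**  Profiles live on 360 bins at integer degrees, bin *i*
  covering `[i − 0.5, i + 0.5)`.  Bet centers are continuous (mouse
  positions are), and components are evaluated exactly at each bin; only
  the stored heights are gridded.  Height lookups (`y(b)`, scoring) read
  the bin nearest the position.
* **Wrapping.**  Components are wrapped Gaussians, summed over ±2
  revolutions.  At the default sd of 4° the wrap mass is far below
  machine precision, but wrapping keeps the engine correct for any sd up
  to the enforced cap of 90°.
* **Penalty semantics.**  The penalty factor is a scalar read at the bin
  nearest the bet center and applied to the whole component — the rule
  scales the *component to be added*, it does not reshape it pointwise.
  The factor is clamped to `[0, 1]`, so a bet can never remove mass.
* **The height ceiling.**  The recursion has an asymptote at height 1:
  provided `first_bet_multiplier × standard_peak ≤ 1` (enforced at
  construction), heights stay below 1 no matter how bets are stacked.
* **The standard peak.**  The points rule fixes everything except the
  height of the unscaled component.  We default to
  `standard_peak = 0.1`: a unit-area Gaussian with sd 4° peaks at
  ≈ 0.0997, 0.1 makes the double-height first bet a round 0.2 (so a
  perfect first bet alone earns 100 points), and six stacked bets then
  score ≈ 199.2 — the printed 200-point maximum up to rounding.  A
  calibrated mode instead solves the scalar stacking recursion
  (`uniroot` to 1e-14) for the peak giving exactly 200
  (≈ 0.10057).  Both normalizations are first-class; which one is active
  is a configuration flag, since the original display units cannot be
  recovered from the points rule alone.
* **Circular conventions.**  Angles are degrees everywhere; signed
  errors live in `(−180, 180]` with positive = clockwise, and the
  antipodal tie resolves to +180 by convention.  The circular mean is
  the direction of the vector resultant; when the resultant length falls
  below 1e-8 (e.g. two bets exactly 180° apart) the mean is *undefined*
  and the package signals an error rather than guessing — affected
  trials are excluded, with a warning, by the analyses.  Cumulative
  averages weight all bets equally: the worked `+10°, −4° → +3°` example
  that defines the analysis is an unweighted mean, and the double points
  of bet 1 concern reward, not estimation.

## The observer models (what the generator emulates)

`simulate_trial()` draws, per trial: an encoding error
`ε ~ N(0, encoding_sd)` (circular), giving the internal center
`m = target + ε`; a per-trial internal width `w`; and the six bets:

* **sampling** — every bet, including the first, is an independent draw
  from the internal distribution `(m, w)`; bet *k* gets additional
  motor/decay noise of sd `bet_noise_growth × (k − 1)`.
* **discrete** — bet 1 is exactly `m`; bets 2–6 are `m` plus symmetric
  scatter of width `w` (plus the same growth noise), with `w` drawn
  independently of `ε`.
* **discrete_confidence** — as discrete, but `w` mixes an independent
  draw with a term proportional to `|ε|` (weight `confidence_coupling`),
  emulating a scalar confidence signal that tracks the trial's true
  error.

Any bet is replaced by a uniform mis-click with probability
`lapse_rate`; with the undo mechanic enabled, a lapsed bet may be erased
(recorded) and re-placed, at most once per trial — undone bets therefore
sit near the 90° chance error while their replacements look like
ordinary bets.

Skew (for the sampling observer) is implemented as a two-component
mixture: with probability 0.3 a draw is offset by `2 w × skew`.  Nothing
hinges on this particular mechanism; any asymmetric internal
distribution shared by all six bets produces the flip-sensitive KS
signature, and the mixture is the simplest such device.

Circular noise is wrapped normal by default — at the widths involved
(≤ ~30°) it is indistinguishable from a von Mises of matched
concentration — with a von Mises switch (`noise = "vonmises"`, Best &
Fisher rejection sampler) for robustness checks.

**Defaults.**  `encoding_sd = 12°`, `internal_sd_mean = 10°`,
`internal_sd_spread = 3°`, `bet_noise_growth = 2°/bet`,
`lapse_rate = 0.004`, cohort 40 × 150 with ±20% multiplicative
participant heterogeneity.  These were chosen once to place group mean
first-bet error in the mid-teens of degrees with chance at 90°, i.e. the
performance regime of human observers in this kind of brief-masked
continuous report, and they are configuration values, not claims about
any particular dataset.  Reproducibility is hierarchical: a master seed
spawns per-participant seeds, which spawn per-trial seeds, so extending
a cohort never perturbs existing trials.

**What the generator does not emulate:** response timing and mouse
kinematics, stimulus rendering and pixel noise, sequential effects and
learning across trials, and serial dependence between trials.  Passing
the discrimination tests on this synthetic world shows the *analyses*
separate the accounts under realistic noise; it cannot show which
account describes human data.

## The analysis battery and its design choices

**Spread–error correlations.**  Per participant, the Pearson correlation
across trials between `|bet-1 error|` and a spread measure — the median
absolute adjacent-bet distance by default, or the sd / IQR of the drawn
profile about the target — is Fisher-z transformed and the z's tested
against zero.  Pearson (not circular) correlation is deliberate: both
variables are nonnegative linear magnitudes.  Participants with zero
variance in either variable have no defined correlation and are excluded
with a warning.  One subtlety found while validating the battery:
mis-click lapses induce a small *positive* correlation even for the
fixed-spread discrete observer, because a lapsed first bet inflates both
the trial's error and its adjacent-bet spread.  A clean independence
null therefore requires a lapse-free discrete cohort, and that is what
the test suite uses; with lapses on, the discrete observer's small
positive mean z is a real property of the paradigm, not a bug.

**Profile-vs-error KS.**  Each trial's profile is circle-shifted to put
the target at 0 and averaged binwise; the across-trial distribution of
first-bet signed errors is compared to this average profile with a
Kolmogorov–Smirnov test.  Comparing a sample against a binned density
requires a choice; the default draws a *deterministic pseudo-sample*
from the normalized profile by inverse CDF at quantiles
`(i − 0.5)/n` — same size as the error sample, fully reproducible —
followed by a standard two-sample KS test (asymptotic p).  A one-sample
variant against the profile's piecewise-linear CDF is available
(`variant = "cdf"`) for sensitivity analysis.  The *flipped* control
mirrors the profile about the aligned target before comparing
(`flip_axis = "bet1"` mirrors each trial's profile about its first bet
instead — the two axes answer slightly different symmetry questions, and
both are provided because the choice is genuinely underdetermined).

Because every trial's first bet contributes to *both* the error sample
and the averaged profile, the all-trials comparison shares sampling
noise between its two sides.  That dependence slightly favors the
unflipped orientation — enough that, with 40 participants, a paired test
can declare even a perfectly symmetric observer "flip-sensitive".  The
`split = "half"` option takes the error sample from odd trials and the
profiles from even trials, removing the dependence; it is the right
instrument when the flip effect itself is the question, and it is what
the discrimination tests use.  The default remains `split = "none"`,
which mirrors the original form of the analysis and maximizes the data
on each side.

**Bet-order curves.**  Per participant, mean `|error|` of each
individual bet, and of the running circular mean of bets 1..k, each
submitted to a classical one-way repeated-measures ANOVA
(`aov` with a subject error stratum; df `(k−1, (k−1)(n−1))`; no
sphericity correction).  Two eta-squared conventions are reported:
`SS_effect / (SS_effect + SS_error)` as the headline value, and the
total-variance version including the subject stratum, since reporting
conventions differ across software.  The discriminating contrast is
cumulative bet-6 error vs bet-1 error, tested pairwise across
participants.  On the individual curve, note that under the default
growth noise the expected bet-1 → bet-2 increment is only ≈ 0.1°,
comparable to Monte-Carlo error at a 40 × 150 cohort; the package's
tests therefore treat "error rises with bet order" as a positive
per-participant linear trend (with strict step-wise monotonicity
accepted when observed), rather than asserting that six noisy sample
means happen to be perfectly ordered.

**Undo summary.**  Usage rate, error of undone bets vs their
replacements, and usage by bet index.  Under lapse-driven undos the
undone bets sit near 90° (uniform clicks) while replacements match
ordinary bet error — the pattern expected if undos correct mis-clicks
rather than revise genuine responses.

## Problem sizes and test design

The unit tests run on small cohorts (4–12 participants, tens of trials)
where the qualitative fingerprints are already unambiguous; the
end-to-end discrimination tests use the full 40 × 150 design with a
fixed seed, which runs in well under a minute.  Statistical primitives
are verified against independent brute-force oracles (longhand scalar
stacking recursion; exhaustive ECDF enumeration for KS D; raw
sums-of-squares ANOVA; covariance-formula correlation) on small
fixtures, and the Monte-Carlo chance level of 90° is checked at 10⁶
draws.

## Known limitations

* The engine models scoring, not interaction: no motor timing, preview
  dynamics, or click-guard rules.
* Observer models are generative stand-ins defined by this package, not
  fits to any human dataset; an import adapter for real trial-level CSV
  data exists (`read_dataset()`), but model *fitting* is out of scope.
* The KS p-values are asymptotic; with ~150 trials per participant that
  is the standard regime, but exact small-sample p-values are not
  provided.
* The discrete-confidence coupling is linear in `|ε|`; real confidence
  is surely noisier, which would only weaken (not reverse) the
  spread–error correlation it produces.
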