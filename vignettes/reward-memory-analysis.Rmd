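---
title: "Modelling location memory under reward anticipation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling location memory under reward anticipation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilmem)
```

## The scientific problem

Continuous-report memory tasks ask a participant to reproduce a studied
feature — here, a location on a circle — rather than to recognise it. The
signed reproduction error carries more information than a hit/miss score:
its distribution is a mixture of trials where retrieval succeeded (errors
clustered tightly around zero) and trials where it failed (errors uniform
on the circle). When the study phase additionally manipulates reward
anticipation and records pupil diameter, the same dataset supports three
linked questions: did the reward manipulation engage arousal (reaction
times, anticipatory pupil dilation), did it change the *probability* of
remembering, and did it change the *fidelity* of what was remembered?

`pupilmem` implements that full analysis chain, together with a
synthetic-data generator that produces data with exactly the statistical
structure the analysis assumes, so every stage is testable end to end
without access to any particular dataset.

## The mixture model

Errors `x = wrap(response − target)` in radians are modelled as

$$p(x) = (1 - p_u)\,\varphi_\kappa(x) + p_u \frac{1}{2\pi},$$

with $\varphi_\kappa$ a zero-mean von Mises density
$e^{\kappa\cos x} / (2\pi I_0(\kappa))$. The two reported parameters are
memory success $p_t = 1 - p_u$ (probability of successful retrieval,
unitless, in [0, 1]) and memory precision $\kappa$ (von Mises
concentration, unitless, ≥ 0; at $\kappa \gtrsim 4$ the component's
circular SD is roughly $1/\sqrt{\kappa}$ radians).

**Estimation.** `fit_mixture()` maximises the log-likelihood over
$(p_u, \kappa)$ on the transformed scale $(\mathrm{logit}\,p_u,
\log\kappa)$, which makes the box constraints smooth for the L-BFGS-B
inner optimiser. Nine deterministic starts ($p_u \in \{0.2, 0.5, 0.8\}
\times \kappa \in \{2, 8, 32\}$) guard against the likelihood's ridges;
the best converged start wins, and an all-starts failure is an error, not
a silent fallback. $\kappa$ is bounded to [0.5, 500]: below 0.5 the
component is near-indistinguishable from uniform (the $p_u$/$\kappa$
identifiability degeneracy), above 500 the data would have sub-degree
noise no continuous-report task produces. The per-trial density is floored
at the smallest normal double so the log-likelihood is always finite.

**Known small-sample behaviour.** At ~42 trials per cell (the scale of a
six-block session split by condition) the MLE of $\kappa$ is noticeably
variable and slightly biased upward, and $p_t$ estimates carry an upward
bias of roughly +0.01 to +0.02. The recovery tests report the observed
$\kappa$ bias rather than hiding it; analyses at this scale should treat
participant-level $\kappa$ with corresponding caution (which is also why
the estimate-level outlier screen exists).

**Trial-level classification.** The crossover threshold solves
$(1-p_u)\varphi_\kappa(x^*) = p_u/(2\pi)$ by bracketed root-finding
(`uniroot` on (0, π), tolerance 1e-10). By default it is computed from the
fit to errors pooled across participants and conditions, so that every
trial is judged against one common density ratio; condition-wise
thresholds can be computed by fitting per condition, but are not the
default. Degenerate fits return sentinels: `Inf` when the von Mises
component dominates the entire circle (every trial correct), 0 when it
dominates nowhere. A tie at the threshold counts as correct. Trial
precision is `1/|error|` (1/degrees) for correct trials; absolute errors
below 0.5° are capped at 0.5° so a zero-error trial maps to precision 2
rather than infinity — the cap sits below the resolution at which such
tasks distinguish responses.

## Behavioural quality control

Three rules, applied in this order by `run_pipeline()`:

1. **Chance-level exclusion** (`exclude_chance_participants()`): mean
   absolute error ≥ 75° excludes the participant (uniform guessing has
   expected absolute error 90°). The threshold is inclusive.
2. **Misclassified study trials** are removed once, centrally: only trials
   whose study-phase item classification was correct enter mixture fitting
   and pupil analyses.
3. **Minimum trial count**: a participant left with fewer than 10 trials
   in either condition after rule 2 is excluded from model fitting. The
   exact count behind "too few trials" in such experiments is a judgement
   call; 10 per condition is the package default and is configurable.

The estimate-level screen (`detect_outlier_estimates()`) flags fitted
parameters more than 2.5 *sample* standard deviations (n − 1 denominator)
from their condition mean; it feeds a sensitivity re-analysis, not an
automatic exclusion.

## Pupil preprocessing

The chain is fixed: foreshortening hook → blink interpolation → zero-phase
low-pass → epoching → QC → baseline correction.

- **Foreshortening correction** (gaze-angle-dependent apparent pupil-size
  change) is a pass-through hook: specialised external tooling performs
  the geometric correction, and `correct_foreshortening()` accepts either
  a corrected trace or a user function.
- **Blink interpolation** replaces samples from 100 ms before blink onset
  to 400 ms after offset with linear interpolation between the nearest
  valid neighbours; edge blinks extend the nearest valid value.
  Interpolated samples stay flagged and count as *invalid* for epoch QC —
  they carry no measurement information.
- **Filtering**: 10-Hz fourth-order Butterworth, forward–backward for zero
  phase. `signal::filtfilt` zero-pads internally, which drags trace edges
  toward zero; `lowpass_pupil()` therefore wraps the pass in odd-reflection
  padding (2 s), restoring exact DC gain and clean edges. Traces shorter
  than 27 samples are rejected by name.
- **Epochs** (0.2-s windows, half-open `[start, start + 0.2)`, 8 samples
  at 40 Hz): pre-item (0.2 s before item onset), choice (0–0.2 s after the
  choice display, minus the pre-item mean — exact subtraction, so adding a
  constant to a trace shifts pre-item but leaves choice untouched), and
  the anticipation *change* (final minus first 0.2 s of the anticipation
  period). The change measure needs both sub-windows to pass QC.
- **Epoch QC**: > 50 % invalid samples excludes the epoch (exactly half is
  retained); surviving epochs have samples > 3 SDs from the epoch mean
  removed in a single pass before averaging. The screen runs after
  interpolation, on the filtered trace — the interpolated values are the
  ones actually averaged, so they are the ones screened. Manual artifact
  checking is replaced by an optional, deterministic amplitude-jump
  heuristic (`despike_jump_mm`), off by default.

## Statistics

Condition contrasts use classical two-tailed paired t-tests plus the JZS
Bayes factor: the marginal likelihood under a Cauchy(0, r = 0.707) prior
on standardised effect size, evaluated by adaptive quadrature of the
g-prior mixture integral (relative tolerance 1e-10); the test oracle
recomputes it through the independent noncentral-t route. Zero-variance
differences are an error — a t statistic of 0/0 is undefined, and
reporting t = 0 would silently overstate the evidence.

The trial-level pupil–behaviour associations in such studies are usually
fit with mixed-effects models; those fits are deliberately delegated to
dedicated tools (`run_pipeline()` exports tidy trial tables ready for
them). The package's own tested summary is the transparent two-stage
version: per-participant OLS slopes, then a one-sample t-test across
participants. It is less efficient than a random-slope model but has no
convergence knife-edges and its sampling behaviour is fully checkable
against closed-form OLS.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions the pipeline targets:
36 participants; 84 trials in six blocks of 14, conditions balanced within
block; targets on a 4°-step circle consumed from shuffled 90-angle cycles
with the paired dot 180° away; fixation 3–6 s and anticipation 2–4 s
uniform; mixture parameters $p_t$ 0.58/0.55 and $\kappa$ 13.67/17.02
(reward/neutral); item-classification accuracy 0.93; 40-Hz pupil traces
with baseline 3.5 mm, anticipatory dilation ramps of mean 0.10/0.03 mm
(trial SD 0.40 mm), white noise 0.05 mm and slow sinusoidal drift;
reaction times 422 ms (reward offset −44 ms) coupled to the anticipatory
change at −30 ms/mm with 60 ms noise; blinks at 0.10 Hz lasting
100–400 ms, a rate chosen so that post-QC epoch retention lands in the
high-80 % range typical of chinrest eye-tracking; and an adaptive deadline
staircase targeting 70 % positive feedback.

The staircase form is asymmetric-step: after positive feedback the
deadline tightens by $(1 - p^*)\,s$, after negative feedback it relaxes by
$p^*\,s$ (target $p^* = 0.7$, budget $s = 30$ ms, start 400 ms, clamped to
[200, 1500] ms). The zero-drift equilibrium of this walk is exactly the
target rate for any stationary RT distribution, and the start/step values
let a single 42-reward-trial session reach the high-60s already. Reward
trials pay +15c when the response is both correct and inside the deadline,
−10c otherwise; neutral trials always pay 0c.

The anticipatory dilation ramp is flat over the first and final 0.2 s of
the anticipation window, so the late-minus-early change measure recovers
the drawn amplitude exactly in the noise-free limit; real pupil responses
are smoother, but the analysis only consumes the two 0.2-s window means.
Von Mises draws use the Best–Fisher rejection sampler. Old/new recognition
decisions, confidence ratings and lure items are outside the generator's
scope (lure responses are not analysed in this paradigm), as are gaze
position, saccades and foreshortening geometry.

Passing recovery tests on these synthetics therefore demonstrates that the
estimation and preprocessing machinery is correct *given the model*; it
does not certify the model against real data with swap errors, non-uniform
guessing, pupil responses to luminance, or non-stationary RTs.

## Problem sizes and reproducibility

Every simulation function takes its seed from `SimConfig` (streams offset
per stage), so identical configurations reproduce identical tables and
files byte for byte. The test suite runs recovery at the scales the
analyses themselves use — 35 participants × 42 trials for mixture
recovery, 200 replicate datasets for the calibration property, 10⁴ trials
for staircase convergence and tail-mass checks, 60 replicate runs for the
type-I property of the condition contrast — sizes at which the Monte-Carlo
error of each check is comfortably below its asserted tolerance.

## Known limitations

- No swap/misbinding component in the mixture (responses drawn to the
  paired dot would inflate apparent guessing); no hierarchical shrinkage
  across participants.
- $\kappa$ at ~42 trials is noisy; between-condition precision contrasts
  at this scale have limited power, which the recovery tests quantify.
- The pupil generator is additive-Gaussian with linear ramps; it does not
  emulate pupil impulse-response dynamics, luminance responses, or
  gaze-dependent foreshortening.
- Mixed-effects and fully Bayesian regression modelling are exported-table
  territory, not in-package fits.
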