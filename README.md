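# pupilmem

Analysis tools for continuous-report location-memory experiments with
concurrent pupillometry under reward-induced arousal.

In this class of experiment, participants study items placed on a circle
while a cue signals whether a fast response can earn money, and later
reproduce each item's location by clicking on the circle. Recall quality is
a *graded* circular error rather than a binary hit, and phasic arousal is
tracked through the pupil. `pupilmem` is aimed at cognitive-neuroscience /
psychophysics researchers who need the full chain for such designs:
a synthetic-data generator emulating the task, the mixture decomposition of
recall errors, pupil preprocessing and event epoching, and paired-design
statistics with default Bayes factors.

## The model

Signed recall errors θ̂ − θ (response minus target, wrapped to
(−180°, 180°]) are modelled as a two-component mixture:

    p(θ̂) = (1 − p_u) · φ_κ(θ̂ − θ) + p_u · 1/(2π)

where φ_κ is a zero-mean von Mises density with concentration κ and p_u is
the proportion of uniform guesses. Two interpretable parameters result:

- **memory success** `p_t = 1 − p_u` — the probability that a location was
  retrieved at all;
- **memory precision** `κ` — how tightly successful retrievals cluster
  around the target.

Parameters are estimated by multi-start maximum likelihood
(`fit_mixture()`). Trial-level classification uses the density-ratio
crossover of the aggregate fit (`crossover_threshold()`): a trial is
"correct" when its error is more likely under the von Mises component than
under the uniform one, and trial precision is the inverse absolute error of
correct trials.

The pupil side implements the standard preprocessing chain — blink
interpolation (100 ms pre / 400 ms post widening), 10-Hz fourth-order
zero-phase Butterworth filtering, event epoching (pre-item, choice,
anticipation), per-epoch QC (> 50 % invalid exclusion, 3-SD sample
removal) and pre-item baseline correction — and the statistics side
provides paired t-tests with JZS Bayes factors (Cauchy prior, r = 0.707)
and transparent two-stage per-participant regression summaries.

## Worked example

```r
library(pupilmem)

run <- run_pipeline(sim_config(n_participants = 8, seed = 42))
run
#> <pupilmem_run>
#>   8 participants, 672 trials (seed 42)
#>   excluded: 0 at chance, 0 with too few trials
#>   aggregate fit: p_t = 0.538, kappa = 16.95, threshold = 31.4 deg
#>   positive feedback on reward trials: 66.1%
#>   contrasts:
#> # A tibble: 4 x 5
#>   measure           mean_diff t_stat  p_value   bf10
#>   <chr>                 <dbl>  <dbl>    <dbl>  <dbl>
#> 1 p_t                 -0.0283  -1.06 0.323     0.525
#> 2 kappa               -5.46    -1.52 0.171     0.786
#> 3 rt_ms              -37.2     -5.62 0.000801 49.4
#> 4 anticip_change_mm    0.0890   2.61 0.0349    2.49
```

Reading the output: the aggregate mixture fit estimates that ~54 % of
trials were successful retrievals with concentration ~17, which puts the
correct/incorrect crossover at ±31° of error. The reward manipulation
shows up where it should — reaction times are ~37 ms faster and the
anticipatory pupil dilation ~0.09 mm larger on reward trials (strong and
anecdotal-to-moderate Bayes-factor evidence respectively) — while memory
success and precision do not differ between conditions at this sample
size. The trial-level coupling is summarised by the two-stage regression:

```r
run$rt_pupil$group
#> # A tibble: 1 x 8
#>   term                  n mean_slope   sem t_stat    df p_value  bf10
#> 1 anticip_change_mm     8      -35.0  7.17  -4.87     7 0.00180  25.6
```

i.e. reaction time drops by ~35 ms per mm of anticipatory dilation
(generative value −30). Individual pieces compose with pipes:

```r
cfg    <- sim_config(n_participants = 8, seed = 42)
trials <- generate_design(cfg) |> simulate_recall(cfg)
fit    <- fit_mixture(deg2rad(trials$error_deg[trials$classified_correct]))
fit
#> <mixture_fit> p_t = 0.538, kappa = 16.95 (loglik -814.54, n = 628)
glance(fit)      # one-row tibble; tidy(fit) for long form
autoplot(fit)    # mixture density over the error circle
```

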