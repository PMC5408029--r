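# gravobs

An ideal-observer simulation of how a strong internal prior on gravity can
rescue the perception of an otherwise ambiguous visual scene.

## The problem

An observer watches a ball fly toward them on a parabolic path and must judge
its horizontal velocity — a quantity the retina never senses directly. What
the visual system *can* measure are two optical variables: the elevation angle
γ (the angle between straight-ahead gaze and the line of sight to the ball)
and its rate of change γ̇. For a head-on symmetric parabola with gravity *g*
and constant horizontal speed *v*ₕ,

    γ(t)  = arctan( g·t / (2·vₕ) )
    γ̇(t) = 2·g·vₕ / (g²·t² + 4·vₕ²)

Both variables depend on gravity and horizontal speed only through their
ratio, so many (g, vₕ) pairs produce *identical* optics: the stimulus is
fundamentally ambiguous. A Bayesian observer can break the ambiguity with a
prior over gravity — and because terrestrial gravity has been constant over
evolutionary time, that prior can be very sharp (a "strong prior",
σ = 0.5 m/s² here).

`gravobs` simulates the full encoding/decoding loop:

1. **Trajectory family** — 56 parabolas (velocities 3–10 m/s × gravities
   0.7g–1.3g with 1g = 9.820 m/s²), observed for 0.2 s.
2. **Population encoding** — each optical value drives a bank of Gaussian
   tuning curves (11 peaks on [0, 1.0] rad for γ; 15 peaks on [0.1, 2.2] rad/s
   for γ̇; SD 0.1) whose spike counts carry independent Poisson noise.
3. **Decoding** — velocity is read out over the 56 candidate trajectories by
   maximum likelihood alone, or by a MAP rule adding the log density of a
   Gaussian gravity prior N(μ_g, σ²) at each candidate's gravity.
4. **Experiment** — 1000 seeded trials at 1g, summarized as the fraction of
   exactly correct velocity decisions, swept over the assumed prior mean.
   Conjugate Gaussian prior–likelihood fusion is included for the continuous
   strong-prior picture.

## Worked example

```r
library(gravobs)

# the worked stimulus: gamma_dot 0.2 s into a 6 m/s parabola under 1g
tr <- trajectory(9.820, 6)
round(elevation_rate(tr, 0.2), 3)
#> [1] 0.797

# encode it on the gamma_dot bank and decode by grid MLE
sim <- build_simulation()           # default study conditions
r   <- encode(sim$banks$gamma_dot, 0.797, seed = 99)
mle_decode(sim$banks$gamma_dot, r)
#> [1] 0.783

# many trajectories are compatible with that estimate (10% margin):
nrow(match_candidates(trajectory_grid(), 0.797, 0.2, "gamma_dot")$members)
#> [1] 10

# 1000 trials: the strong prior rescues the velocity judgment
rec <- run_trials(1000, sim$grid, sim$banks, sim$prior, t = 0.2, seed = 1)
summarize_trials(rec)
#>   decoder  variable    n n_correct fraction          se
#> 1     mle     gamma 1000       304    0.304 0.014545927
#> 2   bayes     gamma 1000       778    0.778 0.013142146
#> 3     mle gamma_dot 1000       461    0.461 0.015763217
#> 4   bayes gamma_dot 1000       989    0.989 0.003298333
```

Without a prior, maximum likelihood recovers the correct velocity on fewer
than half the trials — the γ̇ value simply does not identify the trajectory.
Adding a strong prior centered on the true gravity lifts γ̇-based decoding to
99% correct (and γ-based decoding, inherently more ambiguous, to 78%). Sweeping
the assumed prior mean away from 1g collapses performance back toward the 1/8
chance level:

```r
sw <- prior_sweep(round(seq(0.7, 1.3, 0.05) * 9.820, 4), 0.5, 1000,
                  sim$grid, sim$banks, seed = 1)
plot_sweep(sw)   # fraction correct vs assumed prior mean, peaked at 9.82
```

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","gravsim.R", package="gravobs"))')" \
    simulate --trials 1000 --seed 1 --out results/
```

Subcommands: `simulate`, `sweep`, `check-ranges`, `make-fixtures`. Every run
writes a JSON provenance block (config, config hash, seed) so results are
exactly reproducible.

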