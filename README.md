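# freqdep

Bayesian inference for frequency-dependent social learning in binary
choice experiments.

## The problem

In demonstrator–observer experiments, an observer animal watches two
groups of demonstrators exploit two options (here: a black and a white
feeder) and then makes its own first choice. The scientific question is
*what* the observer copies: the **majority of individuals** (conformity),
or the **majority of behavioural instances** such as feeding activity
(public information use) — and whether the response is *conformist*
(disproportionate adoption of the majority option, a sigmoidal
frequency-response curve that stabilizes traditions) or *anti-conformist*
(majority options favoured less than proportionally).

`freqdep` implements the full inference chain for this question:

- the observer's first peck at the black feeder is Bernoulli with

  ```
  logit(p) = β₁ + β₂ · black_side + β₃ · f(X)
  f(X)     = X + c·X(1−X)(2X−1) − 0.5
  ```

  where `f` is the Boyd–Richerson conformist-transmission function, `X`
  is the proportion of demonstrator activity at the black feeder, and the
  shape parameter `c` distinguishes conformist (`c > 0`), linear
  (`c = 0`) and anti-conformist (`c < 0`) responses;
- `X` is one of three candidate predictors — the proportion of
  demonstrator **birds**, **visits**, or **pecks** at the black feeder —
  selected by a categorical indicator `m` whose posterior weights
  measure the predictors' relative predictive power;
- priors: `β₁..₃, c ~ Normal(0, precision = 0.1)` (sd √10),
  `m ~ Categorical(⅓, ⅓, ⅓)`;
- posterior sampling by Metropolis-within-Gibbs (random-walk updates for
  the continuous parameters, a closed-form categorical update for `m`),
  with split-R̂ and effective-sample-size convergence gating (minimum
  3000 effective samples from 3 chains, R̂ upper bound ≤ 1.01);
- a seeded trial simulator reproducing the experimental design
  (majority:minority demonstrator ratios 1:2, 2:4, 3:3, 1:5,
  counterbalanced feeder colour and cage side, single-sex trials) with a
  known generative truth, so the whole chain is validated by parameter
  recovery.

The package is aimed at behavioural ecologists analysing two-option
social-learning experiments and at methodologists studying
frequency-dependence estimators.

## Worked example

Simulate a 66-trial experiment with an anti-conformist pecks-driven
truth, then fit the pecks model:

```r
library(freqdep)

truth <- model_parameters(beta1 = -0.51, beta2 = 0.28, beta3 = 4.35,
                          shape = -3.79, measure = "pecks")
sim <- simulate_dataset(design_spec(n_trials = 66), activity_spec(),
                        truth, seed = 1)

cfg <- mcmc_config(n_iter = 20000, n_burn = 5000, seed = 1,
                   target_min_ess = 0)
fit <- fit_fixed(sim$trials, "pecks", config = cfg, override = TRUE)
fit
#> posterior summary [fixed:pecks], 66 trials
#>  parameter median       95% CCI
#>      beta1  -0.31 [-1.02, 0.38]
#>      beta2  -0.01 [-0.98, 0.96]
#>      beta3   0.35 [-2.90, 5.34]
#>          c  -1.84 [-5.80, 4.62]
#> indicator weights: birds 0.00, visits 0.00, pecks 1.00
#> convergence: PASS
```

Each row is the pooled-chain posterior median with its 95% central
credible interval: `beta1` is the baseline (log-odds) preference for the
black feeder, `beta2` the side-of-cage effect, `beta3` the weight of the
social-information term and `c` its shape (negative medians point toward
anti-conformity; at n = 66 the intervals are wide, as expected). The
three predictors are strongly collinear in this design:

```r
round(collinearity_report(sim$trials), 2)
#>        birds visits pecks
#> birds   1.00   0.94  0.94
#> visits  0.94   1.00  0.97
#> pecks   0.94   0.97  1.00
```

which is why relative predictive power is assessed with the indicator
(`fit_joint()`) rather than by including all three predictors at once.
`fit_pair()` fits the two-predictor supplements, `response_curve()`
produces median/95%-interval frequency-response curves, and
`recovery_experiment()` runs simulate–fit–score replicate studies.

A command-line front-end over the same functions (subcommands
`simulate`, `fit`, `curve`, `recover`, `collinearity`) is installed at
`inst/cli/freqdep-cli.R`; all its outputs are byte-reproducible given
`--seed`.

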