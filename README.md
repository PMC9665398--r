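# dcewtp

Hierarchical Bayesian willingness-to-pay analysis for surveys on
driverless-car collision ethics.

## What problem this solves

Driverless cars must be programmed how to respond to unavoidable
collisions — save the most lives, the occupants, or the pedestrians. If one
algorithm is mandated for all cars, consumers who dislike it may not buy a
driverless car at all, and depressed uptake of (much safer) driverless cars
can cost more lives than the mandate saves. The decisive quantity is how
much a buyer's preferred algorithm is worth in money. `dcewtp` is for survey
researchers studying that question with a discrete-choice experiment (DCE):
participants repeatedly pick between two cars differing in collision
program and price, and a hierarchical Bayesian probit model converts those
choices into willingness-to-pay (WTP) premiums.

## The model

For cars A and B with prices in £k and program utilities
`Prog ∈ {0 (save-the-most, reference), Occ, Ped}`:

    ΔU(A,B) = (Price_B − Price_A) + (Prog_A − Prog_B)
    p_AB(A) = Φ(τ · ΔU(A,B))            # inverse probit link
    choice  ~ Bernoulli(p_AB(A))

Each individual i has its own (Ped_i, Occ_i, τ_i) drawn from population
normals `N(HPed, 1/Ht)`, `N(HOcc, 1/Ht)`, `N(Hτ, 1/Ht2)`, with hyperpriors
`HPed, HOcc ~ N(0, 10)` and `Hτ, Ht, Ht2 ~ Gamma(1/2, 1/2)`. The WTP
premium of a program is `−1000 ×` its population utility (in £): positive =
the population would need that discount to accept the program instead of
save-the-most. Estimation is by a Metropolis-within-Gibbs sampler with
classic Gelman–Rubin R-hat diagnostics and highest-density intervals.
Around the core model sit the 36-scenario choice design, CSV survey
readers/writers, a seeded synthetic-survey generator, McNemar–Bowker
symmetry tests of framing effects, Likert willingness summaries, and an
end-to-end pipeline with parameter-recovery experiments.

## Worked example

Simulate a UK-sized survey at the shipped population preset, fit the model,
and read off the premiums:

```r
library(dcewtp)

scen <- generate_choice_design()          # 36 scenarios, 9 offers
pop  <- population_preset("uk-paper", seed = 1)
ind  <- draw_individuals(pop)             # 186 individuals
rec  <- simulate_choices(ind, scen, seed = 2)

post <- sample_posterior(rec, scen,
                         model_config(n_chains = 3, n_samples = 4000,
                                      n_burnin = 1000, seed = 1))
summarise_posterior(post)
#>   parameter         mean    hdi_lower  hdi_upper     rhat
#> 1      HPed -10.62462569 -11.29879878 -9.9323095 1.002118
#> 2      HOcc  -2.85751396  -3.40741489 -2.2829133 1.000851
#> 3      Htau   0.29991427   0.27197199  0.3270521 1.002905
#> 4        Ht   0.09905655   0.07531778  0.1241539 1.006446
#> 5       Ht2  43.57494266  31.59977746 55.5946242 1.000805

wtp_report(post)
#> Willingness-to-pay premiums (GBP; positive = disfavoured vs MOST)
#>      program premium hdi_lower hdi_upper
#>         MOST       0         0         0
#>  PEDESTRIANS   10625      9932     11299
#>    OCCUPANTS    2858      2283      3407
#> P(individual sensitivity < 0 | hierarchy): 0.025  [FLAG: > 1% mass below 0]

posterior_predictive_check(post, rec, scen)$hit_rate
#> [1] 0.8982975
```

Read: a pedestrian-programmed car needs a discount of about £10,600 before
this (simulated UK) population accepts it over a save-the-most car, an
occupant-programmed car about £2,900; the generating truths were £10,700
and £3,170 and both sit inside the 95% HDIs. The model predicts about 90%
of the individual decisions it was fitted to. (The sensitivity flag notes
the fitted hierarchy puts slightly over 1% mass on negative individual
sensitivities — a known mild over-dispersion of the sensitivity hierarchy
at this design depth; see the methods vignette.) `preference_battery()`
runs the framing and willingness tests on the categorical and Likert
tables.

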