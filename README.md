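# groupcmr

Bayesian closed-population capture–mark–recapture (CMR) abundance
estimation for species that live in stable social groups — mountain
gorillas being the motivating case — where an individual can only be
detected after its group has been detected. Ignoring that dependence, as
the conventional closed CMR model does, yields abundance estimates whose
credible intervals are deceptively narrow: they miss the true abundance
roughly half the time. `groupcmr` implements a hierarchical **Two-Step**
estimator that models group detection and individual detection separately,
restoring honest interval coverage, and ships the conventional **One-Step**
model, a group-structured capture-history simulator, and a Monte-Carlo
study harness for comparing the two.

Intended users: wildlife statisticians and survey biologists analysing
sweep-style nest/den surveys (non-invasive genetic CMR) of group-living
taxa — great apes, canid packs, lion prides, elephant herds.

## The model

A survey comprises `K` sweeps of the study area; within a sweep, each
detected group is followed to `T` nest sites, at each of which every group
member may be sampled.

**Step 1 — groups.** Sweep-level group detections with data augmentation:

    W_gk ~ Bernoulli(z_g · p_g),   z_g ~ Bernoulli(ψ_g),   g = 1..M

The number of groups is `G = Σ z_g`.

**Step 2 — individuals within detected groups.** With per-occasion
detection probability `p_i` zeroed in sweeps where the group was missed,
an individual is detected at least once with probability
`p* = 1 − Π_k (1 − p_i·W_gk)^T`. The collection of observed individual
histories in group `g` is conditional-multinomial with cells equal to
their Bernoulli products divided by `p*`, and the number of observed
members is zero-truncated Binomial:

    n_g ~ ZTBinom(m_g, p*),   m_g ~ ZTPoisson(λ)

Sizes of included never-detected groups are draws from `ZTPoisson(λ)`;
total abundance is `N = Σ m_g` over included groups. A variant adds
solitary individuals with their own detection probability `p_s` and
augmentation (`N = Σ m_g + S`). Priors: uniform(0,1) on all probabilities,
uniform(0,30) on `λ`. Inference is Gibbs sampling with slice updates for
`p_i` and `λ` (Rcpp backend), with Gelman-Rubin convergence checks.

## Worked example

```r
library(groupcmr)

pop <- simulate_population(n_groups = 40, lambda = 13, seed = 7)
cap <- simulate_capture_histories(pop, p_g = 0.7, p_i = 0.7,
                                  K = 2, T_occ = 3, seed = 8)
pop$N
#> [1] 533

fit <- fit_twostep(build_group_data(cap),
                   mcmc = mcmc_config(preset = "fast", seed = 11))
fit
#>  parameter    mean      sd    q2.5   q97.5 rhat
#>        p_g   0.699  0.0681   0.554   0.820    1
#>        p_i   0.690  0.0101   0.671   0.710    1
#>      psi_g   0.372  0.0531   0.274   0.481    1
#>     lambda  13.605  0.6148  12.448  14.829    1
#>          G  39.986  2.9460  36.000  47.000    1
#>          N 542.958 40.9243 488.000 646.000    1

one <- fit_onestep(condense_sweep_histories(cap),
                   mcmc = mcmc_config(preset = "fast", seed = 12))
one
#>  parameter    mean      sd    q2.5   q97.5 rhat
#>          p   0.671  0.0202   0.631   0.711    1
#>        psi   0.374  0.0149   0.345   0.403    1
#>          N 540.714 11.4889 520.000 565.000    1
```

Both models centre near the true abundance of 533, but the One-Step
posterior SD (11.5) is a third of the Two-Step's (40.9): its 95% interval
is far too confident about a population it only partially observes. The
Two-Step model additionally reports the number of groups `G` (truth: 40)
and mean group size `lambda` (truth: 13).

A full estimator comparison (bias, RMSE, CV, 95% BCI coverage over
replicated simulations):

```r
res <- run_scenario(scenario(p_g = 0.7, p_i = 0.7, n_reps = 100, base_seed = 1))
res$metrics
```

## Command line

```sh
Rscript inst/cli/groupcmr simulate --n-groups 40 --pg 0.7 --pi 0.7 --seed 1 --out sim
Rscript inst/cli/groupcmr fit-twostep --input sim_individuals.csv --out fit.csv
Rscript inst/cli/groupcmr study --reps 100 --seed 1 --out-dir study_out
```

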