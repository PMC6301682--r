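---
title: "Two-Step closed CMR for group-living species: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-Step closed CMR for group-living species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groupcmr)
```

## The estimation problem

Closed-population capture–mark–recapture estimates abundance `N` from
repeated detections of identified individuals, assuming the population is
closed for the survey's duration and that individuals are detected
independently. Species that move in stable groups violate the independence
assumption in a specific, structured way: an individual cannot be detected
unless its group is detected first, so individual detection probability is
zero in every sampling occasion in which the group was missed. Treating
such data with the conventional model produces a detection probability
that averages over this hidden heterogeneity. The abundance point estimate
remains roughly unbiased, but its posterior understates uncertainty badly
— the model believes it observed many independent Bernoulli trials that
never happened.

The Two-Step model makes the hierarchy explicit. Step one is a closed CMR
model for *groups* over `K` sweeps; step two estimates each detected
group's size from individual detections across `T` nest-site sub-occasions
per sweep, conditional on the group's sweep-level detection pattern.
Abundance is assembled as the sum of group sizes over all groups estimated
to exist, so the uncertainty about undetected groups propagates into `N`.

## Likelihood

For group `g` with inclusion indicator `z_g ~ Bernoulli(ψ_g)`:

* sweep detections `W_gk ~ Bernoulli(z_g p_g)`, and `G = Σ z_g` via data
  augmentation over `M` group rows;
* given the detection pattern `w`, a member is detected per occasion with
  `p_i w_k`, hence detected at all with `p* = 1 − Π_k (1 − p_i w_k)^T`
  (`p_star()`);
* the observed members' histories are conditional-multinomial with cell
  probabilities "Bernoulli product ÷ p*" (`history_cell_probs()`); the
  number observed is `n_g ~ ZTBinom(m_g, p*)`;
* `m_g ~ ZTPoisson(λ)`, zero-truncated because a group has at least one
  member (truncation moves to 2 when singletons are modelled separately as
  solitaries).

Two algebraic facts the implementation leans on, both covered by tests:
the `p*^{n_g}` factors cancel between the conditional multinomial and the
truncated binomial, and under a constant `p_i` the per-sweep *count* of
nest sites at which an individual was sampled, `Binomial(T, p_i w_k)`, is
the sufficient reduction of the occasion-level Bernoulli history. The
package therefore stores per-sweep counts (the "summed by sweep" CSV
dialect) and keeps the occasion-level path in the simulator and in
`history_cell_probs()` for checking.

The solitaries variant gives lone individuals their own per-sweep
detection probability `p_s` and augmentation (`S = Σ z_s`), with
`N = Σ m_g + S`. A solitary builds one nest per night, so there is no
nest-site sub-occasion for solitaries — one Bernoulli per sweep.

## Parameters and defaults

| parameter | meaning | prior / default |
|---|---|---|
| `p_g` | per-sweep group detection | uniform(0,1) |
| `p_i` | per-nest-site individual detection, given group detection | uniform(0,1) |
| `p_s` | per-sweep solitary detection | uniform(0,1) |
| `ψ_g`, `ψ_s` | augmentation inclusion | uniform(0,1) |
| `λ` | mean group size (ZT-Poisson rate) | uniform(0, 30) |
| `K`, `T` | sweeps, nest sites per sweep | 2, 3 (the field protocol) |
| `M` | augmentation sizes | groups `max(3×obs, obs+20)`; individuals `3×obs`; solitaries `max(8×obs, obs+20)` |

The λ upper bound of 30 is far above realistic mean group sizes for the
motivating taxon (observed means near 7–13); a warning fires if it fails
to clear the largest observed group. Augmentation sizes are our own
defaults (the benchmark study does not report its `M`): large enough that
the prior on `G`, `N` and `S` is effectively flat over the plausible
range, with a ceiling advisory whenever more than 1% of posterior mass
sits above `0.95·M`. The solitary default is deliberately generous (8×)
because solitary detection tends to be low and the `S` posterior wide; if
the advisory still fires, raise `M_solitaries` — one recovery test in the
suite does exactly this.

"Mean group size 13" is interpreted as the Poisson rate λ = 13 before
truncation; the truncated mean differs by under 3e-5 at that rate, and
`ztpois_mean()` computes the exact value where it matters.

## Sampler

All updates except two are conjugate Gibbs: `p`, `p_g`, `p_s` and the ψ's
are Beta draws, and because augmented all-zero rows are exchangeable,
their inclusion count is a single Binomial draw rather than `M` Bernoulli
updates. `p_i` and `λ` get slice sampling with interval shrinkage on their
bounded supports (tuning-free, exact). Each observed group's `m_g` is
drawn exactly from its discrete full conditional on the truncated grid
`[max(n_g, min), cap]`; the grid's upper bound `λ + 8√λ + 10` is
conservative because the conditional tail of `m_g` is lighter than its
ZT-Poisson prior tail. Sizes of included never-detected groups carry no
likelihood, so they are fresh prior draws in each iteration — the
marginalized (lower-variance-per-cost) form of the update; `λ`'s full
conditional correspondingly uses observed groups only.

Correctness is checked two independent ways: the joint log-likelihood
(`twostep_loglik()`) against a hand-derived enumeration on a two-group
toy, and the posterior mean of `N` against a prior-space
importance-sampling oracle with `m_g` and the inclusion indicators summed
out analytically on a three-group dataset.

Chain defaults are 3 chains × 50,000 iterations, 1,000 burn-in. The
study harness uses a documented `fast` preset (3 × 6,000, 1,000 burn-in)
— these posteriors are low-dimensional and nearly conjugate, so mixing is
rapid — plus a one-shot 2× extension whenever any monitored parameter has
Gelman-Rubin r-hat ≥ 1.1. The r-hat is the classic non-split form,
matching its long-standing use with Gibbs samplers of this vintage; BCIs
are equal-tailed 2.5–97.5 percentiles, linear-interpolation for continuous
parameters and nearest-rank for integer ones (`N`, `G`, `S`), so integer
interval endpoints are achieved draws — this convention matters because
BCI coverage is a headline metric.

## What the simulator states, and what it omits

`simulate_population()` / `simulate_capture_histories()` generate exactly
the stated world of the benchmark simulations: 40 groups, ZT-Poisson(13)
sizes, `K = 2`, `T = 3`, independent Bernoulli detections with constant
`p_g` and `p_i`, members of undetected-in-sweep groups forced to all-zero,
solitaries one Bernoulli per sweep. Replicate seeds are spawned from one
base seed (`replicate_seeds()`), so studies reproduce exactly.

Real surveys differ in ways the generator deliberately does not emulate:
detection heterogeneity among groups (size, terrain, territory overlap
with effort) and among individuals, time variation across sweeps, group
fission–fusion, genotyping error in individual identification, and
imperfect group-membership assignment. A green simulation test therefore
establishes that the estimators behave as claimed *under the model's own
assumptions* — the deceptive-precision phenomenon and its repair — not
that either model is robust to these field realities.

## Degenerate inputs and numerical choices

Log-zero is a value (`-Inf`), never an exception, so samplers can reject
naturally; `p = 0` in the truncated binomial returns log-zero for any
positive count. `history_cell_probs()` errors only on an all-undetected
pattern, which admits no observable history. All-zero capture rows are
rejected at the I/O boundary (observed-only files) and again by
`build_group_data()`, which also enforces the conditional-detection
invariant record by record. Zero-variance chains return r-hat 1 by
convention. ZT-Poisson sampling is inverse-CDF on the truncated support in
R; the C++ path uses rejection with an inverse-CDF fallback (identical
distribution, faster at the rates of interest).

When only individual capture CSVs are available, sweep-level group
detection is inferred as "any member sampled in that sweep". This is
exact unless a nest site was found but yielded no usable samples for an
entire group — rare at realistic `p_i` and `T`, and avoidable by
supplying the group-detection CSV (`read_group_csv()`).

## Known limitations

Constant detection probabilities (no M_t/M_b/M_h-style variation, no
covariates such as group size on `p_g`); no spatial capture–recapture
structure; stable group membership assumed throughout the survey; group
membership of observed individuals taken as known. The scenario grid's
parameter-level reference values exist only for the `p_g = p_i = 0.7`
cell, so other cells are checked as shape properties (coverage flatness,
RMSE ordering), not point targets.
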