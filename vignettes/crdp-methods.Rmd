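---
title: "Methods: constrained randomised dynamic programming trial designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained randomised dynamic programming trial designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crdp)
```

## The decision problem

A two-armed trial with `n` sequentially arriving patients and binary,
immediately observed responses is a finite-horizon Bayesian Bernoulli
two-armed bandit. Each arm's unknown success probability carries an
independent Beta prior; conjugacy means the whole history is summarised
by four counts `(s_A, f_A, s_B, f_B)` and the posterior mean of an arm
is its prior-augmented success fraction. The design question is which
arm to give the next patient, balancing treating that patient well
(exploitation) against learning for the remaining patients
(exploration).

The package solves this exactly by backward induction. The value of a
state at stage `t` is the best Bayes-expected number of successes
obtainable from patients `t + 1 .. n`, computed from the terminal stage
backwards via the principle of optimality. Three nested generalisations
share one solver, `solve_policy(n, p, ell, prior)`:

* `p = 1, ell = 0`: the classical optimal (DP) design. Deterministic,
  maximal patient benefit, but unrandomised, severely underpowered and
  badly biased for estimating the treatment effect.
* `0.5 <= p < 1, ell = 0`: randomised actions (RDP). The chosen action
  allocates its favoured arm with probability `p` only, so every
  patient has at least probability `1 - p` of receiving either arm.
  The action-value recursion folds the randomisation into both the
  one-period reward and the transition kernel.
* `ell > 0`: the constrained design (CRDP). A terminal reward of `-n`
  is paid whenever either arm ends with fewer than `ell` observed
  patients. Because the penalty dwarfs any attainable success count,
  the optimal policy sacrifices expected successes near the end of the
  trial to guarantee (at `p = 1`) or strongly favour (at `p < 1`) a
  minimum per-arm sample size — which is what restores estimability
  and power.

At `p = 0.5` the two actions coincide and the design degenerates to
fixed equal randomisation; the posterior-mean martingale then gives the
closed form `F_0 = n (mu_A + mu_B) / 2`, which the tests use as an
exact anchor alongside a brute-force enumeration oracle for small `n`.

## Tunable parameters

* **`n`** — trial size. The state lattice has `choose(t+3, 3)` states at
  stage `t` (about 1.5 million in total for `n = 75`); cost grows as
  `n^4`. A guard refuses `n > 200` unless raised explicitly, the point
  where backward induction stops being practical on one machine.
* **`p` (degree of randomisation), default 0.9** — the probability with
  which the policy-favoured arm is actually assigned. Raising `p`
  raises patient benefit and lowers power; 0.9 keeps most of the
  benefit while remaining genuinely randomised.
* **`ell` (degree of constraining), default `0.15 n`** — the minimum
  per-arm observed sample size enforced through the terminal penalty.
  Values around `0.10 n`–`0.15 n` buy most of the attainable power;
  beyond that the patient-benefit cost outweighs further gains. `ell`
  is kept real-valued and the penalty triggers when an observed count
  is *strictly* below it, so `ell = 11.25` at `n = 75` requires 12
  patients per arm. Users who prefer an integer convention can pass a
  rounded `ell` directly; nothing in the solver assumes integrality.
* **prior pseudo-counts, default `Beta(1, 1)` on both arms** — the
  equipoise (uniform) prior used throughout the package's reference
  results. Any strictly positive reals are accepted; the constraint
  threshold always applies to observed counts only, never to the
  prior-augmented ones, so an informative prior cannot silently
  satisfy the sample-size floor.

Two further choices are fixed in the implementation. Ties between the
two action values (absolute difference at most `1e-12`, in double
precision throughout) are recorded as ties and resolved 0.5/0.5 at
allocation time; this preserves the exact arm-exchange symmetry that
holds at the empty history under a symmetric prior, and any
deterministic tie-break would leave the symmetric scenario's results
dependent on an arbitrary arm labelling. The state lattice is addressed
by a closed-form combinatorial rank within each stage, so the solver and
the simulator never search for states; `keep_values = FALSE` retains
only two adjacent stages of the value table during the sweep when the
policy alone is needed.

## The trial simulator

`simulate_trials()` emulates the idealised protocol the designs assume:
one patient at a time, arm drawn from the rule's current probability,
response available before the next arrival, trial size fixed in
advance. A master seed spawns one sub-seed per replicate and each
replicate consumes its own uniform stream in a fixed order (arm draw,
then outcome draw), so a batch is reproducible as a whole and any
single replicate is reproducible in isolation — the batch and the
one-trial-at-a-time simulator are tested to agree bit for bit.

What the generator deliberately does not emulate: delayed or
non-binary responses, staggered or stochastic accrual, drift in the
success probabilities over calendar time, early stopping,
non-compliance, and more than two arms. Passing operating
characteristics under this generator therefore demonstrate the
decision-theoretic properties of the allocation rules under their own
assumptions, not robustness to the ways real trials violate them —
the immediacy assumption in particular is only plausible when accrual
is slow relative to response time, which is the rare-disease setting
the designs target.

## Evaluation choices

The end-of-trial test is Fisher's exact test, the conditional test
given both margins, two-sided by the point-probability rule (sum of all
hypergeometric point masses no larger than the observed one, with the
customary `1e-7` relative guard); `stats::fisher.test` serves as an
independent reference in the test suite rather than as the
implementation, which is vectorised over the distinct tables of a
replicate batch. The conditional test is conservative, so the nominal
level is set to 0.1 throughout the reference results. A table with an
empty margin returns p = 1.

The treatment effect is estimated by the difference of per-arm sample
proportions. Replicates in which an arm recruited nobody have no
estimate: they are excluded from the bias/MSE/estimator-mean averages
(the count of estimable replicates is always reported) and counted as
non-rejections. The unconstrained adaptive designs make such
replicates rare and the constrained design eliminates them; the
reported standard errors of the estimators are across-replicate
standard deviations, the interpretation consistent with the fixed
design's value `sqrt(0.5 * 0.5 / 37.5) ≈ 0.083` at `n = 75`.

When the arms are truly equal the "superior" arm is defined as arm A,
so the percentage-on-superior metric is well defined (and ≈ 50% for
every sensible design) in the null scenario. No multiplicity
adjustment is applied across scenario grids: each scenario is a
separate simulation experiment.

## Problem sizes and reproducibility

The packaged tests exercise exact values at `n <= 6` against a
brute-force tree oracle, structural invariants (value bounds,
monotonicity in `p`, arm-swap symmetry, penalty monotonicity) at
`n = 8`–`20`, and the full reference study — four designs, nine
scenarios, `n = 75`, 10,000 replicates per cell — as an acceptance
suite; the whole run takes well under a minute because policies are
solved once per design and replicates advance in lockstep.
`scripts/acceptance.R` repeats the reference study end to end from a
single seed and writes the headline numbers as JSON.

## Known limitations

Two arms, binary endpoints, fixed `n`, immediate responses. The
backward-induction solver is exact but `O(n^4)` in time and `O(n^3)`
per stage in memory, with a practical ceiling around `n = 200`. Bias
of the treatment-effect estimator under the constrained design is
small but not zero; no bias-corrected estimator is provided. The
randomised play-the-winner comparator implements the general
`(u, alpha, beta)` urn with the classic `(1, 0, 1)` defaults; its
operating characteristics depend on that choice, which is exposed as
configuration.
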