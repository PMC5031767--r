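---
title: "Estimating replication success probabilities and detecting excess success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating replication success probabilities and detecting excess success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toogood)
```

## The problem

A multi-test experiment in psychology or biomedicine typically supports its
claims with a *pattern* of hypothesis-test outcomes: some contrasts must be
significant (in a specific direction), others must be non-significant.
Because every study draws a random sample, even a true set of effects only
reproduces its full pattern with some probability well below one. When an
article reports several independent experiments that were *all* fully
successful, but the estimated probability of that joint event is small, the
set looks "too good to be true": some combination of selective reporting,
flexible analysis, or claims fitted to sampling noise is the more plausible
explanation. The Test for Excess Success (TES) formalises that diagnostic.

`toogood` implements the full pipeline: a declarative model of an
experiment's population and success criterion, a Monte-Carlo engine that
simulates direct replications, a closed-form noncentral-*t* module for
single tests, sample-size sweeps that find the attainable ceiling of the
success probability, and the cross-study product aggregation that yields
the excess-success flag.

## The model

One **condition** is a group of `n` participants whose within-subject
measures follow a multivariate normal distribution with means $\mu$,
standard deviations $\sigma$, and correlation matrix $R$ (covariance
$\Sigma_{ij} = \sigma_i \sigma_j R_{ij}$). Measures are modelled jointly
even when only marginal tests are requested, because within-subject
contrasts depend on the correlation between measures: the paired difference
has $\mathrm{sd}(x_1 - x_2) = \sqrt{\sigma_1^2 + \sigma_2^2 -
2\rho\sigma_1\sigma_2}$, so ignoring $\rho$ would misstate paired power. A
**study design** is a set of such conditions sharing one measure list, and
a **success criterion** is a conjunction of test requirements, each either

* *significant in direction*: two-sided $p < \alpha$ **and** the observed
  mean difference has the expected sign (a significant effect in the wrong
  direction does not replicate the original pattern), or
* *non-significant*: two-sided $p \ge \alpha$.

Two test kinds are supported: the between-condition two-sample *t* test on
one measure, and the within-condition paired *t* test on the difference of
two measures. The default two-sample variant is the pooled (Student) test
with $df = n_1 + n_2 - 2$, matching the analysis conventions of the
2000s-era studies this diagnostic is typically applied to; the Welch
variant is available via `variant = "welch"`. Significance is strict
($p < \alpha$); a tie at exactly $\alpha$ counts as non-significant, an
event of probability zero under the continuous model. The default
$\alpha = 0.05$ two-sided is configurable per test, since source articles
rarely state it explicitly.

## Monte-Carlo estimation

`estimate_success()` draws `reps` complete replications (default 100,000),
evaluates every test on each, and reports

$$\hat p = \frac{\#\{\text{replications meeting all requirements}\}}{\text{reps}},
\qquad \mathrm{se}_{MC} = \sqrt{\hat p (1 - \hat p)/\text{reps}},$$

together with each test's marginal success rate counted on the same
replications, which makes the conjunction bound
$\hat p \le \min_k \hat p_k$ exact rather than approximate. The engine is
vectorised: per condition, all replications' draws are generated as one
standard-normal block, transformed through a deterministic eigenvalue
factorisation of $R$ (which also handles positive-semidefinite but
singular correlation matrices), and reduced to the per-replication means
and variances the *t* statistics need. Draws are chunked to bound memory
at roughly four million values per block, so sample sizes in the thousands
remain feasible.

Tests sharing a condition's sample are dependent — in a seven-test battery
over three conditions the same simulated participants enter several
statistics — so the joint probability cannot be obtained by multiplying
marginal powers. That dependence is the reason the engine exists;
`simulate_once()` exposes the single-replication reference path the
vectorised estimator must agree with (and a test checks that it does).

## Analytic single-test probabilities

For one test in isolation the outcome probabilities are exact noncentral-*t*
masses. With noncentrality $\delta = d\sqrt{n_1 n_2/(n_1+n_2)}$ (between,
$d = (\mu_A - \mu_B)/\sigma_{pooled}$) or $\delta = d_z\sqrt{n}$ (paired,
$d_z$ the standardized mean difference of the paired contrast), and
$t_c$ the two-sided critical value, the probabilities of
significant-in-direction, significant-wrong-direction, and non-significant
outcomes are the masses beyond $t_c$ on the effect's side, beyond $-t_c$ on
the other, and between them; they sum to one. When condition SDs differ,
the effective $d$ uses the $(n-1)$-weighted pooled SD of the referenced
measure — a definition this package fixes explicitly because the source
literature rarely defines an effect size at all.

This module is both the fast path for planning and the *independent
oracle* in the test suite: for randomly generated single-test designs the
Monte-Carlo estimate must agree with the analytic probability within
3 Monte-Carlo standard errors. That agreement is exact only when the
pooled *t* statistic actually follows a noncentral *t*, i.e. under
variance homogeneity across the two conditions. The fixture generator
therefore draws one population SD per measure shared by all conditions;
heteroscedastic designs can still be specified by hand, but for them the
pooled-*t* analytic value is a Behrens–Fisher approximation and only the
Monte-Carlo engine is exact.

## Sample-size sweeps and the ceiling phenomenon

`success_curve()` re-instantiates the design on a grid of per-condition
sample sizes (equal allocation) and estimates the joint and marginal
success probabilities at each point (default 10,000 replications per grid
point). For criteria built only of significance requirements with real
effects, success is monotone in `n` and approaches 1. When the criterion
also requires non-significant outcomes from contrasts whose true effect is
small but nonzero, those tests eventually reach significance as `n` grows:
the joint success curve rises, peaks at an interior optimum
(`find_optimum()`, ties broken toward the smaller, cheaper `n`), and then
declines toward zero. This ceiling is the practically important output —
it can show that *no* sample size gives a direct replication a good chance
of reproducing the full reported pattern, in which case a replication
attempt is arguably not worth its cost and a differently designed study is
needed.

The default grid is 5 to 200 in steps of 5, bracketing both the optima
observed in published analyses of this kind (around 45 per condition) and
the large-`n` decline.

## Aggregating across studies

Independent studies succeed jointly with probability equal to the product
of their success probabilities; `aggregate_product()` computes it and
flags the set when the product falls below a threshold. The threshold
defaults to 0.1, the conventional value in the excess-success literature,
and is always printed alongside the product because the flag is only as
meaningful as its cutoff. The product is permutation-invariant and
multiplicative over subsets, properties the suite checks.

## Randomness and reproducibility

Every stochastic entry point takes an integer `seed` and is bitwise
reproducible from it; the RNG state of the caller's session is saved and
restored around each call. Sweeps derive one independent L'Ecuyer-CMRG
substream per grid point from the master seed, so grid points are
statistically independent yet the whole curve is reproducible from a
single integer. Within one estimate the replications are generated from a
single seeded stream; the estimate is a pure function of
(design, criterion, reps, seed), which is the reproducibility contract the
package promises. `INSUFFICIENT_REPS` rejects estimates below 100
replications, where the Monte-Carlo standard error exceeds 0.05 and the
estimate is not meaningfully interpretable.

A degenerate replication (zero sample variance in a tested contrast)
aborts the whole estimate with a `DEGENERATE_SAMPLE` error rather than
being counted as failure: under a continuous population model it has
probability zero, so its occurrence always indicates a malformed design
rather than an unlucky draw.

## The synthetic-data generator

`make_random_design()` produces valid design/criterion pairs for testing
and exploration: standardized effects drawn from a configurable range with
random signs, correlation matrices that are positive semidefinite by
construction (two-factor loading structure shrunk toward the identity to
respect the configured magnitude bound), sample sizes from a configurable
interval, and a configurable mixture of significance and non-significance
requirements whose expected signs match the true population effects. Every
generated pair passes `validate_design()` and runs end to end.

`study1_template()` encodes the structural battery of the three-condition
priming study that motivates the package: conditions of 13, 12 and 14
participants, two correlated measures (frames-to-detection of
crime-relevant and crime-irrelevant objects), and seven tests — five
required significant (three between-condition contrasts on the relevant
measure and the within-subject contrast in each prime condition) and two
required non-significant (the prime contrasts on the irrelevant measure).
The template intentionally has no default numeric parameters: the original
article does not print usable means, SDs or correlations (they exist only
in external supplementary material), and inventing defaults would let
fabricated numbers masquerade as published data. The parameter file
shipped in `inst/extdata/study1_synthetic_params.csv` is explicitly
synthetic and exists to exercise the pipeline.

## What the synthetic conditions do and do not show

The generator and template emulate the *sampling* process of small
multi-test experiments under exactly normal populations with known
parameters and homogeneous variances. Passing tests therefore demonstrate
that the estimator, oracle and sweep machinery are correct under the
stated model. They do not show that real data are normal, that reported
sample statistics equal population values (the method's central working
assumption, inherited from the TES literature), or that test batteries in
real articles are as clean as the declarative criterion assumes. Those are
limitations of the method itself, not of any particular implementation,
and conclusions drawn from a low product should be phrased accordingly.

## Problem sizes used in the checks

The shipped test-suite and acceptance script run at 10,000 replications
for property checks, 40,000 for null-calibration rates, 100,000 for the
headline template estimate, and 10,000 per grid point across a 20-point
sweep — sizes at which Monte-Carlo standard errors (≤ 0.005) are small
relative to every tolerance asserted, while a full run stays comfortably
interactive.
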