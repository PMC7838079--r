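---
title: "Scoring moral-dilemma batteries: the CAN algorithm and processing-tree models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring moral-dilemma batteries: the CAN algorithm and processing-tree models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canmpt)
```

## The four-cell dilemma design

Classic trolley-style dilemmas confound three things an agent might be doing:
following a moral norm, weighing consequences, or simply preferring action
(or inaction) regardless of either. The four-cell design breaks the
confound by varying the same scenario along two factors: whether the norm is
*proscriptive* (forbids the proposed action) or *prescriptive* (mandates it),
and whether the benefits of acting are *greater* or *smaller* than its costs.
Writing the probability of choosing action in the four variants as

* `p1` — proscriptive norm, benefits > costs,
* `p2` — proscriptive norm, benefits < costs,
* `p3` — prescriptive norm, benefits > costs,
* `p4` — prescriptive norm, benefits < costs,

a participant who completes the standard battery (six dilemmas per cell,
24 trials) yields an empirical estimate of each `p` as a multiple of 1/6.

## The CAN algorithm

The CAN scores are contrasts of the four cell probabilities:

$$C = \frac{(p_1 - p_2) + (p_3 - p_4)}{2}, \qquad
  N = \frac{(p_3 - p_1) + (p_4 - p_2)}{2}, \qquad
  A = \frac{p_1 + p_2 + p_3 + p_4}{4}.$$

`C` (consequence sensitivity) averages the benefit-greater minus
benefit-smaller contrast within each norm type; `N` (norm sensitivity)
averages the prescriptive minus proscriptive contrast within each
consequence type; `A` is the overall action preference, with 0.5 the neutral
point. Because the scores are plain linear maps, they exist for every
participant individually — no likelihood, no group pooling — and can enter
correlations, regressions and multiple comparisons directly.

```{r}
p <- c(p1 = 0.51, p2 = 0.21, p3 = 0.86, p4 = 0.56)
can_parameters(p)
```

The group-level decision rules are implemented in `group_summary()` (means,
SDs and two-tailed one-sample t tests of C and N against 0 and A against
0.5) and `classify_group()`: a significant positive (negative) mean C or N
means sensitivity supporting (opposing) consequences or norms; a
non-significant A combined with at least one significant sensitivity is a
*pure morality* profile; nothing significant is classified as random
responding. The tests use alpha = 0.05, two-tailed, with no multiplicity
correction across the three parameters, matching standard reporting for
this design. Zero-variance groups are flagged `degenerate` rather than
given an infinite t statistic; `classify_group()` then falls back on the
exact mean (a constant group at the neutral point is insensitive, a
constant group away from it deterministically differs).

The rules above are defined for group means. Per-participant significance
with 6 trials per cell would rest on very little data, and no standard
convention exists; the package therefore classifies groups only, while the
individual scores themselves are always available from `can_scores()`.

## The three processing trees

The same cells can be modelled by three-parameter multinomial processing
trees. The **CNI** tree assumes the agent consults consequences, then norms,
then a generalized inaction preference:

$$\begin{aligned}
p_1 &= C + (1-C)(1-N)(1-I) & p_2 &= (1-C)(1-N)(1-I)\\
p_3 &= C + (1-C)N + (1-C)(1-N)(1-I) & p_4 &= (1-C)N + (1-C)(1-N)(1-I)
\end{aligned}$$

The **NCI** tree swaps the first two stages; the **DNA** tree makes the two
moral drives parallel: with probability `D` the choice is principle-driven
(norms dominate with probability `N`), otherwise an overall action
preference `A` applies. `cni_forward()`, `nci_forward()` and
`dna_forward()` evaluate the equations; `cni_invert()` gives the closed
form

$$C = \tfrac{(p_1-p_2)+(p_3-p_4)}{2}, \quad
  N = \frac{-p_1-p_2+p_3+p_4}{2-p_1+p_2-p_3+p_4}, \quad
  I = 1 - \frac{p_2}{(1-C)(1-N)},$$

which round-trips the forward equations exactly for interior parameters and
fails loudly for degenerate cells (`C` or `N` at 1) or cells off the model
manifold (`p1 - p2 != p3 - p4`).

Three exact identities connect the frameworks, and the test suite verifies
them over a full parameter grid:

1. on CNI-generated cells the CAN `C` equals the CNI `C` exactly;
2. the CAN `N` equals `(1 - C)` times the CNI `N` — the sequential tree
   inflates norm sensitivity by `1/(1 - C)`;
3. `A - 0.5 = (1-C)(1-N)(0.5 - I)`, so `A` and `I` sit on opposite sides
   of 0.5 whenever both are away from it.

On DNA-generated cells, `C = D(1-N)` and `N = DN` exactly — the parallel
tree and the algebraic scores agree by construction.
`run_hypothesis_checks()` evaluates all three identities on data, with a
default tolerance of 0.02 for noisy batteries (about one trial in a
24-trial battery) and 1e-3 recommended for noise-free, model-generated
input.

## Maximum-likelihood fitting

`fit_mpt()` fits any of the three trees to aggregated cell counts (the
sufficient statistic) by maximizing the product-binomial likelihood across
the four cells of each group. Numerical choices:

* parameters are optimized on the logit scale with L-BFGS-B, boxed to
  [1e-6, 1 - 1e-6]; estimates within 1e-4 of the box are flagged as
  boundary solutions;
* multi-start from a fixed 3×3×3 interior grid {0.25, 0.5, 0.75}³ plus the
  closed-form inversion of the observed proportions clamped to
  [0.02, 0.98]; the best likelihood wins and ties go to the first start,
  so fits are deterministic;
* gradients are analytic (chain rule through the tree equations and the
  logistic reparameterization);
* without cross-group constraints the likelihood factorizes, so groups are
  fitted separately and recombined — identical results, smaller problems;
* fit quality is `G² = 2 Σ obs·ln(obs/exp)` over the action and inaction
  counts of every cell, with zero observed counts contributing zero, and
  `df = 4·(groups) − (free parameters)` — 1 for a single group, 2 for two
  free groups.

`delta_g2_test()` implements the likelihood-ratio comparison used for group
differences: a parameter is forced equal across two groups (or to a fixed
value in one group), and `ΔG² = G²_constrained − G²_unconstrained` is
referred to chi-square with 1 df. The constrained fit reuses the free
optimum as a warm start; a constrained fit beating the free one beyond
tolerance raises an optimization-failure error rather than returning a
negative statistic. Cohen's *w* = sqrt(ΔG²/total observations) is reported
as a descriptive effect size; no conversion to Cohen's *d* is attempted
because there is no standard mapping from ΔG² on pooled counts to a
standardized mean difference.

## The simulator and what it does (not) emulate

`population_spec()` + `simulate_battery()` generate trial-level data under
any of the trees or under direct cell probabilities. Participant
heterogeneity is logit-normal: latent parameters are
`plogis(rnorm(qlogis(mean), sd))`, which respects (0, 1) without
truncation artifacts; `latent_sds = 0` reproduces the means exactly. The
default battery is 24 trials (4 cells × 6), the standard design. One seed
governs everything, and per-participant sub-seeds make each participant's
draw independent of how many others are simulated.

The simulator emulates binomial trial noise and (optionally) latent
heterogeneity. It does not emulate item effects (specific dilemma wording),
response times, sequence effects, or careless responding. Passing
parameter-recovery and calibration tests on simulated data therefore shows
the estimators are correct under the stated model, not that real batteries
satisfy that model.

Simulation sizes used by the test suite, chosen to keep Monte-Carlo error
well inside the tolerances being checked: recovery uses 200 participants at
6 trials/cell (1200 Bernoulli draws per cell, SE of each cell proportion
about 0.014); calibration uses 1000 replicates of two 50-participant
groups, for a binomial SE of about 0.007 around a true rate of 0.05.

A note on calibration: the group-level G² test treats pooled counts as
binomial, which is exact when participants within a group share one
parameter triple. With real between-participant heterogeneity the pooled
counts are overdispersed and the ΔG² test can exceed its nominal level —
one more reason the individual-level scores are the safer inferential
route. The calibration suite therefore simulates the homogeneous null the
test actually assumes.

## Group comparisons and reports

`compare_groups_can()` runs pooled-variance Student's t tests
(df = n1 + n2 − 2) on the individual C, N, A scores of two groups, with
Cohen's d from the pooled SD; Welch's version is available via
`var_equal = FALSE`. `build_comparison_report()` pairs each tree-side ΔG²
test (C, N, I) with the corresponding score-side t test (C, N, A — the
third row pairs the two frameworks' action/inaction parameters, which
measure reversed tendencies) and flags whether both land on the same side
of alpha. `correlate_traits()` adds Pearson correlations between a trait
measure and the three individual scores, with listwise deletion of missing
traits and degenerate-variance flags.

```{r, eval = FALSE}
low  <- simulate_battery(population_spec(200, "cni", c(0.3, 0.4, 0.4), seed = 14),
                         group = "low",  id_prefix = "lo_")
high <- simulate_battery(population_spec(200, "cni", c(0.3, 0.6, 0.4), seed = 15),
                         group = "high", id_prefix = "hi_")
build_comparison_report(combine_batteries(low, high))
```

## Design choices and limitations

* **Long-format CSV is canonical.** Trial-level rows generalize to any
  per-cell trial count; the reader normalizes codings via `column_map` and
  `response_codes`, and incomplete participants are a hard error unless
  `allow_incomplete = TRUE` drops them with a message.
* **Only the three published trees are implemented.** There is no
  user-defined tree DSL and no hierarchical/latent-trait extension.
* **Binary responses only.** The algebra extends to continuous response
  scales, but this implementation scores binary action/inaction data.
* **24 trials is few.** Individual scores from 6 trials/cell are coarse
  (multiples of 1/6) and noisy; the package reports them without shrinkage
  or measurement-error correction, and no index of score reliability is
  provided.
* **Group-level MPT fits assume homogeneity** (see the calibration note
  above).
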