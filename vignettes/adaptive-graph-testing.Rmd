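---
title: "Adaptive graph-based multiple testing: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive graph-based multiple testing: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agmtp)
```

This vignette explains the statistical machinery behind `agmtp`, the
choices the package makes where the methodology leaves room, and what its
simulation-based validation does and does not establish.

## 1. Graphs as closed weighted Bonferroni tests

A hypothesis graph (`hyp_graph()`) consists of node weights `w` with
`sum(w) <= 1` and a transition matrix `G` with zero diagonal and row sums
at most 1, both in units of the familywise level α. The graph is shorthand
for a full closed testing procedure: `derive_weights()` expands it into
weights `w[j, J]` for all `2^m - 1` intersection hypotheses by removing the
hypotheses outside `J` one at a time, reallocating each removed node's
weight along its outgoing edges and rewiring the remaining edges,

$$w'_j = w_j + w_\ell\, g_{\ell j}, \qquad
  g'_{jk} = \frac{g_{jk} + g_{j\ell}\, g_{\ell k}}{1 - g_{j\ell}\, g_{\ell j}},$$

with the convention that a row is zeroed when the denominator vanishes
(the removed node and its neighbour formed a closed two-cycle, so there is
nothing left to pass weight to). The result does not depend on the removal
order; the test suite checks this against a brute-force remover over random
graphs and random orders. Two consequences worth knowing:

* if every row of `G` sums to exactly 1, no weight leaks — each
  intersection's weights sum to the same total as the full graph;
* weights are monotone under nesting: removing competitors never decreases
  a hypothesis' weight.

The fixed-sample analysis can use either `closed_test()` (explicit
closure) or `sequentially_rejective()` (the m-step shortcut); the two are
equivalent for graph-generated weights and the suite verifies this over
randomized instances.

## 2. Partial conditional errors and the adaptive closure

At an unblinded interim analysis after `n1` of `n` planned subjects per
group (information fraction `t = n1/n`), the conditional probability that
the preplanned one-sided z-test of H_j inside H_J would reject is

$$A_{j,J} = 1 - \Phi\!\left(\frac{z_{1-w_{j,J}\alpha} - z_j^{(1)}\sqrt{t}}
  {\sqrt{1-t}}\right),$$

implemented in `ztest_pce()`. Its two key properties are built into the
tests: it is strictly increasing in both the level and the interim
z-score, and its expectation under the null equals the level (the
martingale property that makes conditional-error arguments work). The sums
`B_J = sum(A[j, J])` (`pce_table()`) are the budget available to *any*
level-`B_J` test of H_J based on independent second-stage data; `B_J` is
not a probability and may exceed 1, in which case H_J is rejected on the
interim data alone.

Second-stage weighted Bonferroni tests (`agmtp_closed_test()`) reject H_J
when some `q_j < v[j, J] * B_J`. The default allocation fractions re-express
a possibly modified second-stage graph on the `B_J` scale: `solve_gamma()`
finds the adjusted level γ_J with
`sum(A(z1, w2 * gamma, t)) = B_J` and sets `v = A(z1, w2 * gamma, t)/B_J`.
When the weights are unchanged this gives γ_J = α and reproduces the
preplanned conditional levels exactly; when positively weighted hypotheses
are dropped it gives γ_J ≥ α — this is precisely where the adaptive test
gains over the inverse-normal comparator, a dominance the suite checks
replicate by replicate. Two alternative strategies are provided:
`"equal_recycling"` (each continued hypothesis keeps its own conditional
error plus an equal share of the dropped ones) and `"direct"` (`v = w2`
as given; valid but not level-preserving for unchanged weights).

The second-stage strategy may be passed either as a graph or as an edited
per-subset weight table. The distinction matters: zeroing dropped
hypotheses in the *graph* and re-deriving is not the same as zeroing their
columns in the preplanned *per-subset* weights, and the dominance theorem
is stated for the latter construction.

## 3. Numerical choices

* Simplex constraints are checked with tolerance 1e-9 and clamped at the
  boundary; weights below 1e-12 are snapped to zero so that "zero weight"
  logic (a dropped hypothesis can never be tested) is exact rather than
  approximate.
* `solve_gamma()` uses bracketed bisection on `[0, 1/max(w2)]` — the sum
  of conditional errors reaches at least 1 at the upper bracket, is
  continuous and nondecreasing, so a solution exists for every `B_J < 1`.
  The iteration keeps the invariant `f(lo) <= B_J`, so for a
  discontinuous conditional-error function (discrete test statistics) it
  returns the largest bracketed level with sum at most `B_J`; only the
  continuous z-test path is first-class. Absolute tolerance 1e-10 on the
  sum.
* Levels below 1e-15 are treated as zero before calling `qnorm()` to
  avoid infinities.
* The preplanned rule (`closed_test()`) uses a non-strict comparison
  `p <= w * alpha`, the adapted rule (`agmtp_closed_test()`) a strict
  `q < v * B`. Both follow the respective definitions; for continuous
  statistics the difference is a probability-zero event, and the
  acceptance suite exercises both conventions.
* Full subset enumeration is limited to m ≤ 16 with a hard error;
  the adaptive closure is inherently exponential because the adapted test
  need not be consonant.
* Ties in the sequentially rejective shortcut (several p-values at or
  under their boundary in one pass) are resolved by rejecting all of them
  and removing their nodes one at a time; order invariance of the removal
  makes this well defined.

The elementary critical levels quoted for the worked example deserve a
note: the smallest conditional level over the intersections containing H1
is 0.0742 (from {1,3,4} and {1,4}), and over those containing H3 but not
H1 it is 0.1108 (from {3,4}). Summaries that first round the A terms to
three decimals arrive at slightly different numbers (0.075, and 0.088 via a
different subset); the package always reports the exact minima computed at
full precision and rounds only for display.

## 4. What the trial simulator emulates

`trial_scenario()` describes a three-arm trial (two treatments, common
control) with hierarchically ordered primary and secondary endpoints per
treatment plus a toxicity marker per treatment. The six standardized test
statistics are multivariate normal with mean
`sqrt(n_s/2) * (d1/s1, d2/s2, d1/s1, d2/s2, 0, kappa/st)` and a
correlation matrix assembled from: 1/2 for the same endpoint across arms
(balanced groups sharing the control), ρ between endpoints within an arm,
ζ between a treatment's toxicity marker and its primary endpoint, and the
induced products elsewhere. This matrix is positive semi-definite for all
|ρ|, |ζ| ≤ 1 — it encodes a realizable factor structure — so validation
errors arise only from genuinely impossible inputs.

Default parameters describe the study conditions the package targets:
σ = 1, ρ = 0.3, ζ = 0.5, α = 0.025 one-sided, n = 116 and n1 = 58 per
group (the smallest multiple of 4 giving 90% power for a primary
rejection at effect size 0.4), toxicity threshold s = qnorm(0.95) = 1.645,
and a reallocated second-stage per-group size of 82. The last value is a
stated design constant rather than an arithmetic consequence: splitting the
dropped arm's 58 second-stage subjects equally over the two continued
groups would give 87, so the constant is kept configurable
(`n2_reallocated`) and results that depend on it should be read with that
ambiguity in mind. The acceptance checks deliberately use only quantities
insensitive to it (null scenarios, no-reallocation power, drop
probabilities).

Stages are simulated as independent score draws, with the full-data
statistic formed as `sqrt(t) z1 + sqrt(1-t) z2`. For z-tests this is
exactly equivalent to patient-level simulation and far cheaper. Four
interim rules are implemented: PP (no change), SB (keep the arm with the
larger interim primary z), FF (coin-flip selection, independent of data),
and SF (drop any arm whose toxicity score exceeds s — possibly both arms,
in which case no hypothesis can be rejected). When nothing is dropped the
preplanned test is performed, as the conditional-error condition is then
satisfied by the original design.

The vectorised engine (`operating_characteristics()`) exploits a
structural fact of these scenarios: the second-stage graph (continued
arm's hierarchy at weight 1) gives every intersection at most one
positively weighted hypothesis, whose allocation fraction is exactly 1, so
no root-finding is needed inside the Monte Carlo loop. `run_trial()`
recomputes single replicates through the generic object pipeline
(`adapt_design()`, `agmtp_closed_test()`, `samtp_gpa()`), and the test
suite requires the two paths to agree trial by trial across rules and
procedures — the engine is fast *because* it is specialised, and honest
because it is cross-checked.

What passing simulations do **not** show: the generator draws exactly
normal scores with known variances and exchangeable endpoint structure.
Real trials add estimated variances (t-statistics), non-normal endpoints,
unequal allocation, information fractions off 1/2, and interim decisions
influenced by information outside the model. The FWER guarantee of the
procedure itself is unconditional — it holds for any data-dependent
adaptation rule — but the *power* figures produced here are specific to
the scenario family above.

## 5. Problem sizes used in the checks

The packaged test suite runs closure-equivalence and order-invariance over
roughly a thousand random graphs (m ≤ 6), per-replicate dominance over a
thousand simulated adaptive trials plus a thousand randomized designs,
null-mean (martingale) checks at 10⁵ draws, and familywise error under the
global null for every rule/procedure/reallocation combination at 2 × 10⁴
replicates each, with three-standard-error bounds. The acceptance script
uses 10⁶ replicates per simulated scenario and 2 × 10⁵ per sample-size
candidate. These sizes keep each stochastic check's Monte Carlo error well
below the differences that matter (a few tenths of a percentage point)
while the whole suite stays in the minutes range on a single core.
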