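# agmtp — adaptive graph-based multiple testing procedures

`agmtp` implements graph-based multiple testing for confirmatory clinical
trials that are adapted at an unblinded interim analysis: treatment arms may
be dropped, sample sizes reallocated, and the weighting strategy itself may
be changed — all while keeping strong familywise error rate (FWER) control.
It is aimed at biostatisticians planning or analysing multi-arm, multi-
endpoint two-stage designs.

## The methodology in brief

A *graphical multiple comparison procedure* encodes a weighted Bonferroni
strategy for m one-sided hypotheses H\_1, ..., H\_m as a directed weighted
graph: node weights w\_i give the initial split of the level α, and edge
weights g\_ij say what fraction of a rejected hypothesis' level moves to
each remaining hypothesis. Removing nodes one at a time with the update

    w'_j = w_j + w_l * g_lj,
    g'_jk = (g_jk + g_jl * g_lk) / (1 - g_jl * g_lj)

generates weights w\_{j,J} for every intersection hypothesis H\_J, and the
closed test rejects H\_i iff every H\_J with i ∈ J has some p\_j ≤
w\_{j,J} α. For the preplanned (non-adaptive) analysis this closure is
equivalent to the familiar sequentially rejective shortcut.

The adaptive extension works through *partial conditional error rates*. At
the interim analysis, the probability that the preplanned z-test of H\_j
inside H\_J would reject, conditional on the first-stage data,

    A_{j,J} = 1 - Φ( (z_{1 - w_{j,J} α} - z_j^(1) √t) / √(1 - t) ),

is computed for every j and J, with t = n₁/n the information fraction. The
sums B\_J = Σ\_{j∈J} A\_{j,J} are the conditional levels available to *any*
second-stage test of H\_J — whatever adaptation was made. The adaptive
graph-based MTP (agMTP) tests each intersection with a second-stage weighted
Bonferroni rule q\_j < v\_{j,J} B\_J, where the allocation fractions
v\_{j,J} re-express a (possibly modified) second-stage graph on the B\_J
scale via an adjusted level γ\_J solving Σ\_j A\_{j,J}(w̃\_{j,J} γ) = B\_J.
If B\_J ≥ 1 the intersection is rejected at interim outright. Because the
adapted closure is in general not consonant, all 2^m − 1 intersections are
evaluated explicitly.

The package also provides the simpler, strictly conservative comparator
(saMTP / graph-based partitioning algorithm, gPA): set dropped hypotheses'
p-values to one, combine stagewise p-values by the inverse-normal rule, and
run the preplanned graph unchanged. agMTP rejects everything gPA rejects,
and more whenever a positively weighted hypothesis is dropped.

## Worked example

A trial compares two treatment regimens against control on a primary
endpoint (H1, H2) and a secondary endpoint (H3, H4), level split equally
between the primaries, each primary passing its level on to its own
secondary. At the interim analysis (58 of 116 subjects per group, t = 1/2)
the first-stage z-scores are (1.66, 1.42, 1.90, 0.79); treatment 2 is
dropped for safety and its patients reallocated.

```r
library(agmtp)

graph <- graph_two_arm_hierarchy()
plan  <- stage_plan(alpha = 0.025, n = 116, n1 = 58)

pt <- pce_table(c(1.66, 1.42, 1.90, 0.79), derive_weights(graph), plan)
dplyr::select(pt, subset, B)
#>    subset         B
#>  1 {1,2,3,4} 0.106
#>  4 {1,3,4}   0.0742
#> 11 {3,4}     0.111
#> 15 {4}       0.0238     (11 further rows)
```

Every intersection containing a dropped hypothesis keeps its conditional
error: B for {1,3,4} is A₁(α/2) + A₄(α/2) = 0.074, so the second-stage
p-value of H1 only needs to undercut 0.074 rather than α/2. The final
analysis with second-stage z-scores 1.56 and 1.87 (q₁ = 0.059, q₃ = 0.031):

```r
fit <- agmtp(
  z1 = c(1.66, 1.42, 1.90, 0.79), q = c(0.059, 1, 0.031, 1),
  graph = graph, graph2 = graph_two_arm_hierarchy(dropped = 2),
  plan = plan, continued = c("H1", "H3")
)
fit
#> <agmtp> adaptive graph-based closed test
#> rejected: H1, H3
```

Both hypotheses on the continued arm are rejected: q₁ = 0.059 is below the
smallest conditional level of any intersection containing H1 (0.074), and
q₃ = 0.031 below the smallest level of the intersections containing H3 but
not H1 (0.111) — even though 0.059 would have failed the preplanned
boundary α/2 = 0.0125. The fixed-sample comparator is available as
`samtp_gpa()`, and `tidy()` / `glance()` summarise any fit.

Monte Carlo operating characteristics and sample-size determination:

```r
scen <- trial_scenario(delta1 = 0.4, delta2 = 0.4, rule = "SB")
operating_characteristics(scen, "agMTP", reps = 1e5, seed = 1)
find_sample_size(target = 0.9, delta = 0.4, rho = 0.3, reps = 1e5, seed = 1)
```

A command-line interface covering all of the above lives in
`inst/cli/agmtp.R` (subcommands `derive-weights`, `closed-test`, `pce`,
`adapt`, `simulate`, `find-n`, `make-fixtures`); see `?agmtp_cli`.

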