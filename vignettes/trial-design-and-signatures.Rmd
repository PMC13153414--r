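---
title: "Methods: two-stage design inference and transcriptomic response signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage design inference and transcriptomic response signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialsig)
```

This vignette records the models implemented in `trialsig`, the
assumptions behind them, the tunable parameters and their defaults, the
numerical choices made where several conventions were defensible, and what
the synthetic-data tests do and do not establish about real data.

## The two-stage design engine

A Simon two-stage design is stored as `(r1, n1, r, n)` with the
conventions *stop for futility if stage-1 responses ≤ r1* and *declare
positive if total responses ≥ r + 1*. A protocol phrased as "≥ 4 responses
in 17 to continue" therefore maps to `r1 = 3`, `n1 = 17`. All operating
characteristics are exact binomial convolutions — nothing in the design
engine is simulated.

`simon_search()` enumerates every admissible `(r1, n1, r, n)` with
`n ≤ n_max` (default 100). For each `(n, n1, r1)` the smallest final
boundary `r` satisfying the size constraint is found by bisection, which
is valid because the rejection probability is non-increasing in `r`;
stage-1 configurations whose early-stopping probability under `p1`
already exceeds `β` are pruned, since no final boundary can rescue the
power. Among feasible designs, *optimal* minimises `EN(p0)` and *minimax*
minimises `n` then `EN(p0)`; remaining ties break by smallest `n`, then
smallest `n1`, so the search is deterministic. The brute-force scan in the
test suite (no bisection, no pruning) confirms the pruned search attains
the true minimum expected sample size on a grid of hypotheses.

### Conditional-error recalibration

When a trial under-enrols, we keep the stage-1 rule and re-derive the
final boundary from the conditional error
`A(s1) = Pr[X2 ≥ r + 1 − s1; n − n1, p0]` (0 below the futility boundary,
1 at or above the positivity boundary). The recalibrated threshold is the
smallest total `m` with `Pr[X2* ≥ m − s1; n2_attained, p0] ≤ A(s1)`.
Because each conditional rejection probability is bounded by the original
`A(s1)`, the unconditional type-I error of the recalibrated rule can never
exceed the original design's exact size — the suite checks this to 1e−12
over a design grid. When no achievable total can reject (for example,
`n2_attained = 0` with `s1 ≤ r`), the function returns an `NA` sentinel
with a warning rather than a misleading number.

### Design-consistent inference

The one-sided p-value uses the stagewise ordering of two-stage outcomes,

$$p(p_0) = \sum_{m_1 = r_1+1}^{n_1} b(m_1; n_1, p_0)\,
  \Pr[X_2^* \ge s_{\text{total}} - m_1;\, n_2^{\text{att}}, p_0],$$

with the second-stage tail taken as 1 when `s_total − m1 ≤ 0` and the
*attained* second-stage size inside the tail; the stage-1 law is
unchanged. This is the natural adaptation of design-consistent
(Koyama–Chen) inference to under-enrolment: the ordering is the planned
design's, the sampling is the attained one. Confidence bounds invert this
tail in the true response probability at mass `(1 − level)/2` per side.
The tail is monotone increasing in `p`, so plain bisection suffices; we
iterate to an absolute bracket of 1e−9 and require 1e−6, clipping to
[0, 1]. Intervals are reported to three decimals, matching the precision
at which such trials print them.

Two open conventions were decided as follows. The attained stage-1 size is
assumed equal to the planned `n1` — a stage-1 deviation changes the
ordering itself and is rejected with an error rather than silently
accommodated. Denominators for response-rate inference are
RECIST-evaluable counts (here 36 and 27), not enrolled counts, because
those are the denominators of the observed rates being inverted.
Unconfirmed PRs count as responses. The clinical-benefit rate has no
design-linked ordering, so it gets the exact Clopper–Pearson interval via
beta quantiles; the test suite verifies both printed CB intervals match
that convention before relying on it.

## Gene ranking

Counts are normalised as
`logCPM = log2((count + prior) / (libsize + 2·prior) · 1e6)` with
`prior = 1`. Group comparison uses an empirical-Bayes moderated t: the
pooled within-group variance `s_g^2` on `d_g = n − 2` df is shrunk toward
a prior `s_0^2` with weight `d_0`,
`s̃_g² = (d0·s0² + d_g·s_g²)/(d0 + d_g)`, and the statistic is referred to
a t on `d0 + d_g` df. The hyperparameters come from matching the moments
of `log s_g²` to a scaled-F prior (digamma/trigamma identities, with a
Newton inverse-trigamma); when the observed log-variance spread is no
larger than pure chi-square noise, `d0 = ∞` and every gene uses `s0²`.
Setting `d0 = 0` disables shrinkage and recovers the ordinary
pooled-variance t exactly — a useful limiting check, asserted in the
suite. The implementation agrees with the established empirical-Bayes
implementation to machine precision on random matrices.

One deliberate divergence from common RNA-seq practice: no mean–variance
precision weights are applied to the logCPM values before the moderated
fit. The weights matter most for very small counts; here they would add a
modelling layer the rest of the pipeline does not depend on, at the cost
of self-containment. Rankings from the two approaches are close but not
identical, and downstream enrichment uses only the ranking.

Ties in the ranking statistic break lexicographically by gene identifier,
so every downstream result is deterministic.

## Preranked enrichment and the leading edge

The enrichment score is the extremum of the weighted Kolmogorov–Smirnov
running sum: walking down the ranking, a set member at position `i` adds
`|t_i|^w / Σ_{hits}|t|^w` and a non-member subtracts `1/(N − n_hits)`;
`w = 1` by default, `w = 0` giving the classic unweighted statistic. On an
exact tie between the positive maximum and negative minimum the positive
extremum is preferred. The leading edge is the set members at or before
the peak (positive ES) or at or after the trough (negative ES); the
extremum always falls on a hit, so a leading edge is never empty.

Significance uses gene-label permutations — set positions redrawn
uniformly, `n_perm = 1000` by default with a mandatory seed — which is the
only permutation scheme consistent with taking a single preranked list as
input. The p-value is `(1 + #{same-sign |ES*| ≥ |ES|}) / (1 + #same-sign)`
and `NES = ES / mean(|same-sign ES*|)`; a set with no same-sign
permutation score gets `NA` and is excluded from the BH adjustment. Sets
are filtered to `min_size = 5` and `max_size = 2000` members present in
the ranking. `n_perm = 0` skips permutations entirely, which is the cheap
path when only ES and leading edges are needed (as in signature
derivation).

The resistance signature is derived exactly as a cross-arm consensus:
within each arm, union the leading edges of the named pathways; then
intersect across arms; sort. Pathway names are configuration, not
hard-coded, because gene-set collections version faster than methods.

## Single-sample scoring and association

The rank-based score ranks each sample's values ascending (average ties),
takes the mean rank of the signature genes over `N`, normalises by the
theoretical bounds `(n_up + 1)/(2N)` and `(2N − n_up + 1)/(2N)`, and
centres by −0.5. Scores live in [−0.5, 0.5], hit the bounds exactly when
the signature occupies the extreme ranks, and are invariant to any
monotone transform of a sample — so counts, logCPM and vst inputs agree.
The z-mean score (for externally normalised data) z-scores each gene
across samples with the sample (n − 1) SD and averages over signature
genes, dropping zero-variance genes with a warning; the two-point example
in the tests pins the SD convention.

Associations: AUC by the rank-sum identity with midrank ties (equal to
concordant-pair counting, verified exhaustively), p from the
normal-approximated rank-sum test, with an orientation flip (`1 − AUC`)
available for resistance-type signatures whose high scores predict the
negative outcome; Wilcoxon rank-sum / signed-rank tests (exact for small
untied samples, tie-corrected normal otherwise; all-zero paired
differences give p = 1 with a warning); Spearman's rho on midranks with
the t-approximation, censoring ignored — observed times enter as-is,
mirroring how such exploratory scatterplots are usually drawn; a
censoring-aware association is out of scope. Survival comparisons use
Kaplan–Meier curves, the log-rank test, and a single-covariate Cox model
with Efron tie handling (the standard choice for continuous clinical
time); the high/low score split is at the median by default, a choice made
for symmetry rather than optimised — it is configurable at the call site.
The platinum-resistant stratified analysis is a row filter followed by the
same machinery, never a separate code path.

## The synthetic cohort generator

The generator is the package's test surface, and its defaults are the
study conditions for every planted-signal property: 15 CB + 15 NCB
samples, 2000 genes, a 20-gene resistance program at +1 log2 fold-change
in NCB, NB dispersions uniform on [0.05, 0.4] (bulk tumor RNA-seq scale),
baseline mean counts log-uniform on [5, 500], library size factors uniform
on [0.7, 1.3], hazard link θ = 0.8 per SD of true program activity on a
baseline exponential hazard of 0.2 events/month, censoring at 24 months.
Counts are NB with variance `μ + αμ²`. PFS is exponential conditional on
the true score. Response categories are drawn consistently with the
planted group and the simulated PFS — a CB sample with PFS < 4 months must
be a PR, an NCB sample with PFS ≥ 4 months must be a PD — so that
`label_benefit()` reproduces the planted groups exactly; an assignment
rule that ignored this coupling could contradict the CB definition it is
meant to exercise. One global seed expands into named substreams
(genes / counts / clinical), so regenerating one component never perturbs
another.

What the generator deliberately does not emulate: gene–gene correlation
(genes are independent given their means), batch effects, tumor purity,
library-composition bias, overlapping pathway structure, and informative
censoring. Passing the planted-signal tests therefore shows the pipeline
recovers signal *of the planted form* at realistic effect sizes and
sample counts — it does not certify performance on real tumors, where
correlated programs and confounding shrink effective information.

## Problem sizes and runtime choices

Test and driver problem sizes are chosen so every property has real
resolution while the whole suite stays interactive: design searches at
`n_max = 40–60`; Monte-Carlo design calibration at 100 000 replicate
trials (3-SE bands); null calibration of the moderated t at 2000 genes;
p-value uniformity at 2000 null cohorts; planted-signal recovery at 20
replicates of the default cohort; oracle equivalences at ≤ 50-gene
enrichment instances, ≤ 6-per-group rank tests, ≤ 12-sample AUCs.

## Known limitations

- The design engine covers single-arm binomial endpoints only; no
  randomised comparisons, survival-endpoint designs, or alpha-spending
  beyond the single conditional-error recalculation.
- The moderated-t ranking omits voom-style precision weights (above).
- Leading-edge derivation depends on gene-set definitions supplied by the
  user; no identifier mapping is attempted.
- The Cox association is single-covariate; the optional
  platinum-adjusted logistic regression common in such analyses is left
  to standard `glm()` at the call site.
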