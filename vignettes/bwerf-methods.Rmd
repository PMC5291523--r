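---
title: "Backward-elimination random forests for layered regulatory networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backward-elimination random forests for layered regulatory networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Metabolic and canonical pathways are rarely controlled by a flat set of
transcription factors (TFs). Regulation is layered: low-level regulators bind
the pathway genes directly, mid-level regulators coordinate them, and a few
high-level regulators respond to cellular and environmental signals. `bwerf`
reconstructs such a multilayered hierarchical gene regulatory network
(ML-hGRN) from an expression matrix, a list of bottom-layer pathway genes,
and a pool of candidate regulators.

## The procedure

For one layer, with $q$ bottom genes and $p$ candidate regulators observed on
$n$ samples, the network-inference problem is split into $q$ independent
regressions: bottom gene $j$'s profile is the response, the pool's profiles
are the predictors.

**Random forest and importance.** Each regression is fitted with a regression
random forest of fully grown trees (recursion stops only at zero response
impurity or indistinguishable predictor rows). At a node splitting $n$
samples into children of sizes $n_1, n_2$, the splitting variable earns

$$IV = n\,\delta_p - n_1\,\delta_{c1} - n_2\,\delta_{c2},$$

the decrease in variance, where $\delta$ denotes the *population* variance of
the responses in a node. Under that convention $n\delta$ is a sum of squared
deviations, so IV is additive: within a tree the per-feature importance (the
sum of IV over the nodes splitting on that feature) conserves the tree's
total variance decrease exactly, a property the test suite asserts. Forest
importance is the per-feature mean over trees.

**Backward elimination.** A single forest fit on a pool with hundreds of
noise variables dilutes the importance of moderate regulators: noise features
absorb splits deep in the trees. The algorithm therefore ranks the pool by
importance, removes the least important fraction (rate $r$, default 0.1,
never fewer than one), refits on the survivors, and repeats until one
regulator remains. A regulator's *final* importance is its value in the last
round in which it was modelled — the least noise-contaminated model that
still contained it. The alternative (keeping the first-round snapshot) would
simply reproduce the single-pass ranking for most of the pool and forfeit the
range expansion that makes true regulators separable, which is why last-seen
is the default and only behaviour.

**Aggregation.** Per-gene final importances are combined into one unified
value per regulator, $U(t) = \sum_j w_j \, I(t, g_j)$, with user weights
$w_j \ge 0$ (default 1) on the pathway genes only; promoted layers always use
unit weights. Raw values are aggregated — no per-gene re-normalisation — so a
regulator serving many pathway genes accumulates evidence; an optional
`normalize` flag in `aggregate_importance()` rescales each gene's vector to
sum 1 for sensitivity analysis.

**Layer selection.** The unified values are modelled as a $K$-component
univariate Gaussian mixture fitted by EM ($K = 2$ by default: background vs
regulators). The E-step computes posterior membership weights
$w_{ik} = \alpha_k \varphi_k(x_i) / \sum_l \alpha_l \varphi_l(x_i)$; the
M-step applies the closed-form updates for $\alpha_k$, $\mu_k$, $\sigma_k^2$.
Points whose posterior is maximal for the component with the largest mean
form the layer. A fixed count (`selection = "fixed"`) is available when the
user prefers to set the layer size empirically.

**Recursion.** Selected regulators are removed from the pool, become the new
bottom layer, and the procedure repeats until the requested number of layers
is built or the pool (or the selection) empties, in which case the build
stops early with a warning.

**Baseline.** `build_genie3_baseline()` is the single-pass reference: the
identical pipeline with exactly one forest fit per bottom gene and per-layer
retention counts matched to a completed elimination run, so the two networks
differ only in how they rank.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ntree` | 1000 | trees per forest; unitless count. Large values stabilise the ranking; 200 preserves the qualitative behaviour at a fifth of the cost and is what the heavy tests use. |
| `mtry` | `max(1, floor(p/3))` | candidate features per node, the standard regression-forest third. |
| `rate` | 0.1 | fraction of the pool removed per elimination round. Higher rates are faster but noisier; the ranking is stable down from 0.5 with decreasing variance. |
| `bootstrap_size` | `n` | bootstrap draws per tree, with replacement (classic bagging). |
| `K` | 2 | mixture components; background vs regulators. |
| `tol`, `max_iter`, `restarts` | 1e-8, 500, 5 | EM convergence control. |
| `edge_q` | 0.9 | quantile policy: an edge (t, g) is kept when t's final importance for g reaches the 0.9 quantile of all regulators' importance for g. |

## Numerical choices

- **Variance convention.** Population variance at every node, so importance
  is exactly additive and the re-traversal audit (`retrace_importance()`)
  can demand equality at 1e-12 rather than "close".
- **Split thresholds** are midpoints between consecutive distinct sorted
  feature values; ties in split quality resolve to the lowest feature index,
  then the lowest threshold, which makes a fit a pure function of
  `(X, y, params, seed)`.
- **Seeding.** A master seed derives one independent stream per
  (pathway gene, round) via integer hashing, so per-gene regressions can be
  computed in any order — or in parallel — without changing a single bit of
  the output. Elimination tie-breaks remove the lexicographically larger gene
  ID first.
- **EM in log space.** Membership weights are computed from log densities
  with row-wise log-sum-exp, so tail points never produce 0/0. Variances are
  floored at `1e-8 * var(x)`; an emptied component is re-seeded at the point
  the current model explains worst.
- **EM initialisation** is quantile-based (component $k$ at the
  $(k-0.5)/K$ quantile, shared global variance, uniform weights) plus five
  deterministically jittered restarts; the best log-likelihood wins.
- **Degenerate selection.** When the pool is smaller than $2K$, or the
  mixture assigns everything (or nothing) to the top component, selection
  falls back to the top $\lceil\sqrt{p}\rceil$ regulators with a loud
  warning; a top component larger than half the pool is also warned about,
  never silently truncated.
- **Evaluation.** PR/ROC curves take one point per distinct score (ties
  grouped, step semantics, no interpolation), the PR curve is anchored at
  recall 0 with the precision of the highest threshold, unscored universe
  pairs score 0, and areas use the composite trapezoidal rule.

## What the generators emulate

`simulate_toys()` reproduces the classic single-target benchmark: six true
TFs acting additively on one pathway gene ($X_{1..3} \sim N(1,1)$ the weak
block, $X_{4..6} \sim N(3,1)$ the strong block, coefficients all 1),
1000 independent $N(0,1)$ noise TFs, $n = 100$, response noise
$z \sim N(0, 0.1)$. The second parameter of a normal law is read as a
variance throughout; `noise_scale_is_sd` flips the convention for $z$, and
the package's own conclusions are insensitive to the choice.

One property of this design deserves emphasis: all six true TFs enter the
response with the same coefficient and the same variance, differing only in
mean. Variance-reduction splits are location-equivariant per feature, so
the six are *statistically exchangeable* as predictors — which of them tops
the ranking in a given realisation is arbitrary, and only the distinction
true-vs-noise is identifiable. The tests therefore assert block-level
properties (strong/true TFs above the noise) per seed rather than the
identity of the top variables.

`simulate_hierarchical()` is the recovery oracle for the layered builder:
independent top-layer regulators, each lower variable a positive linear
combination of 1–3 parents in the layer above plus Gaussian noise, plus
independent decoy TFs. The default noise scale (sd 1.5 against per-target
signal variance of roughly 1–3) puts per-target fits at $R^2 \approx$
0.3–0.6, the regime of real microarray regressions; at much lower noise both
the elimination and the single-pass ranking saturate near AUROC 1 and the
benchmark stops discriminating between methods.

`add_noise_genes()` mirrors the in-silico spiking design used for real-data
validation: appending 100–300 uninformative profiles to a TF pool. The
default `"permuted"` mode shuffles samples of existing columns, preserving
marginal distributions while destroying association — the download-free
analogue of drawing real non-regulator genes from the same data set;
`"gaussian"` appends standard normal columns.

None of the generators emulate mechanistic dynamics, feedback, combinatorial
(AND/OR) regulation, hidden confounders, or measurement batch structure.
Passing the recovery tests therefore shows the machinery ranks additive
linear-Gaussian signal correctly under heavy noise — not that real regulons
will be recovered at the same rates.

## Problem sizes used by the test suite

Full-size runs (1006 TFs, 1000-tree forests, tens of elimination rounds) are
the production setting. The automated checks run the full toys design at
`ntree = 200` over five seeds, the hierarchical benchmark
(10 regulators, 20 targets, 100 decoys, $n = 200$) at `ntree = 50` over ten
seeds, and scaled-down variants (50 noise TFs) inside module tests — sizes
chosen so the whole suite completes on a single CPU while preserving every
pass rule at its stated threshold.

## When elimination helps — and when it does not

Backward elimination is a remedy for noise-dominated rankings, i.e. the
$p \gg n$ regime where hundreds of irrelevant TFs absorb splits and dilute
moderate regulators. On the toys design (1006 TFs, 100 samples) the
acceptance runs show the eliminated ranking placing at least as many true
TFs above all noise as the single pass in the majority of seeds. The
converse also shows in the acceptance runs: on the hierarchical benchmark
(110 candidates, 200 samples — comfortably $p < n$) the single-pass forest
already ranks near-perfectly, and elimination only adds greedy selection
variance: a true parent that draws an unlucky early round is eliminated with
a low snapshot score and falls far down the final ranking, so the baseline's
whole-ranking AUROC is the higher one there. Users with more samples than
candidate regulators should prefer the single-pass ranking; elimination
earns its cost when candidates far outnumber samples.

## Known limitations

- Edges carry importance scores, not signs: activation and repression are
  not distinguished.
- "Linked pathway genes" for a selected TF is not uniquely defined by the
  aggregation; both policies (`quantile`, `all_positive`) are exposed and the
  sparse quantile default is a package choice.
- The mixture cut on a heavy-tailed importance background can include
  mid-tail decoys in the top component; the warning about implausibly dense
  layers, `K = 3`, or fixed-count selection are the remedies.
- Per-layer conditioning is greedy: an error in a lower layer propagates
  upward, which is inherent to the bottom-up construction.
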