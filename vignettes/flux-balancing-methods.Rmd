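---
title: "Methods: promoter-combination design and greedy ensemble regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-combination design and greedy ensemble regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promflux)
```

## The problem

A heterologous biosynthetic pathway — here the four-enzyme naringenin route
TAL → 4CL → CHS → CHI in *E. coli* — rarely performs best with every gene
maximally expressed. Flux is limited by the weakest step, intermediates can
be toxic when upstream capacity outruns downstream capacity, and pairwise
epistasis between enzyme variants makes the expression landscape rugged.
Promoter engineering addresses this by choosing, for each gene, one promoter
from a characterized panel; with 12 promoters and 4 genes the design space
holds 12^4 = 20,736 combinations — far more than a screening campaign can
cover, which motivates a learned surrogate model.

`promflux` implements that workflow end to end: library bookkeeping and
coverage mathematics, curation of colorimetric screening data into a
balanced training set, a greedy forward-selected ensemble of 13 base
regressors that predicts titer from the promoter combination, exhaustive
ranking of the design space, and a mechanistic simulator that stands in for
the wet lab so every stage can be tested.

## Library representation and coverage

A `library_spec` is an ordered set of gene positions plus a promoter
alphabet per position. Designs are encoded one-hot, block by block in
position order with alphabet order inside each block, giving a 48-column
binary matrix for the 12 × 4 library; the column layout is fixed by the spec
and persisted with `write_library_spec()` so feature matrices are
reproducible. Encoding and decoding are exact inverses, which the test suite
checks exhaustively over all 20,736 designs.

How many clones must a random library contain before every combination has
probably been seen? Under uniform independent draws the chance that all `n`
designs appear in `m` clones is approximated by treating designs as
independent,

P(m) ≈ (1 − (1 − 1/n)^m)^n,

and `coverage_sample_size(n, p)` inverts this for the smallest `m` with
P(m) ≥ p. For the full library at 95% coverage this gives 267,692 clones —
the order of magnitude that makes exhaustive screening impractical and a
model necessary. The approximation error against the exact
inclusion–exclusion coupon-collector probability is below 0.02 for the small
spaces where the exact sum is numerically stable, and the returned `m`
differs from the exact answer by at most one draw; both facts are asserted
in the tests, with a Monte Carlo check at `n = 100`.

The default roster ships 12 synthetic promoters whose strengths are
log-spaced across a 211-fold dynamic range — the spread reported for
characterized promoter panels of this kind — and are classified
low/medium/high by terciles of log-strength (boundaries assigned downward).
These defaults are placeholders: a real study should supply its own measured
strengths through `promoter_roster()`.

## Screen curation

The screening readout is an Al³⁺-complexation absorbance that increases
monotonically but sublinearly with naringenin titer. The calibration family
is a two-anchor power law

signal(t) = s0 + (s_max − s0) · (t / c_max)^h,

chosen because the three published anchor points — 0.01 a.u. at 0 mg/L,
0.2 a.u. at 130 mg/L, 1.34 a.u. at 1500 mg/L — are inconsistent with a
straight line but are fitted exactly by h ≈ 0.796. With more than one
interior point the exponent minimizes squared signal error; the curve is
strictly monotone so titer and signal maps are mutual inverses.

Curation mirrors a two-round screening funnel. `call_hits()` applies a
strict `signal > threshold` rule ("higher than" semantics throughout).
`assemble_balanced_set()` keeps every hit and adds a seeded uniform sample
of low-signal background records so the model also sees poor producers; 108
hits plus 50 background records reproduce the canonical 158-record training
set. The background draw is pooled by default; a `per_plate` flag stratifies
it evenly across plates instead, since a fixed per-plate quota and a fixed
total cannot both hold in general. `augment_threshold_scan()` adds
second-round records above each candidate titer cutoff, scores each
augmented set with a caller-supplied cross-validated trainer, and keeps the
cutoff with the lowest score; ties go to the largest cutoff, i.e. the
smallest augmentation, keeping the training set lean.

## The ensemble regressor

Thirteen base families span simple linear models through boosted trees:
ridge, lasso, k-neighbors, support-vector, decision-tree, random-forest,
extra-trees, adaptive-boosting, bootstrap-aggregating, gradient-boosting,
extreme-gradient-boosting, light-gradient-boosting, and
categorical-gradient-boosting. Three of them are implemented in the package
itself as standard published algorithms: AdaBoost.R2 with shallow regression
trees, bootstrap aggregation of regression trees, and a least-squares
gradient booster whose trees split directly on the promoter factors rather
than the one-hot expansion (the categorical-native family). The remaining
families are delegated to glmnet, caret, e1071, rpart, randomForest, ranger
and xgboost; the three gradient-boosting variants are distinguished by their
tree construction — exact greedy, histogram depth-wise, and histogram
leaf-wise growth. Hyperparameters are pinned in `default_roster()` and
treated as part of the experiment definition; per-estimator seeds derive
deterministically from one master seed.

Titers are strictly positive and their measurement error is multiplicative,
so by default every base estimator is fitted to log-titer and its
predictions are exponentiated before any averaging or scoring
(`target = "log"`). All metrics — RMSE and Pearson correlation — are always
computed on the raw mg/L scale, and `target = "identity"` restores direct
fitting for targets where the log scale is inappropriate.

Selection follows a rank-then-greedily-integrate scheme. Each estimator is
scored by 10-fold cross-validation (shuffled fold assignment under a fixed
seed); its out-of-fold predictions are pooled over all samples, and the
roster is sorted by CV RMSE, ties keeping roster order. Starting from the
top-ranked estimator, every remaining candidate is examined in rank order
and joins the ensemble iff the uniform average of the members' pooled
out-of-fold predictions plus the candidate's strictly lowers the ensemble
RMSE; rejected candidates are skipped and the scan continues to the end.
Using pooled out-of-fold predictions (rather than refitting) keeps the
selection honest — no candidate is evaluated on data it trained on — and
the strict-decrease rule keeps ensembles minimal. Equal-RMSE candidates are
rejected for the same reason. The accepted-state RMSE trace is therefore
strictly decreasing and the final ensemble can never be worse than the best
single estimator on the selection metric; both invariants are asserted on
every run in the test suite. The final predictor is the unweighted mean of
the member predictions, refitted on the full training set.

An estimator that fails to fit is recorded with infinite CV RMSE and a
warning rather than aborting the run, and a zero-variance training response
degenerates every family to the constant-mean predictor.

## Design ranking

`score_space()` predicts a titer for each of the 20,736 designs (chunked
internally; the full space scores in seconds on one CPU) and ranks them
descending, ties resolved by lexicographic assignment order so output is
deterministic across platforms. `top_k()` nominates candidates — five, in
the canonical workflow. For synthetic benchmarks, `enrichment_fold()`
measures (fraction of the top-k whose true titer lies in the true top-q
quantile) / q: 1/q for a perfect ranking, ~1 for a random one.

## The pathway simulator

The generator is a series-bottleneck ("resistors in series") model. Each
step's capacity is `k_i · s_i` — a per-enzyme rate coefficient times the
strength of the promoter driving it — and steady-state flux is

J = 1 / Σ_i 1/(k_i · s_i),

which is strictly increasing and concave in every strength, bounded above by
each single-step capacity, and makes the weakest step the bottleneck: the
largest marginal gain always comes from relieving it. Expected titer is
`yield_factor · J`, multiplied by `toxicity_penalty` whenever the strongest
upstream capacity exceeds the weakest downstream capacity by more than
`toxicity_ratio` — a minimal stand-in for intermediate toxicity that makes
over-driving an upstream gene harmful and generates sign-epistasis-like
interactions (demonstrated in the tests by a TAL/CHS quartet that the
epistasis classifier labels `sign`). Measured titer multiplies the
expectation by lognormal noise `exp(ε)`, ε ~ N(0, noise_sd²), and the assay
signal is read through the calibration curve.

Default parameters, chosen once as a realistic screen: capacities
(1, 0.8, 0.6, 1.2) flux units per strength unit for TAL/4CL/CHS/CHI so that
no two enzymes are equivalent and CHS is the congenitally weak step;
`yield_factor = 30` mg/L per flux unit, which puts simulated screens in the
tens-to-~1300 mg/L range of real campaigns; `noise_sd = 0.15` (≈15% relative
error, typical of plate-based colorimetric assays); `toxicity_ratio = 20`
and `toxicity_penalty = 0.5`, active in a minority of designs; upstream =
the first two steps (TAL, 4CL produce the coumarate/coumaroyl-CoA
intermediates that CHS and CHI consume), exposed as `upstream_steps`.

What the simulator does *not* emulate: cofactor (malonyl-CoA, ATP) balances,
growth–production coupling, plate and batch effects, promoter context
dependence, and sequence-level mutation effects. Passing the synthetic
benchmark therefore shows that the pipeline recovers a smooth monotone
landscape with mild interaction structure from a few hundred noisy samples —
not that it would perform identically on any real screen.

The epistasis classifier works on the log scale: ε = log f11 − log f10 −
log f01 + log f00 with an additivity tolerance of 0.05 log-units (about 5%,
roughly the resolution of triplicate titer measurements; configurable). If
either mutation's log-effect changes sign across backgrounds the pair shows
sign (one flip) or reciprocal-sign (both flip) epistasis; otherwise the
interaction is magnitude-only.

## Kinetics helpers

`fit_double_reciprocal()` estimates K_M and k_cat by ordinary least squares
on the Lineweaver–Burk transform (slope K_M/V_max, intercept 1/V_max),
because that is the standard bench-side method for these assays;
`fit_michaelis_menten()` provides the direct nonlinear fit as a cross-check,
since reciprocal-space regression is known to inflate low-substrate noise.
On noise-free data both recover planted parameters to numerical precision
(round-trip property in the tests). `catalytic_efficiency()` and
`fold_change()` complete the bookkeeping; printed kinetics tables sometimes
carry a rounded K_M, so the stored efficiency is only required to agree with
k_cat/K_M within 0.5%.

## Numerical and design notes

* Coverage inversion uses `log1p`/`expm1` to stay accurate at `n ~ 10^4`,
  and the returned count is verified minimal by direct evaluation at `m` and
  `m − 1`.
* The calibration exponent has a closed form with one interior point;
  otherwise a 1-D bounded optimization over h ∈ [10⁻³, 10³] is used.
* Fold assignment recycles 1..folds and shuffles under the CV seed, so fold
  sizes differ by at most one.
* All sampling runs under locally scoped seeds (the global RNG stream is
  saved and restored), so package calls never perturb user randomness.
* Tie-breaks are all deterministic: roster order in ranking, the larger
  threshold in the augmentation scan, lexicographic design order in
  `score_space()`.
* Benchmark problem sizes used in the test suite — a 3-promoter × 4-gene
  space for unit tests, and the full 12 × 4 space with n = 200 training
  samples and 10 fold-shuffle seeds for the end-to-end recovery benchmark —
  were chosen so the whole suite exercises every code path at realistic
  scale while remaining quick on a laptop.

## A worked example

```{r example, eval = FALSE}
spec <- default_library_spec()
screen <- simulate_screen(spec, pathway_params(), n = 500, seed = 1)

hits <- call_hits(screen, threshold = 0.2)
background <- dplyr::filter(screen, signal <= 0.2)
curated <- assemble_balanced_set(hits, background, n_background = 50, seed = 1)

model <- fit_ensemble(curated, spec, roster = default_roster(1),
                      cv = cv_config(10, 1))
glance(model)

designs <- score_space(model, spec)
top_k(designs, 5)
```

## Known limitations

* The default promoter roster is synthetic; results on it characterize the
  method, not any real promoter panel.
* Greedy forward selection explores only rank-ordered prefixes with uniform
  weights; a learned meta-model (stacking) is deliberately out of scope.
* The simulator's penalty term is a step function; real toxicity is graded.
* Cross-validated Pearson correlation on heavy-tailed titer distributions is
  dominated by the few highest producers and is accordingly noisy between
  fold shuffles.
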