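---
title: "Semantic embedding of protein sequence space: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic embedding of protein sequence space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Remote homology detection asks whether two protein domain sequences share an
ancestor even when their residue identity has decayed beyond what pairwise
alignment can recognize. Pairwise search programs (profile-based or HMM-HMM)
answer this locally, one pair at a time. `seqembed` instead exploits the
global structure of the similarity network those programs induce: it *learns*
a map of all database proteins into a low-dimensional "semantic" space in
which geometric proximity means homology.

Each database protein $x_i$ is represented by its similarity profile over the
$n$ database proteins,

$$ f(x)_j = \exp\!\big(-E(x, x_j)/\sigma\big), $$

where $E(x, x_j)$ is the E-value a teacher search program assigns to target
$x_j$ given query $x$, and pairs without a reported hit contribute exactly 0.
Since most pairs show no detectable similarity, $f(x)$ is sparse. Rows are
normalized to sum to one by default, so the feature matrix is the transition
matrix of a random walk on the similarity network. The embedding is linear,
$\phi(x) = W f(x)$ with $W \in \mathbb{R}^{d \times n}$, and retrieval ranks
the database by the distance
$D(x, y) = \lVert \phi(x) - \phi(y) \rVert_p$ (default $p = 1$), smaller
being better.

$W$ is learned by stochastic gradient descent on the margin ranking loss over
tuples $(q, p^{+}, p^{-})$ — a query, a teacher-similar protein (E-value
strictly below 0.1), and a random protein:

$$ L = \max\!\big(0,\; m + D(q, p^{+}) - D(q, p^{-})\big). $$

A violating tuple triggers the subgradient update; for the 1-norm the
subgradient applies the sign function componentwise, and only the columns in
the tuples' feature supports are touched, so a step costs
$O(d \cdot \mathrm{nnz})$. $W$ is initialized with i.i.d. standard normal
entries from the configured seed.

Structural side information enters as multitask learning sharing the same
$W$:

* **class centroids** (`aux_mode = "class"`): one learned column of a matrix
  $C$ per fold and per superfamily; each labeled protein is pushed closer to
  the sum of its own two centroid columns than to another example's columns,
  through the same hinge, updating $W$ and $C$ jointly;
* **auxiliary ranking tuples** (`aux_mode = "rank_label"` /
  `"rank_struct"`): extra tuples whose positives are same-superfamily pairs,
  or pairs whose structural-alignment score is strictly above 2.0.

The multitask objective is the sum of the main and auxiliary objectives; we
realize per-tuple SGD on that sum by alternating stochastic draws (one
auxiliary draw per main draw by default, `aux_ratio` configurable), which is
equivalent in expectation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `sigma` | 100 | E-value transfer width; larger keeps weaker hits |
| `d` | 250 | embedding dimension (100 recommended for HMM-HMM teachers) |
| `lr` | 0.05 | fixed SGD learning rate (0.02 for HMM-HMM teachers) |
| `margin` | 1 | ranking margin; only the ratio to `lr` matters |
| `p` | 1 | norm order of the embedding distance |
| `epochs` x `tuples_per_epoch` | 150 x 20,000 | training length |
| `pos_evalue_threshold` | 0.1 | strict upper bound on a positive's E-value |
| `struct_cutoff` | 2.0 | strict lower bound on a "similar" structural score |
| `aux_ratio` | 1 | auxiliary draws per main draw |

The margin defaults to 1, the usual margin-ranking convention: scaling the
margin and the learning rate together leaves the trajectory unchanged, so the
margin is not separately tunable in practice. All hyperparameters, the seed
and the database identifiers are stored in the fitted object, which makes a
saved model self-describing.

Boundary semantics are strict on both thresholds: a teacher E-value of
exactly 0.1 is *not* a positive, and a structural score of exactly 2.0 does
*not* generate auxiliary positives. Negatives are drawn uniformly from the
whole database and are not screened against the teacher — a negative may
occasionally be a true homolog, which the hinge tolerates — but degenerate
draws (`neg == q` or `neg == pos`) are rejected and redrawn, since a
zero-distance negative makes the hinge trivially maximal.

## Score calibration

Distances from different queries live on one common scale, but significance
statements need a null. We build an empirical null from decoy sequences drawn
from a third-order Markov chain fitted to the database (pseudocount-smoothed
transitions over 4-mers; ambiguity codes B/Z/J/U/O/X are mapped uniformly to
their standard expansions). Each decoy is scored by the teacher, embedded,
and its *best-hit* distance to the database recorded — the quantity retrieval
actually thresholds (`null_score = nearest`). Decoys are stratified into
geometric length bins (edges $25 \times 1.5^k$, 1000 decoys per bin by
default), and a query's p-value is read from the bin covering its length.

Because a best-hit score is a minimum over the database, its distribution has
support bounded away from zero. Two consequences shaped the fitting recipe:

* the Weibull fit carries an optional **location** parameter, profiled by
  maximum likelihood over $[0, \min(\text{samples}))$;
* fitting only the lowest `tail_fraction` (default 0.25) of the samples is
  done by **censored** maximum likelihood — samples above the tail threshold
  enter as right-censored observations — because a complete-sample MLE on a
  truncated subsample estimates the truncated shape, not the tail, and
  extrapolates badly.

P-values use the Weibull CDF below the tail threshold (the significant
region, where empirical counts are sparse and a parametric tail is needed)
and the linearly interpolated empirical null CDF above it, which the Weibull
tail continues smoothly. This keeps null p-values uniform across their whole
range, which the test suite checks by a Kolmogorov–Smirnov bound on fresh
decoys.

Multiple testing over a ranked database is corrected by the
$\pi_0$-adjusted Benjamini–Hochberg step-up,
$q_i = \min_{p_j \ge p_i} \min(1, \pi_0\, m\, p_j / r_j)$, with $\pi_0$
estimated by the single-$\lambda$ Storey estimator at $\lambda = 0.5$
(clamped to $(1/m, 1]$); the spline-smoothed variant buys little at database
scale and costs determinism. The conventional reporting threshold is
$q \le 0.01$.

## Evaluation

Targets are labeled relative to a query from a fold/superfamily/family
hierarchy: same superfamily is positive, different fold is negative, same
fold but different superfamily is *ignored* (homology uncertain). An optional
family-exclusion mode additionally ignores the query's own family so that
performance cannot rest on easy family-level matches. Rankings are scored by
ROC$_n$ — the area under the ROC curve truncated at the $n$-th false
positive, normalized so that a perfect prefix scores 1 — with $n = 1$ and
$n = 50$ conventional. Queries with no positives have undefined scores and
are excluded from means, with their count reported. Ties in distance are
broken by ascending target identifier before labeling, so ROC scores are
identical run to run. Methods are compared by the paired two-sided Wilcoxon
signed-rank test (exact below 15 non-zero untied differences, tie-corrected
normal approximation otherwise).

## The synthetic benchmark

`generate_fixture()` builds a self-contained stand-in for a structural
classification benchmark: 4 folds x 2 superfamilies x 2 families x 6 members
(96 sequences, lengths 80–120). Each superfamily has an independent random
ancestral sequence; family ancestors are substitution-mutated copies
(rate 0.30) and members mutated copies of those (rate 0.10). The teacher is
simulated directly: log10 E-values are normal per relationship tier
(family: mean −20, sd 3, reported with probability 0.95; same superfamily,
different family: mean −8, sd 3, probability 0.85; everything else: mean 1,
sd 0.8, probability 0.04), self-hits at E = 0. Structural scores are normal
per tier around means 4.0 / 1.5 / 0.4 so that within-superfamily pairs
usually clear the 2.0 cutoff and cross-fold pairs essentially never do. These
rates make within-superfamily pairs detectable below E = 0.1 over 80% of the
time while leaving the feature matrix more than 80% sparse — the qualitative
structure the method relies on.

What the fixture deliberately does **not** emulate: indels and alignment
artifacts (mutations are substitution-only, so the teacher needs no
alignment), compositional bias, domain architecture, asymmetric E-value
scales between iterated and non-iterated searches, and database-scale class
imbalance. Tests passing on the fixture therefore demonstrate that the
machinery — tuple sampling, gradients, calibration, scoring — does what it
claims under the assumed statistical structure, not that any particular
accuracy transfers to a real structural benchmark.

Test and example runs use desk-scale problem sizes chosen to exercise every
code path: d = 10, 30 epochs x 2,000 tuples on the 76-sequence training
split with 20 held-out queries, and 2,000 decoys per length bin for
calibration. The full-scale defaults (d = 250, 150 x 20,000) are what a real
database run would use through the command-line driver.

## Numerical choices and degenerate inputs

* Transfer weights below 1e-12 are dropped from sparse storage, making the
  teacher's "no detectable similarity" sentinel E-values exact zeros
  deterministically.
* Row normalization divides only non-empty rows; all-zero feature vectors
  (e.g. a decoy with no teacher hits) embed to the origin and are flagged,
  not errored.
* The 1-norm subgradient uses `sign()`, which is 0 at exactly 0 — a measure
  -zero event that finite-difference tests avoid by excluding
  sign-discontinuity neighborhoods.
* Epoch 0 returns the seeded random initialization; the whole fit, the decoy
  calibration and the neighborhood maps are bitwise reproducible from
  (inputs, config, seed).
* Classical (double-centering) multidimensional scaling was chosen over
  stress-minimizing variants for the neighborhood maps because it is
  deterministic and has no convergence parameters; coordinates are unique
  only up to sign and rotation, so tests compare preserved distances.
  Degenerate all-equal point sets project to coincident coordinates.
* Weibull fitting refuses degenerate (all-equal) samples and fewer than 200
  null scores per bin; a query length outside every calibrated bin falls
  back to the nearest bin with a warning.

## Known limitations

* Retrieval is an explicit linear scan, linear in the database size per
  query; no approximate nearest-neighbor index is provided.
* The embedding is defined for single domains; multidomain queries violate
  the transitivity the training objective assumes and must be decomposed
  upstream.
* Teacher scores are always consumed from files; running the search programs
  themselves is out of scope.
* The class-centroid task allocates centroids for the label set given at
  fitting time; labels unseen then cannot be added incrementally.
* `estimate_pi0` uses one fixed $\lambda$; with very few targets the
  estimate is coarse (it is clamped rather than smoothed).

## Workflow sketch

```{r}
library(seqembed)

fx <- generate_fixture(fixture_config(seed = 1))
split <- holdout_split(fx, n_test = 20, seed = 2)
tr <- split$train
th <- fx$hits[fx$hits$query_id %in% tr & fx$hits$target_id %in% tr, ]

fm <- build_feature_matrix(th, tr, sigma = 100, normalize = TRUE)
fit <- seqembed(fm, th, config = seqembed_control(
  d = 10, lr = 0.05, epochs = 30, tuples_per_epoch = 2000, seed = 7
))

qh <- fx$hits[fx$hits$query_id %in% split$test & fx$hits$target_id %in% tr, ]
qf <- query_features(qh, split$test, tr)
ev <- evaluate_queries(fit, qf, fx$labels, n_cap = 1)
mean_roc(ev)

mk <- fit_markov_null(fx$sequences, order = 3, seed = 5)
cal <- calibrate_null(fit, mk, make_decoy_teacher(fit$ids),
                      length_range = c(80, 120), seed = 11)
ranking <- predict(fit, qf[1, , drop = FALSE], type = "ranking")
add_significance(ranking, cal, query_length = 100)
```
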