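---
title: "Sparse rule ensembles from regularized random forests: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse rule ensembles from regularized random forests: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleforest)
```

## The problem

Random-forest regression is accurate on nonlinear biological data but opaque:
a 500-tree forest on a few hundred samples contains tens of thousands of
root-to-leaf paths, each one an IF-THEN regression rule, and no human reads
them. Single regression trees are readable but weak. This package implements
the middle road: keep the forest's rich candidate-rule pool, then let a
1-norm-regularized linear program select a handful of rules that carry the
ensemble's predictive signal, and drop the features those rules never
mention.

## The model

Given training data $(x_i, y_i)$, $i = 1, \dots, l$, a regression forest of
$T$ trees is grown. Every leaf $j$ of every tree defines a rule: the
conjunction of split tests on the path from the root, predicting the leaf
value $a_j$. With $q$ leaves in total, each sample is encoded into *rule
space* as $X_i \in \mathbb{R}^q$ with

$$X_{ij} = a_j \text{ if sample } i \text{ reaches leaf } j, \quad 0
\text{ otherwise},$$

so each row has exactly one nonzero coordinate per tree. A linear model in
rule space, $\hat y = w^\top X + b$, contains the forest itself as the
special case $w_j = 1/T$, $b = 0$ (the package asserts this identity to
$10^{-9}$). Sparse weights are found by the linear program

$$\min_{w, b, \xi} \; \lambda \lVert w \rVert_1 + \sum_{i=1}^l \xi_i
\quad \text{s.t.} \quad \lvert w^\top X_i + b - y_i \rvert \le \xi_i,
\; \xi_i \ge 0,$$

an L1-regularized least-absolute-deviation fit with an unpenalized free
intercept. Rules with zero weight are removed; features appearing in no
surviving rule are removed; the forest is regrown on the survivors; and the
loop repeats until two consecutive iterations select the same feature set.

Because a leaf value can itself be zero, coverage ("sample $i$ reaches leaf
$j$") is tracked in a boolean pattern matrix alongside the numeric matrix;
the numeric matrix is what the LP consumes.

## The LP solver

No general LP library is required: the package ships a primal-dual
interior-point solver (Mehrotra predictor-corrector) specialized to this
program. The standard split $w = u - v$, $u, v \ge 0$ and the substitution
$s_1 = \xi - r$, $s_2 = \xi + r$ (for residual $r$) give an equality-form LP
whose normal-equation system is only $l \times l$; the free intercept adds
one dense row handled by block elimination. Each iteration therefore costs
one sparse rank-update and one Cholesky factorization of an $l \times l$
matrix, independent of $q$ — the property that makes 5-fold cross-validation
over a 20-point $\lambda$ grid on a 37,000-column rule matrix affordable.

Three practical layers sit on top of the core iteration:

* **Analytic certificate for large $\lambda$.** $w = 0$, $b =
  \operatorname{median}(y)$ is optimal exactly when a dual vector $\theta$
  with $\lvert\theta_i\rvert \le 1$, $\mathbf{1}^\top\theta = 0$ and
  $\lvert X_j^\top \theta\rvert \le \lambda$ attains the intercept-only
  objective $\sum_i \lvert y_i - b\rvert$. The sign pattern of $y - b$
  provides such a certificate for every $\lambda$ beyond the data-driven
  scale, so the upper half of the regularization path costs nothing and the
  limit behaviour ($w = 0$, objective $= \sum\lvert y - \text{median}\rvert$)
  is exact rather than approximate.
* **Column generation.** For wide rule matrices the LP is solved on a
  working subset of columns; the solve is accepted only once dual
  feasibility $\lvert X_j^\top p\rvert \le \lambda$ is verified for *every*
  column, so the outcome is the full problem's optimum, not a heuristic.
  Along a cross-validation path the active set of the previous (larger)
  $\lambda$ seeds the next working set.
* **Support polish.** Interior-point iterates approach the analytic center
  of the optimal face, so weights that are zero at a vertex come back as
  $10^{-9}$-size dust. After convergence the LP is re-solved on the support
  of $w$ (weights above $10^{-6}$ of the largest); the polished solution is
  kept only if its objective matches the unpolished one to $10^{-7}$
  relative. Off-support weights are then *exactly* zero, which is what makes
  pruning provably prediction-invariant and retained-rule counts
  well-defined.

Solver tolerances: duality gap and feasibility below $10^{-8}$ for final
fits, $10^{-6}$ inside cross-validation (only held-out mean squared error is
consumed there). A solve that cannot reach $100\times$ its tolerance reports
`solver_status = "numerical-failure"` rather than returning silently.

## Choosing $\lambda$

The grid is 20 logarithmically spaced values spanning $10^{-3}$ to $10^{3}$
times the estimated smallest $\lambda$ at which $w = 0$ becomes optimal
(the dual bound $\max_j \lvert X_j^\top \operatorname{sign}(y -
\operatorname{median} y)\rvert$). Each candidate is scored by mean held-out
squared error over $k$ folds (default 5).

Two selection rules are available. `rule = "min"` takes the score-minimizing
$\lambda$ (ties toward the larger value). The default is `rule = "1se"`: the
largest $\lambda$ whose score is within one standard error of the minimum.
The one-SE rule is the standard parsimony-favouring variant of
cross-validation, and it is the one consistent with this method's purpose
and observed behaviour: plain score minimization retains on the order of a
percent of the forest's rules (hundreds of rules on the six-cluster
benchmark) because many small rule weights buy a marginal error reduction,
while the one-SE rule produces the compact models — well under one percent
of the candidate pool — that make the rule listing worth reading. Users who
want maximal accuracy regardless of model size can switch to `"min"`.

Retained-rule counts under the one-SE rule are seed-sensitive (tens to a
few hundred on the benchmark, depending on where the one-SE threshold cuts
a flat score curve); the selected feature set and the test accuracy are far
more stable. This mirrors the method's character: reruns reshuffle which
near-equivalent rules represent a region, not what the model predicts.

## The refinement loop

Feature elimination is embedded, not filter-based: a feature survives only
by appearing in a rule the LP kept. Iteration $k$ grows a fresh forest on
the surviving features (seed derived as master seed + iteration, so the run
is reproducible without artificially identical forests; a `"fixed"` seed
policy is available), re-selects $\lambda$ by cross-validation, solves the
LP, prunes, and recomputes the feature set. Convergence is declared when two
consecutive iterations select the same set, so an immediate fixed point
still takes two iterations (the second is the confirmation). Guards: a cap
of 20 iterations, cycle detection (stop with a warning if a set recurs),
and an explicit constant-intercept model with a warning if the set empties
(as happens on pure noise, where it is the correct answer). The feature
count is non-increasing by construction, which is asserted in the tests.

## Evaluation protocol

* **Accuracy**: $R^2 = 1 - SS_{err}/SS_{tot}$ on a held-out split; may be
  negative; errors out (rather than returning NaN) on a constant truth.
* **Interpretability**: retained-rule count, conditions per rule (mean and
  SD, counted after merging repeated splits on a feature into one
  interval), and the number of distinct features used.
* **Confusion heatmap**: the combined range of true and predicted values is
  cut into 20 equal-width bins; the true-bin x predicted-bin count matrix is
  normalized by its maximum entry. Equal-width binning over the *union*
  range was chosen so that systematic over- or under-prediction shows up as
  off-diagonal mass instead of being clipped away.
* **Noise robustness**: over $n$ runs with fresh 70/30 splits, each feature
  value is perturbed with probability 0.3 by adding $N(0.5, 0.2)$ noise
  (defaults; applied to train and test, configurable to either), and
  $D = \overline{R^2}_{clean} - \overline{R^2}_{noisy}$ is reported with a
  two-sided paired t-test over the per-run pairs. Noise, split and fit seeds
  are drawn from separate derived streams, so a no-op perturbation yields
  $D = 0$ exactly — a property the tests assert. The forest's own $D$ is
  reported alongside as the robustness baseline.

## Synthetic benchmarks

`make_artificial()` builds the six-cluster benchmark: six isotropic
Gaussian clusters (sd 0.5, 100 samples each) whose numeric labels 1-6 are
the regression target. The cluster centres are a reconstruction chosen so
that the decision boundaries fall where the method's reference rule listing
places them (thresholds near $x_1 \approx 3.7$-$3.8$, $x_2 \approx
1.9$-$2.0$ and $x_2 \approx 3.9$), with spacing about 2 at sd 0.5; they are
configurable and should be read as a geometry of that *kind*, not as
measured ground truth. On this layout the forest reaches a test $R^2$
around 0.9 and the pruned model follows within a few hundredths while
keeping well under 1% of the rules. Because the clusters are fairly well
separated, even very sparse models remain accurate here; data with heavier
class overlap would show a larger accuracy gap between forest and sparse
model at the same sparsity.

`make_sparse_signal()` plants a known signal: i.i.d. standard-normal
features, of which a chosen few drive the target through step functions
(threshold-based, hence exactly representable by tree rules) plus Gaussian
noise. The returned informative set enables recovery scoring. The recovery
experiment in the test suite uses shallow trees (`min_samples_leaf = 150`
on 500 samples) with `max_features = "all"`: with few informative features
among many, exhaustive split search concentrates the top splits — and hence
the rule conditions — on the signal, which is precisely the mechanism the
embedded elimination relies on. Deep trees on wide noisy data dilute rules
with incidental noise-feature splits and make "appears in a retained rule"
a weak filter; this is a real limitation of the elimination criterion, not
of the fixture.

What passing these tests shows: the pipeline recovers planted structure,
matches its analytic identities, and reproduces the reference experiment's
accuracy profile under the stated geometry. What it does not show: behaviour
under heavy feature correlation, mixed types (inputs must be numeric;
encode categoricals upstream), missing data, or targets whose structure
trees cannot express compactly.

## Numerical and degenerate-input choices

* Tree ties at a threshold go left (`<=`), matching the underlying
  forest's split semantics; thresholds are kept at full precision and
  rounded only for display (default 2 decimals).
* Rules are ordered tree-major then by leaf id, so rule-matrix columns are
  reproducible across runs with the same seed.
* Bagged trees occasionally contain an unreachable branch (an empty
  interval after simplification). Such leaves are kept — the rule count
  must equal the leaf count and their columns are identically zero — and
  the LP fixes their weights at zero.
* A constant target makes every leaf predict the constant; $R^2$ is
  refused (undefined) rather than silently returned.
* Zero-tolerance for pruning defaults to $10^{-8} \max(1, \max_j |w_j|)$;
  with polished solutions the discarded weights are exact zeros, so the
  tolerance only matters for unpolished solver output.
* Serialized models store thresholds and weights with 17 significant
  digits, which round-trips IEEE doubles exactly; a reloaded model predicts
  bit-identically through the condition-evaluation path.

## Problem sizes in the test suite

The suite exercises the reference six-cluster experiment at its stated
size (600 samples, 500 trees, 10 seeded repetitions), the recovery
experiment at 500 samples x 50 features over 20 seeded runs, and the noise
protocol at 10 runs; unit tests use miniature forests (tens of trees) where
only logical behaviour, not accuracy, is at stake. These sizes are the
package's own choice of what each property needs to be demonstrated
convincingly.

## Known limitations

* The LP is solved exactly (no lasso/coordinate-descent approximation), so
  very large rule matrices pay real solver time; column generation keeps
  this tractable to a few hundred thousand columns but not beyond.
* Retained-rule counts are not a stable statistic across seeds (see above);
  report the feature set and accuracy alongside any rule count.
* The elimination criterion is union-based: one noisy condition inside an
  otherwise useful rule keeps that noise feature alive. Shallow trees
  mitigate this; a per-condition relevance test would be a methodological
  extension, and is out of scope here.
* Ordered targets are treated as plain numbers; ordinal-aware variants are
  out of scope.
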