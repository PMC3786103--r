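---
title: "GA-MLR QSAR modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GA-MLR QSAR modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarga)
```

## The modelling problem

A QSAR (quantitative structure-activity relationship) study starts from a
table of compounds described by computed molecular descriptors and a
measured biological activity, here the half-maximal inhibitory
concentration IC50. The package models the transformed activity

$$\mathrm{pIC}_{50} = -\log_{10} \mathrm{IC50\,(mol/L)} = 6 - \log_{10} \mathrm{IC50\,(\mu M)}$$

as a linear function of a small descriptor subset,

$$\mathrm{pIC}_{50} = \beta_0 + \sum_{j=1}^{k} \beta_j d_{j} + \varepsilon,$$

fitted by ordinary least squares. The scientific work is not the fit — it
is choosing the $k$ descriptors out of hundreds of candidates, and then
demonstrating that the chosen model predicts rather than memorizes. The
package therefore implements the full conventional battery around the
regression: descriptor filtering, genetic-algorithm (GA) and stepwise
subset selection, cross-validated $Q^2$ statistics, Y-randomization,
and leverage-based applicability-domain diagnostics.

Activity units are never guessed: the loader requires an explicit
declaration (`uM_IC50` or `pIC50`), because a silent unit error is the
classic irrecoverable QSAR mistake. Missing descriptor values are
rejected at load rather than imputed.

## Descriptor filtering

Two reductions precede any selection:

* **Near-constant removal** (`remove_constant`): descriptors with sample
  variance at or below `variance_tol` (default $10^{-8}$) are dropped.
  The tolerance quantifies "almost constant"; a strictly-zero test would
  keep numerically useless columns alive.
* **Inter-correlation filter** (`decorrelate`): among any pair with
  $|r| >$ `threshold` (default 0.90), only one is kept. The survivor is
  the member more correlated with the activity, with ties broken by
  column order — a deterministic, auditable rule. Every drop is logged as
  (dropped, kept, $r$). When a train/test split exists, the filter sees
  training rows only, so the held-out compounds cannot influence which
  descriptors survive.

## Genetic-algorithm subset selection

Each candidate subset is a binary chromosome over the descriptor pool.
The defaults are the conventional small-population configuration for
descriptor selection: 30 chromosomes, on average five active genes in
the initial population, at most 30 variables per model, 1% per-gene
mutation, 50% crossover probability, and fitness based on
cross-validated explained variance over five deletion groups:

$$Q^2_{cv} = 1 - \mathrm{PRESS}/\mathrm{TSS},$$

with PRESS pooled over groups, each group predicted from an OLS fit on
its complement. Maximizing $Q^2_{cv}$ is identical to minimizing PRESS.

Three design choices deserve explanation, because naive CV-fitness GAs
fail quietly at QSAR sample sizes (tens of compounds):

1. **Averaged fitness** (`fitness_repeats`, default 10). A single random
   partition of ~30 compounds into five groups yields a noisy $Q^2$; a
   subset search over thousands of candidates will reliably find subsets
   that exploit one particular partition. The fitness is therefore the
   mean $Q^2_{cv}$ over several deterministic reshuffles of the deletion
   groups.
2. **Parsimony-corrected selection score** (`parsimony_penalty`, default
   0.025). Even with averaging, an extra variable can always buy a small
   apparent $Q^2$ gain by fitting quirks of the finite sample, so
   chromosomes compete on $Q^2_{cv} - 0.025\,k$. The penalty sits between
   the small spurious gain an uninformative variable typically brings at
   these sample sizes and the much larger contribution of a genuinely
   informative descriptor, so it prunes hitchhikers without starving the
   model. The reported fitness values are always the uncorrected
   $Q^2_{cv}$; the penalty shapes the search only.
3. **Memetic elite refinement.** The carried-over elite is improved by a
   steepest single-bit-flip local search each generation. This is the
   deterministic cleanup step that sheds the riders a stochastic search
   leaves in an otherwise good chromosome; its cost is negligible
   because fitness values are cached.

Selection is binary-tournament, crossover is uniform, infeasible
chromosomes (zero or too many genes) are repaired by random flips toward
feasibility so the population size never changes, and the single best
chromosome always survives — which makes the per-generation best
selection score non-decreasing. The search stops after
`max_generations` (200) or 30 generations without improvement. A run is
a pure function of `(dataset, config, seed)`.

The regression inside the fitness is OLS, matching the final model and
every downstream statistic; a latent-variable (PLS) fitness is a
possible extension point but is not implemented, since with at most 30
variables and ~30 training compounds the OLS reading is the coherent
one. The number of generations is a budget choice, not a convergence
guarantee; the stagnation rule is what normally terminates a run.

A classical forward/backward stepwise search on partial-F p-values
(`stepwise_select`, enter at $p < 0.05$, remove at $p > 0.10$) is
provided as the baseline selection tool.

## Validation battery

All cross-validated coefficients have the $1 - \mathrm{PRESS}/\mathrm{TSS}$
form, with TSS about the full-sample mean:

* $Q^2_{LOO}$ uses the exact OLS identity $e_{(-i)} = e_i/(1 - h_i)$ —
  no refitting; the identity is verified against explicit refits to
  $10^{-10}$ in the test suite. Leverage $h_i = 1$ (an exactly
  interpolated compound) is a hard error.
* $Q^2_{LGO}$ repeats random partitions into groups of
  $\lceil n \cdot \mathrm{fraction}\rceil$ (default fraction 0.2, i.e.
  five deletion groups, 100 repeats) and pools PRESS and TSS over all
  repeats.
* $Q^2_{BOOT}$ (default 5000 resamples) fits on each bootstrap resample
  and scores only the out-of-bag compounds, pooling squared errors over
  all resamples; reference deviations use the full-sample mean.
  Aggregating pooled errors rather than averaging per-resample $Q^2$
  values is the documented convention here — it is the stabler of the
  two and fully specified, so results are reproducible. Rank-deficient
  resamples are skipped and counted; more than 50% skips is an error.
* **Y-randomization** permutes the response, refits, and records
  training $R^2$ and $Q^2_{LOO}$ per iteration (default 10 iterations,
  the size of a conventionally reported table). For an informative
  model, both original statistics should tower over every permuted
  value; the null expectation of the permuted $R^2$ is $k/(n-1)$ for an
  independent design.
* **External validation** reports $\mathrm{RMSE}_{test}$ and
  $R^2_{test} = 1 - \mathrm{RSS}/\mathrm{TSS}$ with TSS about the
  test-set mean (the training-mean reference is the documented
  alternative). A single test compound or constant test response leaves
  $R^2_{test}$ undefined (`NA` with a warning); the RMSE is still
  returned. No F statistic is reported for the external set — there is
  no standard convention for one, and the test-set $R^2$/RMSE pair says
  what needs saying.

Training statistics follow the standard conventions: $R^2$, adjusted
$R^2 = 1 - (1-R^2)(n-1)/(n-k-1)$ (training role only), overall-regression
$F$, and $\mathrm{RMSE} = \sqrt{\mathrm{RSS}/n}$ — the $n$ denominator,
because a reported QSAR "root mean square error" conventionally carries
no degrees-of-freedom correction.

## Applicability domain and descriptor diagnostics

* **Leverage**: $h_i = \tilde x_i^T(\tilde X^T\tilde X)^{-1}\tilde x_i$
  with the intercept-augmented training design, i.e. the hat-matrix
  diagonal. This makes $\sum_i h_i = p$ (variables + intercept) and the
  warning leverage $h^* = 3p/n$ internally coherent.
* **Williams classification**: standardized residual = raw residual /
  training RMSE (externally studentized residuals are a stricter
  alternative; the simple form is what Williams plots conventionally
  display), cutoff $\pm 3$ by default. Compounds are flagged
  `high_leverage` ($h > h^*$), `outlier` (|std. residual| > cutoff),
  `both`, or `in_domain`; the emitted table plus the $h^*$/cutoff
  metadata is exactly the data behind a Williams plot.
* **VIF**: $1/(1-R_j^2)$, computed as the diagonal of the inverse
  correlation matrix; advisory bands (1 = none, up to 5 acceptable,
  above 10 unstable) are attached as labels, never enforced as errors.
* **Mean effects**: $MF_j = \beta_j\sum_i d_{ij} / \sum_k \beta_k \sum_i
  d_{ik}$, the coefficient-weighted share of each descriptor in the
  model's total signal; the intercept is excluded and reported as 0, and
  the values sum to 1 whenever the denominator is nonzero (a near-zero
  denominator is an error, since the shares are then meaningless).

## The synthetic benchmark

Because published QSAR studies rarely deposit their descriptor tables,
the package ships a generator (`synthetic_spec`/`generate_qsar`)
producing compound-by-descriptor matrices from a zero-mean,
unit-variance multivariate normal with a configurable correlation
structure, plus a sparse linear activity with Gaussian noise. Normal
descriptors make the null expectations used in the validation tests
(e.g. $E[R^2] = k/(n-1)$ under permutation) exact. An exchangeable-$\rho$
shorthand is provided because hand-writing large positive-definite
matrices is error-prone.

`benchmark_spec()` fixes the canonical study conditions: 36 compounds,
50 candidate descriptors, exchangeable $\rho = 0.3$ (moderate residual
correlation, which is what a descriptor pool looks like *after* the
$|r| > 0.90$ filter), five true descriptors with coefficients
$(1.5, -1.2, -2.0, 2.5, 1.8)$, and noise fixed analytically at
$\sigma = \sqrt{b^T\Sigma_S b \cdot 0.15/0.85} = 1.5748$ so the
population $R^2$ of the true model is 0.85 — the regime a well-fitting
small-molecule QSAR model occupies.

What the generator does **not** emulate: real descriptor distributions
(counts, heavy tails, block structure of descriptor families),
activity-dependent heteroscedasticity, and measurement error in the
descriptors themselves. Selection-power results on the benchmark
therefore demonstrate algorithmic correctness under known truth, not
performance guarantees on laboratory data.

## Numerical choices and degenerate inputs

* Rank deficiency in a design is detected by QR rank plus a relative
  condition bound of $10^{12}$; the offending column is named.
* `fit_ols` requires $n \ge k + 2$; LOO/bootstrap/Y-randomization
  require $n \ge k + 3$.
* The train/test split assigns `round(n * fraction)` compounds to the
  test set (36 compounds at 0.2 give the conventional 29/7 partition).
* Constant observed activity makes $R^2$ undefined (error); an exactly
  interpolating model makes standardized residuals 0 rather than 0/0.
* All stochastic routines take explicit integer seeds and restore the
  caller's RNG state; nothing reads or writes global random state.

## Problem sizes in the test suite

The suite exercises the oracle equivalences on ~100 random instances of
up to 40 compounds and 8 descriptors, the permutation null on 2000
permutations at $n = 29$, $k = 5$, and the GA selection-power benchmark
on 20 seeded runs of the canonical 36 x 50 problem — sizes chosen to
match the sample-size regime the methods target while keeping a full
test run comfortably interactive.

## Known limitations

* The GA fitness refits OLS, so candidate subsets are limited to
  $k < n_{train} - 2$; very high-dimensional pools should be filtered
  first (as the workflow does).
* $Q^2_{BOOT}$'s pooled out-of-bag definition is one of several in use;
  values are comparable across runs of this package but not necessarily
  across software.
* The applicability domain is leverage-only; distance-to-model and
  density-based definitions are out of scope.
* Descriptor computation itself (Dragon-style blocks, 3D optimization)
  is out of scope: the package starts at the descriptor table.
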