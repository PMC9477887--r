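---
title: "Batch correction for microbiome counts by conditional quantile regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch correction for microbiome counts by conditional quantile regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microbiome taxa read counts assembled across sequencing runs, processing
sites or studies carry systematic non-biological variation — batch
effects. Unlike expression data, taxa counts are zero-inflated,
over-dispersed and compositionally constrained, so location-scale
adjustments built for (log-)normal-ish data remove batch signal
incompletely and can distort the zeros entirely. `cqbatch` removes batch
effects by modelling, for every taxon and every sample, the *entire*
conditional count distribution, and transporting each observation to the
distribution the sample would have shown had it been processed in a
chosen reference batch.

## The model

Write $Y_{ij}$ for the count of taxon $j$ in sample $i$, $\mathbf{Z}_i$
for the sample's intercept, key variable(s) and covariates, and
$\mathbf{B}_i$ for $B-1$ batch dummies (the reference batch is the
all-zero row). Per taxon (subscript $j$ dropped), two parts are fitted on
all samples:

1. **Presence**: a logistic model
   $\mathrm{logit}\,P(Y_i > 0 \mid \mathbf{X}_i) =
   \mathbf{Z}_i^\top\zeta + \mathbf{B}_i^\top\gamma$.
2. **Positive counts**: linear quantile regression on jittered counts
   $W_i = Y_i + U_i$, $U_i \sim \mathrm{Uniform}(0,1)$, over a grid of
   levels $\tau$:
   $Q_{W_i}(\tau \mid \mathbf{X}_i, Y_i > 0) =
   \mathbf{Z}_i^\top\alpha(\tau) + \mathbf{B}_i^\top\beta(\tau)$.
   Jittering breaks the ties that make quantile regression on integers
   ill-defined, and is inverted exactly on the count scale by
   $\max(\lceil q \rceil - 1, 0)$.

For each sample the fitted parts are assembled into a zero-inflated
conditional quantile function: percentiles up to $1-\hat\pi$ are zero and
the monotone-rearranged positive-count quantiles are squeezed into
$(1-\hat\pi, 1]$ by linear rescaling of $\tau$. Doing this twice — once
as fitted ($\hat Q^o$) and once with $\gamma$ and $\beta(\tau)$ zeroed
($\hat Q^c$) — gives the sample's original and batch-free distributions.
The matching-step locates the observed count in $\hat Q^o$ and returns
$\hat Q^c$ at the same percentile(s): ties (ubiquitous at zero) are
smoothed by the rounded average over all matched grid points, and an
observation absent from the grid falls back to the largest percentile
whose value stays below it (quantile functions are left-continuous).
Zeros can therefore become non-zero and vice versa; presence-absence
differences between batches are treated as sampling zeros and aligned
like everything else.

Because the key variables sit in $\mathbf{Z}_i$, their effects are part
of both $\hat Q^o$ and $\hat Q^c$ and survive the transport; only the
batch contribution is removed.

## Parameters that matter

* **Reference batch** (`ref_batch`): all other batches are aligned to it
  and its samples are returned bit-exactly unchanged. Default: first
  batch level.
* **Quantile grid** (`taus`): defaults to $\tau = 0.005, \dots, 0.995$
  ($k = 199$); `default_taus(19)` (5th–95th percentiles) is the fast
  preset. A finer grid shrinks the discretization error of the matching
  step at linear cost in fitting time.
* **Evaluation grid** (`eval_grid_size`, default 199): the shared
  percentile grid on which the two distributions are evaluated and
  matched. The zero/positive boundary snaps to the grid point below
  $1-\hat\pi$.
* **Mode**: `"default"` treats between-batch library-size differences as
  part of the batch effect and removes them. `"libsize"` keeps library
  size in the model — standardized libsize as a presence predictor, log
  libsize as a fixed offset in the quantile part (equivalently, the
  quantile model acts on log relative abundance) — so depth variability
  is preserved. Default mode is recommended unless depth itself is of
  interest.
* **Fitting strategies** (`fit_strategy()`): `standard` maximum
  likelihood / per-level check loss; `lasso` with the
  sparsity-proportional penalty $\lambda = 2p/n_+$ or $2p/\log n_+$
  (natural log; $p$ counts the intercept; $n_+$ = positive observations
  for the taxon); `composite` (shared slopes, per-level intercepts);
  `batch_only` (drops covariates from both parts — simple
  quantile–quantile matching between batches).
* **`jitter_seed`**: one master seed; each taxon draws its jitter from a
  sub-stream indexed by a hash of its identifier, so results are
  invariant to taxon order, sub-setting into prevalence bins, and
  parallel scheduling.

## Numerical choices

* The check-loss minimizer is a Frisch–Newton primal–dual interior-point
  solver (compiled, Armadillo) generalised to a per-observation quantile
  level. L1 penalties enter as pseudo-observations at $\tau = 1/2$
  ($\rho_{1/2}(-2\lambda b) = \lambda|b|$), and the composite fit is one
  pooled problem on a stacked design. Duality-gap tolerance is $10^{-10}$;
  on small instances the objective agrees with brute-force vertex
  enumeration to $10^{-6}$ or better.
* The intercept and the batch dummies are never shrunk by the L1
  penalty: the batch coefficients are the quantities being subtracted,
  and biasing them toward zero would leave batch signal behind.
* Fitted presence probabilities are truncated to
  $[1/(4n),\, 1 - 1/(4n)]$ so the zero mass never degenerates to the
  whole or empty grid.
* Quantile crossing is repaired by sorting (monotone rearrangement)
  before de-jittering; de-jittering maps $q \mapsto
  \max(\lceil q\rceil - 1, 0)$, which at exact integers equals $q - 1$
  (left continuity).
* Tie-smoothing averages are rounded half-up, so the worked examples in
  the documentation are deterministic. The smoothing rule applies to all
  tied values, not only zeros.
* Identity transport is short-circuited: when a sample's original and
  batch-free grid evaluations coincide elementwise (reference-batch
  samples; all batch coefficients zero), the observed count is returned
  unchanged rather than re-discretized through the grid. This is what
  makes reference-batch preservation exact.
* Degenerate taxa: all-zero columns and taxa with fewer than two
  positive counts are passed through unchanged (correction never changes
  table dimensions). A taxon present in *every* sample is corrected with
  the presence part pinned at one — the two-part model degenerates to
  its quantile part, which still carries the batch effect on abundances.
  Complete separation in a presence fit falls back to the penalized path
  with a warning; in the jittered quantile part, fewer positive rows
  than design columns switch the fit to the penalized path
  automatically.
* In libsize mode the jittered counts are logged and the log library
  size subtracted as an offset before fitting; predictions are shifted
  back, exponentiated and de-jittered with the same ceiling-minus-one
  rule, keeping the back-transform the exact inverse of the forward
  transform.

## Two-layer tuning

`tune_correction()` searches reference batches (outer) and, per
prevalence bin, fitting strategies (inner), scoring every corrected
(sub-)table by PERMANOVA $R^2$ explained by batch (Bray–Curtis by
default, Aitchison selectable) and keeping the argmin; ties break by
candidate order. Default prevalence cutoffs are $0.9, 0.8, \dots, 0.1$;
the default strategy pool is `standard`, `lasso`, `batch_only`
(`composite` is selectable but excluded by default: it is expensive and
its shared-slope assumption is strong). Only per-bin local optima are
sought, and one reference batch serves the whole table — mixing
references across taxa would distort the joint structure.

A known hazard, documented rather than patched: the $R^2$ criterion on
its own can favour a pathologically sparse reference batch, because
dragging every batch toward near-emptiness also makes them
indistinguishable. Inspect candidate references for quality (depth,
sparsity, metadata coverage) before trusting a tuned choice between
batches of very different quality.

## The simulation framework

`synth_starting_data()` emulates a sparse genus-level 16S profile:
a fixed geometric taxon-mean profile spanning four orders of magnitude
(so abundance ranks are stable across seeds), lognormal library sizes
(median $10^4$, sdlog 0.5), gamma-Poisson overdispersion (shape 0.5),
and injected sampling zeros to reach a 70% overall zero fraction —
values chosen once as representative of sparse vaginal-microbiome genus
tables. Defaults are 270 samples by 233 taxa.

On top of it, `simulate_dataset()` draws condition and batch from a
joint Bernoulli distribution with marginals 0.5/0.5 and odds ratio 1.25
(the Plackett cell solution), or links batch to depth via
$p_{\mathrm{batch}} = \mathrm{logit}^{-1}(\mathrm{libsize}^s)$;
resamples counts per sample from a Dirichlet distribution with parameter
(starting counts + 0.5) scaled by library size; injects condition fold
changes into 20 taxa at evenly spaced abundance ranks (directions
alternating) and batch fold changes into a random half/half split of all
taxa — divided taxa by the fold, multiplied taxa by the
library-size-preserving multiplier $FC' = (S - O - D/fc)/P$; and rounds
half-up to integers.

What this emulates: zero inflation, overdispersion, depth heterogeneity,
confounding between condition and batch, and multiplicative batch
effects on the whole profile. What it does not: taxon-taxon
correlations beyond the Dirichlet's, phylogenetic structure, real
measurement error models, or batch effects that change presence
mechanisms rather than abundances. Passing operating-characteristic
tests on these simulations shows the machinery behaves as designed under
the stated generative model, not that every real dataset will be
corrected equally well.

## Design decisions taken where the design was open

* One jitter draw per taxon (the standard usage of the jittering
  technique); averaging over replicate draws is available via repeated
  runs but is not a default.
* Categorical covariates are dummy-expanded against their first sorted
  level; any full-rank coding gives the same batch-effect subtraction.
* Standardized library size is the population z-score over the analysed
  samples.
* Missing metadata handling is strict complete-case on the used columns.
* The matched set is computed on the shared evaluation grid; its
  resolution is a parameter rather than a fixed tie to the fitted grid.
* The tuning distance defaults to Bray–Curtis on counts, the count-scale
  metric used throughout the evaluation battery.
* `penalty_lambda()` counts the intercept in $p$ and reads "log" as the
  natural log.

## Problem sizes used in the shipped checks

The packaged operating-characteristic checks run the full pipeline on
270-sample tables with 100 taxa — 50 replicates of the
batch-dominant scenario (condition FC 4, batch FC 64) and 100 replicates
of the null-batch scenario (condition FC 16, batch FC 1) — sizes chosen
so the whole battery completes on a single CPU in well under half an
hour while keeping Monte-Carlo error small relative to the margins being
tested. The same code scales linearly in samples x taxa x quantile
levels, and taxa parallelize perfectly (`threads` argument).

## Known limitations

* Batch must not completely confound a key variable; construction of the
  design refuses such data.
* Extreme-percentile estimates are unstable in small samples; the
  tie-smoothing average and monotone rearrangement mitigate but cannot
  remove this.
* Correction is not exactly idempotent — re-correcting a corrected table
  moves residual batch $R^2$ by a small amount (empirically below 0.01)
  because jitter and grid discretization differ between passes.
* The two-part model conditions on the supplied covariates only;
  unmeasured sample-level drivers correlated with batch are removed
  along with batch to the extent they are collinear with it.
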