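---
title: "Discovering shared neighbor genes between pathways with sparse regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering shared neighbor genes between pathways with sparse regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossnet)
```

## The problem

Pathways are usually analyzed as independent gene collections, but signaling
pathways coordinate: an upstream receptor cascade drives downstream programs
through genes that belong to neither annotated set. crossnet looks for these
*intermediary* genes from expression data alone. Given an expression matrix
over a gene universe $\Omega$ and two disjoint pathway gene sets $\chi_1$ and
$\chi_2$, it forms the predictor pool
$\Pi = (\Omega \setminus \chi_1) \cap (\Omega \setminus \chi_2)$ and asks
which pool genes' profiles help predict genes in *both* pathways. A motivating
design is the LPS-stimulated dendritic cell time course: the TLR signaling
pathway upstream, antigen processing / apoptosis / Jak-Stat programs
downstream, and MyD88 or TRIF knockouts that sever one signaling branch at a
time.

## The model

Each pathway gene $a_i \in \chi$ with profile $y_i$ (length $T$, the number
of samples) is regressed on the pool profile matrix $X$ ($T \times |\Pi|$)
with the elastic net, which mixes the sparsity-inducing $\ell_1$ penalty with
the grouping $\ell_2$ penalty. Along a penalty-strength path $s$ we solve

$$\hat\omega(s) = \arg\min_\omega \; \frac{1}{2T}\|y_i - \beta_0 - X\omega\|_2^2
  + s\left[\lambda\|\omega\|_1 + \frac{1-\lambda}{2}\|\omega\|_2^2\right],$$

with mixing $\lambda = 0.5$ by default. The written objective of the method
has no overall strength knob, but its companion fitting rule — "explain 75%
of the variance of each modeled gene" — only has meaning along a path of
strengths, so the standard path parameterization above is used: a geometric
grid of 100 values from $s_{\max} = \max_j |x_j'(y - \bar y)|/(T\lambda)$
(the smallest strength at which all coefficients are exactly zero) down to
$10^{-3} s_{\max}$.

Neighbor calling then follows two steps:

1. **Per-pathway neighbors.** For each $a_i \in \chi$, select the model at
   the *largest* penalty whose training variance explained
   ($1 - RSS/TSS$) reaches the target (default 0.75), i.e. the sparsest
   qualifying model, and call the predictors with non-zero coefficients
   ($|\omega_j| >$ `zero_tol`) neighbors of $a_i$. The pathway's neighbor
   set $\Gamma$ is the union over its genes.
2. **Shared neighbors.** $\Gamma_{1\cap 2} = \Gamma_1 \cap \Gamma_2$: pool
   genes connected to at least one gene in each pathway — the candidate
   intermediaries.

When a gene's path never reaches the variance target (possible at small $T$
or with weak signal), its best-fitting (smallest-penalty) model is used and
flagged `met_target = FALSE` in the edge table rather than silently dropping
the gene, which would shrink $\Gamma$ invisibly.

### Solver

The coordinate-descent solver is glmnet, the standard implementation for
this model. Two corrections are layered on top of it:

* glmnet internally rescales a gaussian response by its $1/T$ standard
  deviation, which silently rescales the *ridge* part of the penalty
  relative to the objective above whenever the response is on another scale.
  `fit_enet_path()` therefore transforms the problem exactly (response
  scaled to unit population sd, mixing and penalty grid adjusted jointly,
  coefficients scaled back).
* For $\lambda < 1$ every path point is then *polished* to the exact
  minimizer by active-set linear solves (the ridge term makes each
  subproblem strictly convex). Solutions satisfy the objective's
  stationarity conditions to machine precision, and identical predictors
  receive exactly equal coefficients — the grouping property that motivates
  the elastic net over the lasso. For $\lambda = 1$ (lasso; not strictly
  convex, so the active-set system can be singular) glmnet's solution is
  kept as is.

A single-predictor design is handled by the univariate closed form
(soft-thresholding with ridge shrinkage), since the backend requires two or
more columns.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `mixing` ($\lambda$) | 0.5 | $\ell_1$/$\ell_2$ balance; 1 = lasso (selects at most $T$ predictors), smaller values strengthen grouping of correlated predictors |
| `variance_target` | 0.75 | training $R^2$ the selected model must reach; selection takes the sparsest qualifying model |
| `n_penalties`, `penalty_ratio` | 100, $10^{-3}$ | resolution and depth of the geometric penalty grid |
| `zero_tol` | $10^{-10}$ | separates solver-exact zeros from numerically tiny coefficients |
| `mu` ($\mu$) | 0.1 | correlation-distance threshold of the baseline: neighbor iff $1 - r \le \mu$ |

The correlation baseline uses the *signed* Pearson correlation by default
("correlation distance" conventionally means $1 - r$); an absolute-value
variant is available via `corr_config(absolute = TRUE)` for designs where
anti-correlation should also count. Spearman is available for heavy-tailed
data.

## Preprocessing conventions

* **Dynamic-range filter** (FPKM-like data): keep a gene if, in at least one
  condition, max expression $> 5$ and max $> 2 \times$ min. The
  `max > fold * min` form is exact on positive data and well defined at
  min $= 0$ without a pseudocount.
* **Z-normalization** uses the sample standard deviation (denominator
  $T-1$); the choice is a convention, fixed so that results are
  bit-reproducible. Zero-variance genes must be removed first
  (`drop_zero_variance()` warns and removes).
* **Upper-quartile count normalization** divides each sample by the 75th
  percentile of its *non-zero* counts, computed by linear interpolation at
  position $0.75(n-1)$ (R's default quantile type 7, recorded for
  reproducibility). Zeros stay zero.
* **Minimum-read filter**: in the count workflow the normalization runs
  first, but gene membership is decided on the *raw* counts (at least 1 read
  in every sample) — thresholding normalized values at 1 would discard every
  gene below the upper quartile.
* Gene identifiers are matched exactly and case-sensitively; pathway genes
  absent from the matrix are dropped with a warning and count.

## Condition comparison and enrichment

For a knockout experiment, per-condition gene sets are partitioned into Venn
regions by `venn_regions()` / `compare_conditions()`, with canonical sorted
labels (`"T&W\\M"` = present in T and W, absent from M). The partition
property (regions disjoint, covering the union) is asserted on every call.
Comparing the *shared* sets localizes intermediaries lost with either
branch; comparing $\Gamma_1$ alone localizes genes whose association with
the manipulated pathway depends on the condition — the appropriate view when
the planted/expected intermediaries load on a single branch.

Candidate lists are tested for functional overrepresentation with the
one-sided hypergeometric test, always against the predictor pool $\Pi$ as
background — pool genes are the only ones that *could* have been called, so
a whole-genome background would inflate significance. Benjamini–Hochberg
FDR is applied across all tested terms; zero-overlap terms are reported,
not dropped, so the FDR denominator is reproducible.

## The synthetic-data generator

`simulate_crosstalk()` emulates the statistical structure the method
assumes, with known ground truth:

* two latent pathway activity signals $z_1, z_2$ (unit variance, length
  $T$), drawn either as a random smooth spline curve over ordered samples
  (a stimulation time course; knots $= \min(\max(T/4, 4), 8)$ so the curve
  has few effective degrees of freedom, like a response-decay profile) or
  as an AR(1) series with coefficient 0.8 (unordered population samples);
* pathway-$k$ genes $= \text{loading}\cdot z_k + N(0, \text{noise\_sd})$;
* planted shared intermediaries
  $= \text{loading}\cdot (z_1+z_2)/\sqrt{2} + \text{noise}$ — an additive,
  unit-variance load on both signals, the simplest structure that makes a
  gene predictive of members of both pathways;
* single-signal intermediaries load on one signal only; noise genes are
  independent $N(0,1)$;
* knockout conditions `KO1`/`KO2` replace the ablated signal *per gene*
  with an independent $N(0,1)$ series, so the coherence that signal induced
  collapses (as it should when a branch is genetically severed);
* all rows are z-scored; everything is reproducible from `seed` through an
  isolated RNG stream.

Default scale: $T = 30$ samples, $10 + 10$ pathway genes, $15$ shared and
$5 + 5$ single-signal intermediaries, $300$ noise genes, loading $1$.

### What passing tests do and do not show

The generator is deliberately idealized: Gaussian noise, a single global
latent per pathway, additive loadings, no sequencing-depth or count noise
(the method consumes normalized continuous expression by design). Recovery
results on it bound the method's behavior under its own assumptions; they do
not certify performance on real RNA-Seq, where pathway activity is
multi-factorial and expression noise is heteroskedastic.

Two identifiability properties of this planted design are worth stating
explicitly, because they shape what any neighbor-calling method can recover
from it:

1. **Attenuated shared loadings compete with perfect single-branch ones.**
   A shared intermediary correlates with a pathway gene at
   $\sqrt{(1+\rho)/2} \approx 0.71$ (for latent-signal sample correlation
   $\rho \approx 0$), while single-signal intermediaries correlate at
   $\approx 1$. The sparsest model reaching 75% $R^2$ is satisfied by the
   near-perfect predictors alone, and the correlation baseline's
   $\mu = 0.1$ cutoff demands $r \ge 0.9$. Shared intermediaries are
   therefore recovered only when the two latent signals happen to be
   substantially correlated in-sample (short smooth-curve series make this
   reasonably common, e.g. the seed-1 default draw, but it is not the
   typical case). Recovering attenuated shared loadings in general requires
   either a laxer distance threshold or planted loadings closer to unity.
2. **Knockout neighbor sets inflate by overfitting.** After a knockout the
   ablated pathway's genes are pure noise, yet with $T \ll |\Pi|$ the
   penalty path still reaches 75% training $R^2$ by overfitting, so the
   knockout condition's neighbor set is large and arbitrary rather than
   empty. Venn regions built on these sets are correspondingly noisy.
   A selection rule tied to out-of-sample fit (or the `met_target` flag
   exposed in the edge table) is the natural handle for real analyses.

The test suite asserts solver optimality (stationarity to $10^{-6}$, the
closed form on orthonormal designs, the at-most-$T$ lasso support bound,
monotone variance explained along the path), the exactness of the
enrichment statistics against combinatorial enumeration, the set-algebra
partition invariants, and the recovery behavior above at the default scale
($T = 30$, pool of 325, 50 random solver instances, 10 simulation
replicates — sizes chosen so the whole suite runs in a couple of minutes).

## Numerical choices and degenerate inputs

* The first path point is pinned at $s_{\max}$: coefficients exactly zero,
  variance explained exactly 0.
* Ties in variance-explained selection cannot arise (the grid is strictly
  decreasing and selection takes the first qualifying index).
* A response with zero variance, non-finite values, fewer than 3 samples,
  or orthogonal to every predictor is an error, not a silent fallback.
* Duplicate gene ids, NA cells and ragged rows fail loading with the
  offending gene/cell named.
* `evaluate_recovery()` conventions: empty prediction has precision 1 only
  when the truth is empty, else 0; recall is 1 for an empty truth set.

## Known limitations

* No inferential statistics on coefficients: the method calls an edge
  whenever a coefficient is non-zero at the selected penalty; coefficient
  p-values (e.g. by permutation) are out of scope.
* The weighted correlation network (WGCNA) comparison arm is not
  implemented: extracting neighbor sets from a soft-power adjacency
  requires choices (module membership, adjacency threshold) that the
  underlying procedure does not pin down.
* Direct $\chi_1 \leftrightarrow \chi_2$ edges are not modeled; only
  intermediaries outside both pathways are sought.
* Training-set variance explained is an in-sample criterion; with
  $T \ll |\Pi|$ it is reachable for pure-noise responses (see above).
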