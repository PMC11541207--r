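---
title: "Spatially aware Bayesian topic models for spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially aware Bayesian topic models for spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatopic)
```

## The model

Spatial transcriptomics assays measure a count matrix $x_{ng}$ (cells or
spots $n$, genes $g$) together with 2-D positions. `spatopic` decomposes
these counts into $K$ *topics*: per-cell topic proportions $z_{nk}$ (rows on
the simplex) and per-topic gene profiles $\beta_{kg}$ (rows on the simplex
over genes), under a Gamma-Poisson (negative binomial) observation model

$$x_{ng} \sim \mathrm{GammaPoisson}(\mu_{ng}, \alpha_g), \qquad
\mu_{ng} = l_n \sum_k z_{nk}\,\beta_{kg},$$

where $l_n = \sum_g x_{ng}$ is the observed library size (not a latent) and
$\alpha_g \ge 0$ is a gene-wise dispersion with $\mathrm{Var} = \mu + \alpha
\mu^2$; $\alpha \to 0$ recovers the Poisson. The square root of the
dispersion carries a Half-Cauchy(1) prior, which concentrates near zero —
most genes are not overdispersed beyond the mixture structure itself.

**Topic proportions.** The logits $\tilde z_n$ carry a logistic-normal prior
$\tilde z_n \sim N(0,\, UU^\top + \sigma I)$ with $u_k \sim N(0, I)$ and
$\sigma \sim$ Half-Cauchy(1); $z_n = \mathrm{softmax}(\tilde z_n)$. The
low-rank-plus-diagonal covariance lets topics co-occur or exclude one
another; its rank defaults to $K$.

**Gene modules with structured shrinkage.** Each topic's profile is
$\beta_k = \mathrm{softmax}_g(w_{k} + r)$, where $r_g$ is a background
residual shared by all topics, with prior
$r_g \sim N(\log(\bar x_g + 10^{-8}),\, 1)$ centered at the log of the
gene's observed mean log-normalized expression — it absorbs ubiquitously
expressed genes so they do not dominate every topic. The module scores
$w_{kg}$ carry a *regularized horseshoe* prior,

$$w_{kg} \sim N\!\left(0,\ \frac{c^2 \tilde\lambda^2_{kg}}
{c^2 + \tilde\lambda^2_{kg}}\right),\qquad
\tilde\lambda_{kg} = \delta_g\, \tau_k\, \lambda_{kg},$$

with Half-Cauchy(1) priors on the gene-wise scale $\delta_g$, topic-wise
scale $\tau_k$ and element-wise scale $\lambda_{kg}$, and an
InverseGamma(0.5, 0.5) slab $c$. Small scales pin $w_{kg}$ to zero (a gene
irrelevant to all topics, a topic loading few genes, or a single
gene-topic pair switched off); scales large relative to $c$ saturate the
prior variance at $c^2$, keeping weakly identified scores regularized. The
result is sparse, interpretable modules: few genes per topic, few topics
per gene.

**Multi-sample extension.** With batch labels $s$, the profile becomes
$\beta_{skg} = \mathrm{softmax}_g(w_{kg} + r_g + \tau^{\mathrm{batch}}_k
\delta^{\mathrm{batch}}_{sg})$: gene-wise batch effects
$\delta^{\mathrm{batch}}_{sg} \sim t_{10}(0, 0.01)$ (small scale, heavy
tails — most genes unaffected, some strongly affected) scaled per topic by
$\tau^{\mathrm{batch}}_k \sim \mathrm{Beta}(0.5, 0.5)$. Cells in batch $s$
use $\beta_s$ in their mean.

**Time-series extension.** With time labels, module scores drift:
$w_{\cdot kg} \sim \mathcal{GP}(0, \kappa_{kg})$ over the observed time
points with a Matern-3/2 kernel
$\kappa(t,t') = \tilde\sigma^2_{kg} (1 + \sqrt3\,|t-t'|/l)\,
e^{-\sqrt3\,|t-t'|/l}$, unit length scale $l = 1$, and output variance
$\tilde\sigma^2_{kg}$ given by the same regularized-horseshoe variance as
above, so sparsity and smoothness are controlled jointly. The residual
$r_{tg}$ is per time point, centered at per-time log-normalized means. A
jitter of $10^{-6}$ keeps the kernel matrix positive definite.

## Inference

Exact posteriors are intractable; the package uses amortized black-box
variational inference maximizing the evidence lower bound
$\mathcal{L} = E_q[\log p(X, \Theta, Z) - \log q(\Theta, Z)]$.

Global latents get mean-field guides: normal for real-valued blocks
($w, u, r$, batch effects), lognormal for positive blocks ($\delta, \tau,
\lambda, c, \sigma, \sqrt\alpha$), logit-normal for the unit-interval batch
weights — always matching the prior's support. Per-cell topic logits are
*amortized*: a simplified graph-convolution encoder takes the stacked hop
features $[X, SX, \dots, S^l X]$, where
$S = \tilde D^{-1/2}(A + I)\tilde D^{-1/2}$ is the symmetric normalized
adjacency of the spatial neighbor graph, and outputs the per-cell mean and
scale of $q(\tilde z_n)$. Because the hop features are precomputed once,
training minibatches plain rows — this is the "simplified" part, and it is
how spatial information enters the model (the generative side is
exchangeable over cells).

Gradients are reparameterized: latents are written as deterministic
transforms of standard normal draws, entropies of the location-scale guides
are taken in closed form, and all derivative chains (negative binomial
likelihood, softmax, horseshoe variance, low-rank MVN, GP quadratic forms,
layer-norm/GELU encoder) are implemented analytically and verified against
central finite differences in the test suite. Optimization is Adam with a
cosine learning-rate schedule. Likelihood, local-prior and local-entropy
terms are rescaled by $N/B$ so each minibatch objective is an unbiased
estimate of the full ELBO — the test suite checks that minibatch objectives
over a partition average exactly to the full-data estimate.

### Defaults that matter

| parameter | default | why |
|---|---|---|
| `epochs` | 400 | all study conditions converge well before this; the multi-sample scenario needs most of it (topics can stay collapsed at ~200 epochs) |
| `lr` / `lr_end` | 1e-2 → 1e-3 | cosine decay; larger rates destabilize the horseshoe scales |
| `minibatch` | 256 cells | balances gradient noise and step cost |
| `n_hops` | 1 | one round of neighbor smoothing; more hops give smoother, coarser topics |
| `hidden` | 128 | encoder width; recovery is insensitive between 64 and 256 |
| `mc_particles` | 1 (training), 32 (reported ELBO) | single-particle gradients are standard; reporting averages more |
| `target_sum` | 1e4 | per-cell count scaling before log1p, the field convention |
| guide init | locations 0 (residual at its prior mean, module scores N(0, 0.3)), scales 0.1 | residual init at the data baseline removes a long warm-up phase; the module-score noise breaks the permutation symmetry across topics — with identical zero scores the gradient field is symmetric and optimization can settle into collapsed optima where two topics share one pattern |
| `n_restarts` | 1 | optional independent restarts with the best final smoothed ELBO kept; collapsed optima sit thousands of nats below good ones, so ELBO selection discriminates reliably |

Graph construction: `hex` mode (six nearest neighbors, one ring) for
array-based platforms; `knn` mode defaults to one neighbor per thousand
cells. Edges are symmetrized by union; distances are Euclidean on the raw
coordinates. The encoder consumes log-normalized expression by default
(`input_kind = "counts"` is available); log scale keeps the linear layer
well conditioned.

Numerical guards: unconstrained positive draws are clamped at $|\zeta| \le
25$ before exponentiation (gradient masked where active); the dispersion is
floored at $10^{-10}$ inside the likelihood, with the exact small-$\alpha$
limit used for its gradient below $10^{-8}$; softmaxes subtract row maxima;
non-finite minibatch objectives abort training with the epoch reported.

## Outputs

`extract_results()` returns posterior summaries: $z = \mathrm{softmax}(Z_u)$
(deterministic; a Monte-Carlo posterior mean is optional since the
logistic-normal mean has no closed form), module scores $w$ as the guide
locations, and the residual baseline on the expression scale $\rho_g =
\exp(E_q[r_g])$. Modules are *rescored* to downweight lowly expressed
genes:

$$w^{\mathrm{new}}_{kg} = w_{kg} + \log\frac{\rho_g}{\rho_g + \epsilon},
\qquad \epsilon = \text{10th percentile of } \rho,$$

a non-positive adjustment that is most negative for low-baseline genes and
vanishes for well-expressed ones; equal-baseline genes keep their relative
order. (The published form of this rescoring applies the logarithm to the
residual itself; since the residual's posterior mean lives on the log scale
and can be negative, this package applies it on the expression scale, where
all logarithms are defined — an explicit `epsilon` argument exposes the
choice.) Genes are ranked per topic by rescored score, ties broken
lexicographically, and cells are hard-labeled by their argmax topic.

## Topic-quality metrics

*Module coherence* is the mean normalized pointwise mutual information over
the 190 unordered pairs of each topic's top-20 genes, averaged over topics.
Presence probabilities are cell frequencies from the raw counts, with a
gene counted as present only where its expression is positive and at or
above its own 75th percentile, so background expression does not inflate
co-occurrence. Conventions: a never-co-occurring pair scores $-1$; a pair
present in every cell scores $1$. *Module diversity* is the mean over topics
of the minimum $1 - \mathrm{RBO}$ against the other topics (self-comparison
excluded — including it would make the statistic identically zero), using
truncated rank-biased overlap at depth 20 with persistence $p = 0.9$,
normalized so identical lists score exactly 1. *Moran's I* of each topic's
proportions over the spatial graph quantifies spatial smoothness.

## The synthetic-data generators

`make_patterns()` places blocky rectangular regions on a lattice with
controlled pairwise overlaps (neighboring rectangles always share at least
one lattice column), emulating overlapping anatomical layers; ground-truth
proportions are normalized memberships, with background spots uniform.
`simulate_counts()` runs the generative model forward with planted sparse
modules: the default study condition is a 32×32 lattice (1024 spots), 200
genes, 5 patterns, 20 elevated genes per topic at score +2, library sizes
uniform on [1000, 2000], dispersion 0.05, and an i.i.d. N(0, 0.5²)
background residual — chosen once as a spot-level dataset at realistic
sequencing depth whose modules are strong but not trivially separable.
`inject_batch_effects()` splits cells into contiguous spatial slabs and
multiplies the Gamma-Poisson means of a random half of the genes by
$e^{N(0, 1.5^2)}$ per non-reference batch before resampling counts — a
strong, cross-platform-scale shift, comparable in score-space magnitude to
the planted modules, so that ignoring it demonstrably harms recovery while
modeling it does not. `simulate_time_series()` drifts the planted modules
with a Matern-3/2 GP across time points and offsets each time point's
lattice so the spatial graph never bridges times.

What these generators do *not* emulate: cell-type hierarchies, segmentation
errors, platform-specific spatial artifacts, zero inflation beyond the NB,
or genes outside the selected panel. Passing the recovery tests therefore
shows the estimator is correct under its own assumptions, not that those
assumptions hold on any particular tissue.

## Problem sizes and verification

The test suite and the acceptance script work at deliberate desk scale:
1024 spots × 200 genes for the five-pattern condition (K = 5, 400 epochs),
400 cells × 100 genes for parameter recovery and the batch comparison.
At these sizes a fit takes seconds to about a minute on one CPU core.
Verified behaviors include: bijective recovery of all five overlapping
patterns (matched Pearson r ≥ 0.5 per pattern; observed ≈ 0.83); matched
topic correlations ≥ 0.8 and ≥ 80% planted module genes in the top
rankings on the recovery condition (observed ≈ 0.997 and 100%); the
batch-aware fit losing < 0.1 correlation under injected batch effects while
the batch-unaware fit loses more; exactness of the negative binomial pmf
against its closed form; conservation laws ($\sum_k z_{nk} = 1$, $\sum_g
\beta_{kg} = 1$, $\sum_g \mu_{ng} = l_n$) at machine precision; analytic
gradients against finite differences; the ELBO lower-bounding a quadrature
evidence on a degenerate one-gene toy; and every metric against brute-force
reimplementations.

## Design choices where the design was open

- **Log-normalization** is per-cell total-count scaling to `target_sum`
  followed by natural `log1p`; the residual prior center $\bar x_g$ is the
  per-gene mean of that matrix over all cells. Both are configurable.
- **Gene filtering order**: cells first (detected genes, total counts),
  then genes by detection fraction among *retained* cells.
- **Hex grids** are handled as k = 6 nearest neighbors rather than lattice
  indexing, so irregular spot arrangements work identically.
- **Dispersion sharing** in the time scenario: one $\alpha_g$ across time
  points, matching the single dispersion block of the model.
- **No KL annealing**: the objective is exactly the ELBO; a flag could be
  added but default behavior never deviates from the model evidence bound.
- **HVG selection is delegated**: the package accepts a pre-selected gene
  panel and offers only a simple log-normalized-variance fallback
  (`select_genes_by_variance`).

## Known limitations

Variational posteriors are mean-field for the globals and amortized for the
locals: posterior uncertainty is typically understated, and the topic-logit
covariance is summarized, not fully propagated, into $z$. The multi-sample
scenario converges noticeably more slowly than the single-sample one — at
half the default epochs topics can remain collapsed. Input formats are
MatrixMarket + TSV and dense CSV/TSV; HDF5-based containers are not read.
The model is not designed for condition-versus-condition contrasts, and the
spatial graph influences inference only through the encoder — the
generative model itself is exchangeable over cells.
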