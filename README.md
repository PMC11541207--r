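# spatopic

Interpretable, spatially aware Bayesian topic modeling for spatial
transcriptomics.

Spot- and cell-resolution spatial assays (Visium, Slide-seq, Stereo-seq,
imaging panels) produce a cells × genes count matrix with 2-D coordinates.
Biological signals in such tissue overlap: a spot can sit in a cortical
layer *and* in a diseased niche at once, which hard clustering cannot
express. `spatopic` instead factorizes the counts into **topics** — per-cell
topic proportions `z` (each cell a mixture) and per-topic **gene modules**
`w` (sparse sets of genes that define each topic) — for analysts who want
both a soft spatial decomposition and a ranked, interpretable gene list per
structure.

## Model

Counts follow a Gamma-Poisson (negative binomial) factorization

```
x_ng ~ GammaPoisson(mu_ng, alpha_g),   mu_ng = l_n * sum_k z_nk * beta_kg
beta_kg = softmax_g(w_kg + r_g)
```

with library size `l_n = sum_g x_ng`, background residual
`r_g ~ N(log(xbar_g + 1e-8), 1)` and a **structured regularized horseshoe**
prior on the module scores:

```
w_kg ~ N(0, c^2 λ̃² / (c^2 + λ̃²)),   λ̃_kg = δ_g τ_k λ_kg
δ_g, τ_k, λ_kg ~ HalfCauchy(1),      c ~ InverseGamma(0.5, 0.5)
```

so each topic loads few genes and each gene loads few topics. Topic logits
carry a logistic-normal prior `N(0, UUᵀ + σI)`. Inference is amortized
stochastic variational inference: a simplified graph-convolution encoder
maps the stacked hop features `[X, SX, ..., S^l X]` of the spatial neighbor
graph (`S = D̃^{-1/2}(A+I)D̃^{-1/2}`) to the per-cell posterior over topic
logits, and all latents are trained jointly by maximizing a reparameterized
ELBO with Adam. Multi-sample data add a Student-t × Beta outer-product
batch term inside the softmax; time-series data let modules drift under a
Matern-3/2 Gaussian process. Details and defaults are in the vignette
(`vignettes/spatial-topic-models.Rmd`).

## Worked example

Simulate three overlapping spatial patterns with planted 20-gene modules on
a 20×20 lattice, fit K = 3 topics, and compare against the ground truth:

```r
library(spatopic)

sim   <- simulate_counts(grid = c(20L, 20L), n_patterns = 3L, n_genes = 100L, seed = 0)
ds    <- sim$dataset
graph <- build_graph(ds$coords, mode = "hex")   # six-neighbor spatial graph
fit   <- fit_stm(ds, graph, train_config(n_topics = 3, seed = 0))
res   <- extract_results(fit, ds, graph)

mt <- match_topics(res$z, sim$truth$z_true)     # Hungarian matching
round(mt$cors, 3)
res$rankings[[mt$perm[1]]][1:5]                 # top genes of matched topic 1
score_topics(res, ds, graph)
```

Output:

```
expression_dataset: 400 cells x 100 genes
spatial_graph: 400 cells, 1562 undirected edges (k = 6)
stm_fit: K = 3 topics, scenario 'single', 400 cells x 100 genes
  400 epochs, final ELBO -114144.5
[1] 0.997 0.998 0.998
[1] "gene004" "gene011" "gene018" "gene019" "gene015"
coherence 0.678  diversity 1.000  mean Morans I 0.894
```

The matched correlations say each planted pattern is recovered by exactly
one topic at r ≈ 0.997. The top-ranked genes of the first matched topic all
come from its planted module (genes 1–20). Module coherence 0.678 means the
top-20 genes of a topic strongly co-occur in the same cells; diversity 1.0
means the three modules share no top-ranked genes; mean Moran's I 0.9 means
the topic proportions vary smoothly in space.

`rescore_modules()` is applied inside `extract_results()`: module scores
are shifted by `log(rho / (rho + eps))`, with `rho` the expression-scale
residual baseline and `eps` its 10th percentile, pushing lowly expressed
genes down the rankings.

## Command line

```sh
Rscript inst/cli/spatopic simulate --preset five-patterns --seed 0 --out sim/
Rscript inst/cli/spatopic fit --counts sim/sim.mtx --coords sim/sim.coords.csv \
    --k 5 --graph-mode hex --epochs 400 --seed 0 --out run/
Rscript inst/cli/spatopic transform --model run/model.rds --counts sim/sim.mtx \
    --coords sim/sim.coords.csv --graph-mode hex --out topics/
Rscript inst/cli/spatopic score --counts sim/sim.mtx --coords sim/sim.coords.csv \
    --modules topics/rankings.tsv --topics topics/topics.csv \
    --graph-mode hex --out metrics.json
```

Every run writes a JSON manifest with the fully resolved configuration.
Accepted inputs: MatrixMarket triplets plus gene/cell TSVs, or dense
CSV/TSV with a gene-name header and cell-id first column; coordinates,
batch and time labels as two/three-column CSVs.

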