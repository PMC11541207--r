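# Synthetic data with known ground truth: overlapping spatial patterns on a
# lattice, counts drawn forward from the generative model with planted sparse
# gene modules, multiplicative batch effects, and time-drifting modules.

#' Overlapping blocky spatial patterns on a lattice
#'
#' Spots sit on a regular \code{rows x cols} grid. Each pattern is a
#' contiguous rectangular region; with \code{overlap = TRUE} the rectangles
#' are placed around the grid center so neighboring regions share spots
#' (every spot can belong to several patterns), with \code{overlap = FALSE}
#' they are disjoint vertical strips. The ground-truth topic proportions are
#' the membership indicators normalized to the simplex; spots belonging to no
#' pattern get uniform proportions.
#'
#' @param grid integer c(rows, cols).
#' @param n_patterns number of patterns, default 5.
#' @param overlap whether regions overlap, default TRUE.
#' @param seed integer seed (jitters rectangle centers and sizes).
#' @return list with \code{coords} (N x 2), \code{patterns} (N x K binary)
#'   and \code{z_true} (N x K simplex rows).
#' @export
make_patterns <- function(grid = c(32L, 32L), n_patterns = 5L, overlap = TRUE, seed = 0L) {
  rows <- grid[1]; cols <- grid[2]
  K <- n_patterns
  .assert(K >= 1, "need at least one pattern")
  if (overlap) {
    .assert(min(rows, cols) >= 4, "grid too small to pack %d overlapping patterns", K)
  } else {
    .assert(cols >= K, "grid too narrow for %d disjoint strips", K)
  }
  set.seed(seed)
  coords <- as.matrix(expand.grid(x = seq_len(cols), y = seq_len(rows)))
  N <- nrow(coords)
  patterns <- matrix(0L, N, K)
  if (overlap && K > 1) {
    cx <- (cols + 1) / 2; cy <- (rows + 1) / 2
    rad <- min(rows, cols) / 4
    jamp <- 0.03 * min(rows, cols)  # jitter small enough to keep neighbors overlapping
    # half-sizes: at least one lattice column/row of overlap between
    # neighboring rectangles on the placement circle
    need <- rad * sin(pi / K) + 0.5 + jamp
    hw <- max(0.28 * cols, need); hh <- max(0.28 * rows, need)
    for (k in seq_len(K)) {
      ang <- 2 * pi * (k - 1) / K
      jx <- stats::runif(1, -jamp, jamp); jy <- stats::runif(1, -jamp, jamp)
      x0 <- cx + rad * cos(ang) + jx
      y0 <- cy + rad * sin(ang) + jy
      inside <- abs(coords[, 1] - x0) <= hw & abs(coords[, 2] - y0) <= hh
      patterns[inside, k] <- 1L
    }
  } else if (overlap && K == 1) {
    inside <- coords[, 1] > cols / 4 & coords[, 1] <= 3 * cols / 4 &
      coords[, 2] > rows / 4 & coords[, 2] <= 3 * rows / 4
    patterns[inside, 1] <- 1L
  } else {
    cuts <- round(seq(0, cols, length.out = K + 1))
    for (k in seq_len(K)) {
      inside <- coords[, 1] > cuts[k] & coords[, 1] <= cuts[k + 1]
      patterns[inside, k] <- 1L
    }
  }
  .assert(all(colSums(patterns) >= 1), "a pattern ended up empty; enlarge the grid")
  if (overlap && K > 1) {
    .assert(any(rowSums(patterns) >= 2), "requested overlap but no spot belongs to 2 patterns")
  }
  mem <- rowSums(patterns)
  z <- patterns / pmax(mem, 1)
  z[mem == 0, ] <- 1 / K  # background mass split uniformly
  list(coords = coords, patterns = patterns, z_true = z)
}

# NB sampler in the model's mean/dispersion parameterization
.sample_counts <- function(mu, alpha) {
  n <- length(mu)
  aM <- if (length(alpha) == ncol(mu)) matrix(alpha, nrow(mu), ncol(mu), byrow = TRUE) else alpha
  x <- numeric(n)
  pois <- as.vector(aM == 0)
  if (any(pois)) x[pois] <- stats::rpois(sum(pois), as.vector(mu)[pois])
  if (any(!pois)) {
    x[!pois] <- stats::rnbinom(sum(!pois), size = 1 / as.vector(aM)[!pois],
                               mu = as.vector(mu)[!pois])
  }
  matrix(x, nrow(mu), ncol(mu))
}

#' Simulate counts from planted patterns and sparse gene modules
#'
#' Runs the generative model forward: each topic receives a disjoint block of
#' \code{n_module_genes} genes elevated by \code{module_strength} in score
#' space (all other module scores 0), the background residual is drawn
#' i.i.d. normal, gene embeddings are the gene-axis softmax of scores,
#' library sizes are uniform over \code{library_range}, and counts are
#' Gamma-Poisson with dispersion \code{alpha}.
#'
#' @param patterns output of \code{\link{make_patterns}}; built with the
#'   given \code{grid}/\code{n_patterns}/\code{overlap} when NULL.
#' @param grid,n_patterns,overlap forwarded to \code{\link{make_patterns}}.
#' @param n_genes total gene count G, default 200.
#' @param module_strength score elevation of planted module genes, default 2.
#' @param n_module_genes planted genes per topic, default 20.
#' @param library_range range of per-cell library sizes, default 1000-2000.
#' @param alpha gene-wise overdispersion (scalar or length G), default 0.05.
#' @param baseline_sd s.d. of the background residual draw, default 0.5.
#' @param seed integer seed.
#' @return list with \code{dataset} (an \code{expression_dataset}) and
#'   \code{truth} (patterns, z_true, w_true, beta_true, module_genes,
#'   alpha_true, lib_true, seed).
#' @export
simulate_counts <- function(patterns = NULL, grid = c(32L, 32L), n_patterns = 5L,
                            overlap = TRUE, n_genes = 200L, module_strength = 2,
                            n_module_genes = 20L, library_range = c(1000, 2000),
                            alpha = 0.05, baseline_sd = 0.5, seed = 0L) {
  .assert(module_strength >= 0, "module_strength must be >= 0")
  .assert(all(library_range > 0), "library_range must be positive")
  if (is.null(patterns)) patterns <- make_patterns(grid, n_patterns, overlap, seed)
  K <- ncol(patterns$patterns)
  G <- as.integer(n_genes)
  .assert(K * n_module_genes <= G, "%d topics x %d module genes exceed %d genes",
          K, n_module_genes, G)
  set.seed(seed + 1L)  # distinct stream from the pattern jitter
  w_true <- matrix(0, K, G)
  module_genes <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- ((k - 1) * n_module_genes + 1):(k * n_module_genes)
    module_genes[[k]] <- idx
    w_true[k, idx] <- module_strength
  }
  r_true <- stats::rnorm(G, 0, baseline_sd)
  beta_true <- gene_embedding(w_true, r_true)
  N <- nrow(patterns$z_true)
  lib <- stats::runif(N, library_range[1], library_range[2])
  mu <- mean_expression(lib, patterns$z_true, beta_true)
  alpha_true <- rep(alpha, length.out = G)
  x <- .sample_counts(mu, alpha_true)
  ds <- expression_dataset(x, patterns$coords,
                           gene_ids = sprintf("gene%03d", seq_len(G)),
                           cell_ids = sprintf("spot%04d", seq_len(N)))
  truth <- structure(list(patterns = patterns$patterns, z_true = patterns$z_true,
                          w_true = w_true, r_true = r_true, beta_true = beta_true,
                          module_genes = module_genes, alpha_true = alpha_true,
                          lib_true = lib, mu_true = mu, seed = seed),
                     class = "simulation_truth")
  list(dataset = ds, truth = truth)
}

#' Inject multiplicative gene-wise batch effects
#'
#' Cells are assigned to batches by contiguous spatial blocks (vertical
#' slabs of the x coordinate). Batch 1 is the reference; every other batch
#' gets gene-wise log fold changes drawn N(0, \code{log_fc_sd}^2), nonzero
#' only for a random \code{affected_frac} of genes. Counts are re-sampled
#' from the perturbed means \code{mu * exp(effect)} so the injected effect is
#' exactly multiplicative on the Gamma-Poisson mean.
#'
#' @param sim output of \code{\link{simulate_counts}} (needs
#'   \code{truth$mu_true}).
#' @param n_batches number of batches, >= 2.
#' @param log_fc_sd s.d. of the gene-wise log fold changes, default 1.5
#'   (a strong, cross-platform-scale shift).
#' @param affected_frac fraction of genes perturbed per batch, default 0.5.
#' @param seed integer seed.
#' @return list with \code{dataset} (batch labels attached) and updated
#'   \code{truth} (gains \code{batch_factors}, an S x G log-effect matrix).
#' @export
inject_batch_effects <- function(sim, n_batches = 2L, log_fc_sd = 1.5,
                                 affected_frac = 0.5, seed = 0L) {
  .assert(n_batches >= 2, "need at least 2 batches")
  ds <- sim$dataset; truth <- sim$truth
  N <- nrow(ds$counts); G <- ncol(ds$counts)
  set.seed(seed + 2L)
  cutp <- .quantile7(ds$coords[, 1], seq(0, 1, length.out = n_batches + 1))
  batch <- cut(ds$coords[, 1], breaks = unique(cutp), include.lowest = TRUE,
               labels = FALSE)
  batch <- as.integer(factor(batch))
  effects <- matrix(stats::rnorm(n_batches * G, 0, 1), n_batches, G) * log_fc_sd
  effects[1, ] <- 0
  mask <- as.numeric(stats::runif(G) < affected_frac)
  effects <- sweep(effects, 2, mask, "*")
  mu <- truth$mu_true * exp(effects[batch, , drop = FALSE])
  x <- .sample_counts(mu, truth$alpha_true)
  out <- expression_dataset(x, ds$coords, gene_ids = ds$gene_ids,
                            cell_ids = ds$cell_ids,
                            batch = paste0("batch", batch), time = ds$time)
  truth$batch_factors <- effects
  truth$batch_index <- batch
  list(dataset = out, truth = truth)
}

#' Simulate a time series with smoothly drifting gene modules
#'
#' For each (topic, gene) the module score follows the base planted value
#' plus a Matern-3/2 Gaussian-process draw over the time grid with amplitude
#' \code{drift_scale}, so modules at nearby time points are more similar than
#' at distant ones. Every time point gets an independently sampled dataset on
#' its own copy of the lattice (x coordinates offset per time point so the
#' spatial graph never bridges times).
#'
#' @param n_times number of time points T >= 2.
#' @param drift_scale GP amplitude (s.d. of the drift), default 1.
#' @param grid,n_patterns,n_genes,module_strength,n_module_genes,library_range,alpha,baseline_sd
#'   base simulation settings, as in \code{\link{simulate_counts}}.
#' @param length_scale Matern-3/2 length scale over time, default 1.
#' @param seed integer seed.
#' @return list with \code{dataset} (all time points concatenated, numeric
#'   time labels), \code{per_time} (list of per-time datasets) and
#'   \code{truth} (gains \code{time_w_true}, a T x K x G array).
#' @export
simulate_time_series <- function(n_times = 4L, drift_scale = 1, grid = c(16L, 16L),
                                 n_patterns = 3L, n_genes = 100L, module_strength = 2,
                                 n_module_genes = 15L, library_range = c(1000, 2000),
                                 alpha = 0.05, baseline_sd = 0.5, length_scale = 1,
                                 seed = 0L) {
  .assert(n_times >= 2, "need at least 2 time points")
  base <- simulate_counts(grid = grid, n_patterns = n_patterns, n_genes = n_genes,
                          module_strength = module_strength,
                          n_module_genes = n_module_genes,
                          library_range = library_range, alpha = alpha,
                          baseline_sd = baseline_sd, seed = seed)
  K <- nrow(base$truth$w_true); G <- n_genes
  times <- seq_len(n_times)
  set.seed(seed + 3L)
  Wt <- array(0, c(n_times, K, G))
  if (drift_scale > 0) {
    C <- matern32_covariance(times, drift_scale^2, length_scale)
    L <- t(chol(C))
    drift <- L %*% matrix(stats::rnorm(n_times * K * G), n_times, K * G)
  } else {
    drift <- matrix(0, n_times, K * G)
  }
  for (tt in times) Wt[tt, , ] <- base$truth$w_true + matrix(drift[tt, ], K, G)
  per_time <- vector("list", n_times)
  pat <- make_patterns(grid, n_patterns, TRUE, seed)
  N <- nrow(pat$z_true)
  for (tt in times) {
    beta_t <- gene_embedding(Wt[tt, , ], base$truth$r_true)
    lib <- stats::runif(N, library_range[1], library_range[2])
    mu <- mean_expression(lib, pat$z_true, beta_t)
    x <- .sample_counts(mu, base$truth$alpha_true)
    coords_t <- pat$coords
    coords_t[, 1] <- coords_t[, 1] + (tt - 1) * (grid[2] + 5)
    per_time[[tt]] <- expression_dataset(
      x, coords_t, gene_ids = base$dataset$gene_ids,
      cell_ids = sprintf("t%d_spot%04d", tt, seq_len(N)),
      time = rep(as.numeric(tt), N))
  }
  counts <- do.call(rbind, lapply(per_time, function(d) d$counts))
  combined <- expression_dataset(
    counts, do.call(rbind, lapply(per_time, function(d) d$coords)),
    gene_ids = base$dataset$gene_ids,
    cell_ids = unlist(lapply(per_time, function(d) d$cell_ids)),
    time = unlist(lapply(per_time, function(d) d$time)))
  truth <- base$truth
  truth$time_w_true <- Wt
  truth$z_true <- pat$z_true
  truth$patterns <- pat$patterns
  list(dataset = combined, per_time = per_time, truth = truth)
}
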