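# Shared fixtures, built in code. The heavier fits are computed once per test
# run and cached in an environment so several test files can share them.

.fixture_env <- new.env(parent = emptyenv())

# small random dataset for structural tests
tiny_dataset <- function(n = 12, g = 8, seed = 1, batch = FALSE, time = FALSE) {
  set.seed(seed)
  counts <- matrix(rpois(n * g, 5) + 1, n, g)  # +1 avoids zero-count cells
  expression_dataset(
    counts, cbind(runif(n, 0, 10), runif(n, 0, 10)),
    gene_ids = sprintf("g%02d", seq_len(g)),
    cell_ids = sprintf("c%02d", seq_len(n)),
    batch = if (batch) rep(c("a", "b"), length.out = n),
    time = if (time) rep(c(1, 2, 3), length.out = n))
}

# the parameter-recovery study: 3 planted patterns, 400 spots, 100 genes
recovery_fixture <- function() {
  if (!is.null(.fixture_env$recovery)) return(.fixture_env$recovery)
  sim <- simulate_counts(grid = c(20L, 20L), n_patterns = 3L, n_genes = 100L, seed = 0)
  graph <- build_graph(sim$dataset$coords, "hex")
  fit <- fit_stm(sim$dataset, graph, train_config(3, "single", seed = 0, epochs = 400))
  res <- extract_results(fit, sim$dataset, graph, top_n = 20)
  .fixture_env$recovery <- list(sim = sim, graph = graph, fit = fit, res = res)
  .fixture_env$recovery
}

expect_all_finite <- function(x) testthat::expect_true(all(is.finite(unlist(x))))
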