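# The inference engine: analytic gradients, the encoder map, ELBO behavior,
# and training-loop contracts.

make_small_problem <- function(scenario, seed = 1) {
  if (scenario == "time") {
    sim <- simulate_time_series(n_times = 3, grid = c(4L, 4L), n_patterns = 2L,
                                n_genes = 6L, n_module_genes = 2L, seed = seed)
  } else {
    sim <- simulate_counts(grid = c(5L, 5L), n_patterns = 2L, n_genes = 6L,
                           n_module_genes = 2L, seed = seed)
    if (scenario == "multi") {
      sim <- inject_batch_effects(sim, seed = seed)
    }
  }
  ds <- sim$dataset
  graph <- build_graph(ds$coords, "knn", k = 3)
  config <- train_config(3, scenario, seed = 7, epochs = 1, minibatch = 10)
  ctx <- spatopic:::.build_ctx(ds, graph, config, prior_hyperparameters())
  list(ds = ds, graph = graph, config = config, ctx = ctx)
}

test_that("analytic ELBO gradients match central differences in every scenario", {
  ns <- asNamespace("spatopic")
  for (scenario in c("single", "multi", "time")) {
    pr <- make_small_problem(scenario)
    set.seed(7)
    params <- ns$.init_params(pr$ctx)
    params <- ns$.tree_map1(params, function(x) x + rnorm(length(x), 0, 0.05))
    cells <- 1:10
    set.seed(11)
    eps <- ns$.draw_eps(pr$ctx, length(cells))
    res <- ns$.elbo_grad(params, pr$ctx, cells, eps)
    ga <- ns$.flatten_params(res$grads)
    pv <- ns$.flatten_params(params)
    f <- function(v) ns$.elbo_grad(ns$.unflatten_params(v, params), pr$ctx,
                                   cells, eps, want_grads = FALSE)$elbo
    set.seed(3)
    idx <- sort(sample(length(pv), 120))
    h <- 1e-5
    gn <- vapply(idx, function(j) {
      vp <- pv; vp[j] <- vp[j] + h
      vm <- pv; vm[j] <- vm[j] - h
      (f(vp) - f(vm)) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(ga[idx] - gn) / pmax(1, abs(gn))), 1e-4)
  }
})

test_that("encoder map is deterministic, positive-scaled and row-wise", {
  ns <- asNamespace("spatopic")
  set.seed(20)
  phi <- ns$.encoder_init(9, 6, 3)
  X <- matrix(rnorm(45), 5, 9)
  out1 <- encode(X, phi)
  out2 <- encode(X, phi)
  expect_identical(out1, out2)
  expect_true(all(out1$Zsigma > 0))
  # permuting rows permutes outputs identically
  p <- c(3, 1, 5, 2, 4)
  outp <- encode(X[p, ], phi)
  expect_equal(outp$Zu, out1$Zu[p, ], tolerance = 1e-12)
  # zero weights give zero means and the softplus floor scale
  phi0 <- lapply(phi, function(x) x * 0)
  phi0$g1 <- phi$g1 * 0 + 1
  out0 <- encode(X, phi0)
  expect_equal(out0$Zu, matrix(0, 5, 3), ignore_attr = TRUE)
  expect_equal(unique(as.vector(out0$Zsigma)), log(2) + 1e-4, tolerance = 1e-12)
  expect_error(encode(X[, 1:5], phi), "width")
})

test_that("ELBO estimates are seed-deterministic and tighten with particles", {
  pr <- make_small_problem("single")
  fit <- fit_stm(pr$ds, pr$graph, train_config(3, "single", seed = 1, epochs = 5))
  e1 <- elbo_estimate(pr$ds, pr$graph, fit, seed = 5, mc_particles = 4)
  e2 <- elbo_estimate(pr$ds, pr$graph, fit, seed = 5, mc_particles = 4)
  expect_identical(e1, e2)
  # Monte-Carlo spread shrinks from 1 to 64 particles
  v1 <- vapply(1:20, function(s) elbo_estimate(pr$ds, pr$graph, fit, seed = s,
                                               mc_particles = 1), numeric(1))
  v64 <- vapply(1:20, function(s) elbo_estimate(pr$ds, pr$graph, fit, seed = 100 + s,
                                                mc_particles = 64), numeric(1))
  expect_lt(sd(v64), sd(v1))
})

test_that("ELBO lower-bounds the quadrature evidence of a 1-cell, 1-gene toy", {
  # with a single gene the embedding softmax is degenerate (beta = 1), so the
  # marginal likelihood integrates only over the dispersion:
  # Z = int NB(x; l, s^2) HalfCauchy(s; 1) ds
  x <- 7L
  ds <- expression_dataset(matrix(x, 1, 1), matrix(0, 1, 2),
                           gene_ids = "g1", cell_ids = "c1")
  graph <- structure(list(adjacency = Matrix::Matrix(0, 1, 1, sparse = TRUE),
                          propagation = Matrix::Matrix(1, 1, 1, sparse = TRUE),
                          k = 0L), class = "spatial_graph")
  integrand <- function(s) {
    a <- pmin(pmax(s^2, 1e-8), 1e12)  # clamp for numerical stability only
    si <- 1 / a
    lp <- lgamma(x + si) - lgamma(si) - lgamma(x + 1) +
      si * log(si / (si + x)) + x * log(x / (si + x))
    exp(lp) * (2 / pi) / (1 + s^2)
  }
  logZ <- log(integrate(integrand, 0, Inf, rel.tol = 1e-7)$value)
  ns <- asNamespace("spatopic")
  cfg <- train_config(2, "single", seed = 2, epochs = 1, minibatch = 1)
  ctx <- ns$.build_ctx(ds, graph, cfg, prior_hyperparameters())
  set.seed(2)
  fitted <- list(params = ns$.init_params(ctx), config = cfg,
                 hyper = prior_hyperparameters())
  el <- elbo_estimate(ds, graph, fitted, seed = 9, mc_particles = 64)
  expect_lt(el, logZ)
})

test_that("minibatch objectives average exactly to the full-data ELBO", {
  pr <- make_small_problem("single")  # 25 cells
  fit <- fit_stm(pr$ds, pr$graph, train_config(3, "single", seed = 3, epochs = 3))
  full <- elbo_estimate(pr$ds, pr$graph, fit, seed = 21, mc_particles = 2)
  parts <- split(1:25, rep(1:5, each = 5))
  mb <- vapply(parts, function(cells) {
    elbo_estimate(pr$ds, pr$graph, fit, seed = 21, mc_particles = 2, cells = cells)
  }, numeric(1))
  expect_equal(mean(mb), full, tolerance = 1e-9)
})

test_that("fitting is reproducible and validates its inputs", {
  pr <- make_small_problem("single")
  cfg <- train_config(3, "single", seed = 4, epochs = 4)
  f1 <- fit_stm(pr$ds, pr$graph, cfg)
  f2 <- fit_stm(pr$ds, pr$graph, cfg)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_identical(f1$params, f2$params)
  expect_length(f1$elbo_trace, 4)
  expect_error(fit_stm(pr$ds, pr$graph, train_config(10, "single")), "topics")
  expect_error(train_config(1, "single"), "at least 2")
  expect_error(fit_stm(pr$ds, pr$graph, train_config(3, "multi")), "batch")
})

test_that("re-encoding the training data reproduces the stored posterior means", {
  fx <- recovery_fixture()
  cfg <- fx$fit$config
  nv <- lognormalize(fx$sim$dataset, cfg$target_sum)
  feats <- hop_features(fx$graph$propagation, nv$lognorm, cfg$n_hops)
  out <- encode(feats, fx$fit$params$enc)
  expect_identical(out$Zu, fx$fit$Zu)
  expect_identical(out$Zsigma, fx$fit$Zsigma)
})

test_that("the smoothed ELBO trace is non-decreasing over the final half of training", {
  fx <- recovery_fixture()
  tr <- fx$fit$elbo_trace
  sm <- stats::filter(tr, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  half <- sm[seq(floor(length(sm) / 2), length(sm))]
  expect_gte(utils::tail(half, 1), max(half) - 0.01 * abs(max(half)))
})

test_that("time-series fits recover topics and track drifting modules", {
  st <- simulate_time_series(n_times = 4, drift_scale = 0.5, grid = c(12L, 12L),
                             n_patterns = 3L, n_genes = 80L, n_module_genes = 12L,
                             seed = 0)
  ds <- st$dataset
  g <- build_graph(ds$coords, "hex")
  fit <- fit_stm(ds, g, train_config(3, "time", seed = 0, epochs = 300))
  res <- extract_results(fit, ds, g)
  zt <- st$truth$z_true[rep(seq_len(nrow(st$truth$z_true)), 4), ]
  mt <- match_topics(res$z, zt)
  expect_true(all(mt$cors >= 0.8))
  # inferred per-time module scores correlate with the planted drifting truth
  W <- fit$params$guide$w$loc
  for (tt in 1:4) {
    west <- matrix(W[tt, ], 3, 80)[mt$perm, ]
    expect_gt(cor(as.vector(west), as.vector(st$truth$time_w_true[tt, , ])), 0.7)
  }
  # extraction returns per-time arrays and rankings
  expect_equal(dim(res$w_new), c(4L, 3L, 80L))
  expect_length(res$rankings, 4L)
})

test_that("positive-support guides never produce non-positive latent draws", {
  ns <- asNamespace("spatopic")
  pr <- make_small_problem("multi")
  set.seed(5)
  params <- ns$.init_params(pr$ctx)
  params <- ns$.tree_map1(params, function(x) x + rnorm(length(x), 0, 0.5))
  sp <- ns$.block_specs(pr$ctx)
  for (rep in 1:20) {
    eps <- ns$.draw_eps(pr$ctx, 5)
    for (nm in names(sp)) {
      draw <- params$guide[[nm]]$loc + exp(params$guide[[nm]]$lsc) * eps[[nm]]
      if (sp[[nm]]$kind == "pos") expect_true(all(exp(pmin(draw, 25)) > 0))
      if (sp[[nm]]$kind == "logit") {
        th <- 1 / (1 + exp(-draw))
        expect_true(all(th > 0 & th < 1))
      }
    }
  }
})
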