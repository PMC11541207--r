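test_that("library sizes are per-cell totals and zero cells are refused", {
  expect_equal(library_sizes(matrix(c(2, 3, 5), 1, 3)), 10)
  expect_equal(library_sizes(diag(3)), rep(1, 3), ignore_attr = TRUE)
  expect_error(library_sizes(matrix(c(1, 0, 2, 0), 2, 2)), "zero total")
})

test_that("topic prior covariance is UU' + sigma I and positive definite", {
  expect_equal(topic_prior_covariance(matrix(0, 3, 3), 2), diag(2, 3))
  expect_equal(topic_prior_covariance(matrix(1, 2, 1), 1), matrix(c(2, 1, 1, 2), 2, 2))
  set.seed(1)
  for (rep in 1:5) {
    S <- topic_prior_covariance(matrix(rnorm(12), 4, 3), runif(1, 0.1, 2))
    expect_no_error(chol(S))
  }
  expect_error(topic_prior_covariance(matrix(0, 2, 2), 0), "positive")
})

test_that("softmax topics normalizes rows and is shift invariant", {
  expect_equal(softmax_topics(matrix(0, 1, 3)), matrix(1 / 3, 1, 3))
  z <- matrix(rnorm(12), 3, 4)
  expect_equal(softmax_topics(z + 5), softmax_topics(z), tolerance = 1e-12)
  expect_equal(softmax_topics(matrix(log(c(1, 3)), 1, 2)), matrix(c(0.25, 0.75), 1, 2))
})

test_that("regularized horseshoe variance interpolates horseshoe and slab", {
  expect_equal(regularized_horseshoe_scale(1, 1, 1, 1), 0.5)
  # c -> Inf recovers the pure horseshoe lambda-tilde^2
  expect_equal(regularized_horseshoe_scale(2, 0.5, 3, 1e8), (2 * 0.5 * 3)^2, tolerance = 1e-12)
  # lambda-tilde -> Inf caps at c^2
  expect_equal(regularized_horseshoe_scale(1e6, 1, 1, 2), 4, tolerance = 1e-9)
  # monotone in each scale, bounded by c^2
  set.seed(2)
  d <- runif(20, 0.1, 3); tau <- runif(20, 0.1, 3); l <- runif(20, 0.1, 3)
  v <- regularized_horseshoe_scale(d, tau, l, 1.5)
  expect_true(all(v <= 1.5^2))
  expect_true(all(regularized_horseshoe_scale(d * 2, tau, l, 1.5) >= v))
  expect_error(regularized_horseshoe_scale(-1, 1, 1, 1), "positive")
})

test_that("gene embedding softmaxes summed scores over genes", {
  w <- matrix(rnorm(6), 2, 3)
  r <- rnorm(3)
  b <- gene_embedding(w, r)
  expect_equal(rowSums(b), c(1, 1))
  expect_equal(gene_embedding(w, r, batch_w = matrix(0, 2, 3)), b)
  expect_equal(gene_embedding(matrix(0, 2, 4), rep(3, 4)), matrix(0.25, 2, 4))
  # zero topic-wise batch weight removes the batch term entirely
  bt <- rep(0, 2); bd <- rnorm(3)
  expect_equal(gene_embedding(w, r, batch_w = bt %o% bd), b)
  expect_error(gene_embedding(w, rnorm(4)), "genes")
})

test_that("mean expression conserves library size", {
  mu <- mean_expression(10, matrix(c(0.5, 0.5), 1, 2),
                        matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2, byrow = TRUE))
  expect_equal(as.vector(mu), c(4, 6))
  set.seed(3)
  z <- softmax_topics(matrix(rnorm(15), 5, 3))
  be <- gene_embedding(matrix(rnorm(12), 3, 4), rnorm(4))
  lib <- runif(5, 10, 100)
  expect_equal(rowSums(mean_expression(lib, z, be)), lib, tolerance = 1e-12)
  # single topic reduces to the scaled profile
  expect_equal(as.vector(mean_expression(7, matrix(1, 1, 1), be[1, , drop = FALSE])),
               7 * be[1, ])
})

test_that("gamma-Poisson pmf matches the closed-form negative binomial", {
  # closed-form oracle written out from the Gamma-Poisson mixture
  nb_oracle <- function(x, mu, a) {
    s <- 1 / a
    lgamma(x + s) - lgamma(s) - lgamma(x + 1) +
      s * log(s / (s + mu)) + x * log(mu / (s + mu))
  }
  expect_equal(gamma_poisson_logpmf(0, 1, 1), log(0.5), tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:20) {
    x <- rpois(1, 5); mu <- runif(1, 0.1, 20); a <- runif(1, 0.01, 3)
    expect_equal(gamma_poisson_logpmf(x, mu, a), nb_oracle(x, mu, a), tolerance = 1e-8)
  }
  # normalization over the support by brute-force summation
  p <- exp(gamma_poisson_logpmf(0:2000, 2, 0.5))
  expect_equal(sum(p), 1, tolerance = 1e-8)
  # Poisson limit as dispersion vanishes, on the probability scale (the exact
  # NB log pmf itself differs from Poisson by alpha*((x-mu)^2 - x)/2, which
  # exceeds 1e-6 in the far tail, so the log scale is not the right yardstick)
  for (mu in c(0.5, 2, 10)) {
    x <- 0:20
    expect_true(all(abs(exp(gamma_poisson_logpmf(x, mu, 1e-8)) - dpois(x, mu)) < 1e-6))
  }
  expect_equal(gamma_poisson_logpmf(3, 2, 0), dpois(3, 2, log = TRUE))
  expect_error(gamma_poisson_logpmf(2, -1, 0.5), "positive")
})

test_that("Matern-3/2 kernel has the closed form, decays, and is PSD", {
  K <- matern32_covariance(c(0, 1), 1, 1, jitter = 0)
  expect_equal(K[1, 1], 1)
  expect_equal(K[1, 2], (1 + sqrt(3)) * exp(-sqrt(3)), tolerance = 1e-12)
  # monotone decay in |dt|
  dts <- seq(0, 5, by = 0.25)
  kv <- vapply(dts, function(d) matern32_covariance(c(0, d), 1, 1, 0)[1, 2], numeric(1))
  expect_true(all(diff(kv) <= 0))
  expect_lt(kv[length(kv)], 1e-2)
  set.seed(5)
  for (rep in 1:5) {
    tg <- sort(runif(6, 0, 10))
    expect_no_error(chol(matern32_covariance(tg, runif(1, 0.5, 2))))
  }
})

test_that("log joint equals the sum of named density terms on a 1-cell, 1-gene toy", {
  ds <- expression_dataset(matrix(4L, 1, 1), matrix(0, 1, 2),
                           gene_ids = "g1", cell_ids = "c1")
  nv <- lognormalize(ds)
  state <- list(u = matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2), sigma = 0.7,
                z_logits = matrix(c(0.5, -0.5), 1, 2), r = 0.2,
                delta = 1.3, tau = c(0.8, 1.1), lam = matrix(c(0.5, 2), 2, 1),
                c = 1.4, w = matrix(c(0.3, -0.6), 2, 1), sqrt_alpha = 0.6)
  lj <- log_joint(ds, state, "single")
  # independent per-term oracle
  hc <- function(x) log(2 / pi) - log1p(x^2)
  Sig <- state$u %*% t(state$u) + 0.7 * diag(2)
  zrow <- as.vector(state$z_logits)
  mvn <- -0.5 * (t(zrow) %*% solve(Sig) %*% zrow) -
    0.5 * determinant(Sig)$modulus - log(2 * pi)
  v <- (1.4^2 * (state$delta * state$tau * as.vector(state$lam))^2) /
    (1.4^2 + (state$delta * state$tau * as.vector(state$lam))^2)
  alpha <- 0.6^2
  # with one gene the embedding is degenerate (beta = 1), mu = library size
  lik <- lgamma(4 + 1 / alpha) - lgamma(1 / alpha) - lgamma(5) +
    (1 / alpha) * log((1 / alpha) / (1 / alpha + 4)) + 4 * log(4 / (1 / alpha + 4))
  oracle <- sum(dnorm(state$u, log = TRUE)) + hc(0.7) + as.numeric(mvn) +
    dnorm(0.2, nv$baseline_log_mean, 1, log = TRUE) +
    hc(1.3) + sum(hc(state$tau)) + sum(hc(state$lam)) +
    (0.5 * log(0.5) - lgamma(0.5) - 1.5 * log(1.4) - 0.5 / 1.4) +
    sum(dnorm(as.vector(state$w), 0, sqrt(v), log = TRUE)) +
    hc(0.6) + lik
  expect_equal(lj, oracle, tolerance = 1e-10)
})

test_that("multi-scenario log joint adds exactly the batch prior terms at zero effect", {
  ds <- tiny_dataset(8, 5, seed = 11)
  dsb <- expression_dataset(ds$counts, ds$coords, ds$gene_ids, ds$cell_ids,
                            batch = rep(c("a", "b"), 4))
  set.seed(12)
  K <- 3; G <- 5
  state <- list(u = matrix(rnorm(9, 0, 0.3), 3, 3), sigma = 0.5,
                z_logits = matrix(rnorm(24, 0, 0.5), 8, 3),
                r = rnorm(G), delta = runif(G, 0.5, 2), tau = runif(K, 0.5, 2),
                lam = matrix(runif(K * G, 0.5, 2), K, G), c = 1.2,
                w = matrix(rnorm(K * G, 0, 0.4), K, G), sqrt_alpha = runif(G, 0.2, 1))
  base <- log_joint(ds, state, "single")
  state$batch_delta <- matrix(0, 2, G)
  state$batch_tau <- rep(0.4, K)
  multi <- log_joint(dsb, state, "multi")
  hy <- prior_hyperparameters()
  extra <- sum(dt(0 / hy$batch_t_sd, 10, log = TRUE) - log(hy$batch_t_sd)) * 2 * G +
    sum(dbeta(0.4, 0.5, 0.5, log = TRUE)) * K
  expect_equal(multi, base + extra, tolerance = 1e-9)
  # scenario/label mismatch errors
  expect_error(log_joint(ds, state, "multi"), "batch")
  expect_error(log_joint(ds, state, "time"), "time")
})
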