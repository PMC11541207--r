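# The generative probability model: priors, deterministic transforms, and the
# Gamma-Poisson likelihood, for the single-sample, multi-sample and
# time-series scenarios.
#
# Latents (single sample): per-cell topic logits z~ with logistic-normal prior
# MVN(0, UU' + sigma I); per-topic gene module scores w_kg under a structured
# regularized horseshoe (gene-wise delta_g, topic-wise tau_k, element-wise
# lambda_kg half-Cauchy scales, inverse-gamma slab c); background residual r_g
# centered at the observed log-normalized gene means; gene-wise dispersion
# alpha_g with a half-Cauchy prior on its square root.

#' Default prior hyperparameters
#'
#' @param half_cauchy_scale scale of the Half-Cauchy priors on delta, tau,
#'   lambda, sigma and sqrt(alpha).
#' @param slab_shape,slab_rate InverseGamma parameters of the slab size c.
#' @param residual_sd prior s.d. of the background residual r_g.
#' @param residual_epsilon positivity guard inside log(xbar + eps).
#' @param batch_t_df,batch_t_sd Student-t prior on gene-wise batch effects.
#' @param batch_beta_a,batch_beta_b Beta prior on topic-wise batch weights.
#' @param gp_length_scale Matern-3/2 length scale for time-series modules.
#' @param gp_jitter diagonal jitter of the GP covariance.
#' @return a named list of hyperparameters.
#' @export
prior_hyperparameters <- function(half_cauchy_scale = 1, slab_shape = 0.5, slab_rate = 0.5,
                                  residual_sd = 1, residual_epsilon = 1e-8,
                                  batch_t_df = 10, batch_t_sd = 0.01,
                                  batch_beta_a = 0.5, batch_beta_b = 0.5,
                                  gp_length_scale = 1, gp_jitter = 1e-6) {
  .assert(half_cauchy_scale > 0 && residual_sd > 0 && batch_t_sd > 0 && gp_length_scale > 0,
          "scale hyperparameters must be positive")
  list(half_cauchy_scale = half_cauchy_scale, slab_shape = slab_shape, slab_rate = slab_rate,
       residual_sd = residual_sd, residual_epsilon = residual_epsilon,
       batch_t_df = batch_t_df, batch_t_sd = batch_t_sd,
       batch_beta_a = batch_beta_a, batch_beta_b = batch_beta_b,
       gp_length_scale = gp_length_scale, gp_jitter = gp_jitter)
}

#' Per-cell library sizes
#'
#' The library size is the observed total count of each cell; it is not a
#' latent variable.
#' @param counts cells x genes count matrix.
#' @return numeric vector of positive totals.
#' @export
library_sizes <- function(counts) {
  l <- if (inherits(counts, "Matrix")) Matrix::rowSums(counts) else rowSums(counts)
  if (any(l == 0)) .stopf("cell %d has zero total count", which(l == 0)[1])
  l
}

#' Low-rank-plus-diagonal topic covariance
#'
#' The prior covariance of the topic logits, \eqn{UU^T + \sigma I}.
#' @param u K x R matrix of factor loadings.
#' @param sigma positive diagonal term.
#' @return K x K symmetric positive-definite matrix.
#' @export
topic_prior_covariance <- function(u, sigma) {
  .assert(sigma > 0, "sigma must be positive")
  u <- as.matrix(u)
  tcrossprod(u) + diag(sigma, nrow(u))
}

#' Softmax topic proportions from logits
#' @param z_logits N x K matrix of finite logits.
#' @return N x K matrix with simplex rows.
#' @export
softmax_topics <- function(z_logits) {
  .assert(all(is.finite(z_logits)), "logits must be finite")
  .softmax_rows(as.matrix(z_logits))
}

#' Regularized horseshoe prior variance
#'
#' \eqn{c^2 \tilde\lambda^2 / (c^2 + \tilde\lambda^2)} with
#' \eqn{\tilde\lambda = \delta \tau \lambda}: behaves like the horseshoe for
#' small local scales and saturates at the slab \eqn{c^2} for large ones.
#' Arguments broadcast like the elementwise product delta (gene) x tau
#' (topic) x lambda (element).
#'
#' @param delta,tau,lam positive local scales.
#' @param c positive slab size.
#' @return prior variances, bounded above by \code{c^2}.
#' @export
regularized_horseshoe_scale <- function(delta, tau, lam, c) {
  .assert(all(delta > 0) && all(tau > 0) && all(lam > 0) && all(c > 0),
          "horseshoe scales must be positive")
  lt2 <- (delta * tau * lam)^2
  c^2 * lt2 / (c^2 + lt2)
}

#' Topic-wise gene embedding
#'
#' Softmax over the gene axis of the summed scores: module scores w, the
#' background residual r, plus (multi-sample) the outer-product batch term or
#' (time series) per-time scores/residuals supplied by the caller.
#'
#' @param w K x G gene module scores.
#' @param r length-G background residual.
#' @param batch_w optional K x G batch-effect slice (one batch).
#' @return K x G matrix; each row a simplex over genes.
#' @export
gene_embedding <- function(w, r, batch_w = NULL) {
  w <- as.matrix(w)
  .assert(length(r) == ncol(w), "residual length %d != %d genes", length(r), ncol(w))
  sc <- sweep(w, 2, r, "+")
  if (!is.null(batch_w)) {
    .assert(all(dim(batch_w) == dim(w)), "batch term shape mismatch")
    sc <- sc + batch_w
  }
  .softmax_rows(sc)
}

#' Mean expression matrix
#'
#' \eqn{\mu_{ng} = l_n \sum_k z_{nk} \beta_{kg}}. Because both z rows and
#' beta rows are simplexes, row sums of mu equal the library sizes exactly.
#'
#' @param lib length-N positive library sizes.
#' @param z N x K topic proportions (simplex rows).
#' @param beta K x G gene embeddings (simplex rows).
#' @return N x G positive matrix.
#' @export
mean_expression <- function(lib, z, beta) {
  z <- as.matrix(z); beta <- as.matrix(beta)
  .assert(length(lib) == nrow(z), "library size length mismatch")
  .assert(ncol(z) == nrow(beta), "z topics (%d) != beta topics (%d)", ncol(z), nrow(beta))
  lib * (z %*% beta)
}

# Per-cell group index and group score matrices for each scenario.
# group g has its own beta: single -> 1 group, multi -> batches,
# time -> time points.
.scenario_groups <- function(ds, scenario) {
  if (scenario == "single") {
    list(idx = rep(1L, nrow(ds$counts)), n = 1L, labels = "all")
  } else if (scenario == "multi") {
    .assert(!is.null(ds$batch), "multi scenario requires batch labels")
    list(idx = as.integer(ds$batch), n = nlevels(ds$batch), labels = levels(ds$batch))
  } else {
    .assert(!is.null(ds$time), "time scenario requires time labels")
    tp <- sort(unique(ds$time))
    list(idx = match(ds$time, tp), n = length(tp), labels = tp, times = tp)
  }
}

#' Joint log density of data and latents
#'
#' Sum of all prior log densities and the Gamma-Poisson log likelihood for
#' one full assignment of the latent state, in any of the three scenarios.
#' Used for testing and as the target of the variational objective.
#'
#' @param ds an \code{expression_dataset} (with batch/time labels when the
#'   scenario needs them).
#' @param state named list of latents: \code{u} (K x R), \code{sigma},
#'   \code{z_logits} (N x K), \code{r} (G, or T x G for time), \code{delta}
#'   (G), \code{tau} (K), \code{lam} (K x G), \code{c}, \code{w} (K x G, or
#'   T x K x G array for time), \code{sqrt_alpha} (G); multi adds
#'   \code{batch_delta} (S x G) and \code{batch_tau} (K in (0,1)).
#' @param scenario \code{"single"}, \code{"multi"} or \code{"time"}.
#' @param hyper prior hyperparameters, see \code{\link{prior_hyperparameters}}.
#' @param baseline per-gene residual prior centers: length-G vector (single /
#'   multi) or T x G matrix (time); defaults to those of
#'   \code{\link{lognormalize}} on \code{ds}.
#' @return scalar log density.
#' @export
log_joint <- function(ds, state, scenario = c("single", "multi", "time"),
                      hyper = prior_hyperparameters(), baseline = NULL) {
  scenario <- match.arg(scenario)
  grp <- .scenario_groups(ds, scenario)
  if (is.null(baseline)) {
    nv <- lognormalize(ds)
    baseline <- if (scenario == "time") nv$baseline_log_mean_by_time else nv$baseline_log_mean
  }
  K <- if (scenario == "time") dim(state$w)[2] else nrow(state$w)
  G <- ncol(ds$counts)
  hc <- hyper$half_cauchy_scale
  lp <- 0
  # topic-logit prior: MVN(0, UU' + sigma I)
  lp <- lp + sum(stats::dnorm(state$u, 0, 1, log = TRUE))
  lp <- lp + .dhalfcauchy_log(state$sigma, hc)
  Sig <- topic_prior_covariance(state$u, state$sigma)
  ch <- chol(Sig)
  zt <- as.matrix(state$z_logits)
  quad <- sum(backsolve(ch, t(zt), transpose = TRUE)^2)
  lp <- lp - 0.5 * quad - nrow(zt) * (sum(log(diag(ch))) + 0.5 * K * log(2 * pi))
  # horseshoe hierarchy
  lp <- lp + sum(.dhalfcauchy_log(state$delta, hc)) +
    sum(.dhalfcauchy_log(state$tau, hc)) +
    sum(.dhalfcauchy_log(state$lam, hc)) +
    .dinvgamma_log(state$c, hyper$slab_shape, hyper$slab_rate)
  v <- regularized_horseshoe_scale(
    matrix(state$delta, K, G, byrow = TRUE),
    matrix(state$tau, K, G), state$lam, state$c)
  # residual + module scores
  if (scenario == "time") {
    Tn <- dim(state$w)[1]
    .assert(all(dim(baseline) == c(Tn, G)), "time baseline must be T x G")
    lp <- lp + sum(stats::dnorm(state$r, baseline, hyper$residual_sd, log = TRUE))
    C <- matern32_covariance(grp$times, 1, hyper$gp_length_scale, 0) +
      diag(hyper$gp_jitter, Tn)
    Cch <- chol(C)
    ldetC <- 2 * sum(log(diag(Cch)))
    Wm <- matrix(state$w, Tn, K * G)  # column (k,g), time along rows
    qf <- colSums(backsolve(Cch, Wm, transpose = TRUE)^2)
    vv <- as.vector(v)
    lp <- lp - 0.5 * sum(Tn * log(vv) + ldetC + qf / vv + Tn * log(2 * pi))
  } else {
    lp <- lp + sum(stats::dnorm(state$r, baseline, hyper$residual_sd, log = TRUE))
    lp <- lp + sum(stats::dnorm(state$w, 0, sqrt(v), log = TRUE))
  }
  # dispersion
  lp <- lp + sum(.dhalfcauchy_log(state$sqrt_alpha, hc))
  alpha <- state$sqrt_alpha^2
  # batch terms
  if (scenario == "multi") {
    lp <- lp + sum(.dstudent_log(state$batch_delta, hyper$batch_t_df, hyper$batch_t_sd)) +
      sum(.dbeta_log(state$batch_tau, hyper$batch_beta_a, hyper$batch_beta_b))
  }
  # likelihood
  z <- softmax_topics(state$z_logits)
  lib <- library_sizes(ds$counts)
  x <- as.matrix(ds$counts)
  for (s in seq_len(grp$n)) {
    cells <- grp$idx == s
    beta <- switch(scenario,
      single = gene_embedding(state$w, state$r),
      multi = gene_embedding(state$w, state$r,
                             batch_w = state$batch_tau %o% state$batch_delta[s, ]),
      time = gene_embedding(state$w[s, , , drop = TRUE], state$r[s, ]))
    mu <- mean_expression(lib[cells], z[cells, , drop = FALSE], beta)
    lp <- lp + sum(gamma_poisson_logpmf(x[cells, , drop = FALSE], mu,
                                        matrix(alpha, sum(cells), G, byrow = TRUE)))
  }
  lp
}
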