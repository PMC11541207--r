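# Amortized stochastic variational inference.
#
# Mean-field guides for the global latents (normal on the reals, lognormal on
# the positives, logit-normal on the unit-interval batch weights) and an
# amortized encoder for the per-cell topic logits. The ELBO
# E_q[log p - log q] is estimated with reparameterized Monte-Carlo draws;
# entropies of the location-scale guides are taken in closed form. All
# gradients are derived analytically and checked against finite differences
# in the test suite. Optimization is Adam over minibatches of cells, with the
# likelihood, local-prior and local-entropy terms rescaled by N/B so every
# minibatch objective is an unbiased estimate of the full ELBO.

.ZETA_CLAMP <- 25       # |unconstrained positive draw| bound, guards overflow
.ALPHA_FLOOR <- 1e-10   # dispersion floor inside the likelihood
.CST_NORM <- 0.5 * log(2 * pi * exp(1))

#' Training configuration
#'
#' @param n_topics number of topics K (>= 2).
#' @param scenario \code{"single"}, \code{"multi"} or \code{"time"}.
#' @param seed integer seed driving all randomness (init, minibatch order,
#'   Monte-Carlo draws).
#' @param epochs training epochs.
#' @param minibatch cells per minibatch.
#' @param lr,lr_end Adam learning rate, cosine-decayed from \code{lr} to
#'   \code{lr_end}.
#' @param mc_particles Monte-Carlo particles per gradient step.
#' @param n_hops graph-propagation hops l fed to the encoder.
#' @param hidden encoder hidden width.
#' @param input_kind encoder input, \code{"lognorm"} or \code{"counts"}.
#' @param cov_rank rank R of the topic-logit prior covariance; default K.
#' @param target_sum log-normalization scale target.
#' @param n_restarts independent training restarts; the fit with the best
#'   final smoothed ELBO is kept. Default 1.
#' @return a \code{train_config} list.
#' @export
train_config <- function(n_topics, scenario = c("single", "multi", "time"),
                         seed = 0L, epochs = 400L, minibatch = 256L,
                         lr = 1e-2, lr_end = 1e-3, mc_particles = 1L,
                         n_hops = 1L, hidden = 128L,
                         input_kind = c("lognorm", "counts"),
                         cov_rank = NULL, target_sum = 1e4, n_restarts = 1L) {
  scenario <- match.arg(scenario)
  input_kind <- match.arg(input_kind)
  .assert(n_topics >= 2, "need at least 2 topics")
  .assert(epochs >= 1 && minibatch >= 1 && mc_particles >= 1, "epochs, minibatch, mc_particles must be >= 1")
  list(n_topics = as.integer(n_topics), scenario = scenario, seed = as.integer(seed),
       epochs = as.integer(epochs), minibatch = as.integer(minibatch),
       lr = lr, lr_end = lr_end, mc_particles = as.integer(mc_particles),
       n_hops = as.integer(n_hops), hidden = as.integer(hidden),
       input_kind = input_kind,
       cov_rank = as.integer(if (is.null(cov_rank)) n_topics else cov_rank),
       target_sum = target_sum, n_restarts = as.integer(n_restarts))
}

# Assemble everything the objective needs: dense counts, library sizes,
# encoder features, residual baselines, scenario groups, GP covariance.
.build_ctx <- function(ds, graph, config, hyper) {
  x <- as.matrix(ds$counts)
  lib <- library_sizes(x)
  nv <- lognormalize(ds, config$target_sum)
  enc_in <- if (config$input_kind == "lognorm") nv$lognorm else x
  features <- hop_features(graph$propagation, enc_in, config$n_hops)
  grp <- .scenario_groups(ds, config$scenario)
  ctx <- list(x = x, lib = lib, features = features,
              N = nrow(x), G = ncol(x), K = config$n_topics, R = config$cov_rank,
              scenario = config$scenario, grp = grp, hyper = hyper,
              n_hidden = config$hidden)
  if (config$scenario == "time") {
    ctx$baseline <- nv$baseline_log_mean_by_time
    Tn <- grp$n
    C <- matern32_covariance(grp$times, 1, hyper$gp_length_scale, 0) + diag(hyper$gp_jitter, Tn)
    ch <- chol(C)
    ctx$Cinv <- chol2inv(ch)
    ctx$ldetC <- 2 * sum(log(diag(ch)))
    ctx$Tn <- Tn
  } else {
    ctx$baseline <- nv$baseline_log_mean
  }
  if (config$scenario == "multi") ctx$S <- grp$n
  ctx
}

# guide block specification: name, support kind, dimensions
.block_specs <- function(ctx) {
  K <- ctx$K; G <- ctx$G; R <- ctx$R
  sp <- list(
    u          = list(kind = "real", dim = c(K, R)),
    sigma      = list(kind = "pos",  dim = 1L),
    r          = list(kind = "real", dim = if (ctx$scenario == "time") c(ctx$Tn, G) else G),
    delta      = list(kind = "pos",  dim = G),
    tau        = list(kind = "pos",  dim = K),
    lam        = list(kind = "pos",  dim = c(K, G)),
    c          = list(kind = "pos",  dim = 1L),
    w          = list(kind = "real", dim = if (ctx$scenario == "time") c(ctx$Tn, K * G) else c(K, G)),
    sqrt_alpha = list(kind = "pos",  dim = G)
  )
  if (ctx$scenario == "multi") {
    sp$batch_delta <- list(kind = "real",  dim = c(ctx$S, G))
    sp$batch_tau   <- list(kind = "logit", dim = K)
  }
  sp
}

.zeros <- function(d) if (length(d) == 2) matrix(0, d[1], d[2]) else numeric(d)

.init_params <- function(ctx, init_scale = 0.1, init_w_sd = 0.3) {
  sp <- .block_specs(ctx)
  guide <- lapply(names(sp), function(nm) {
    loc <- .zeros(sp[[nm]]$dim)
    if (nm == "r") loc <- loc + ctx$baseline  # residual starts at its prior mean
    if (nm == "w") {
      # break the topic symmetry: identical zero module scores leave the
      # gradient field symmetric across topics and invite collapsed optima
      loc <- loc + stats::rnorm(length(loc), 0, init_w_sd)
    }
    list(loc = loc, lsc = .zeros(sp[[nm]]$dim) + log(init_scale))
  })
  names(guide) <- names(sp)
  list(guide = guide,
       enc = .encoder_init(ncol(ctx$features), ctx$n_hidden, ctx$K))
}

# one set of standard-normal innovations; z rows cover `n_cells`
.draw_eps <- function(ctx, n_cells) {
  sp <- .block_specs(ctx)
  eps <- lapply(sp, function(s) {
    d <- s$dim
    if (length(d) == 2) matrix(stats::rnorm(prod(d)), d[1], d[2]) else stats::rnorm(d)
  })
  eps$z <- matrix(stats::rnorm(n_cells * ctx$K), n_cells, ctx$K)
  eps
}

# ---------------------------------------------------------------------------
# The objective: ELBO value and analytic gradients for one minibatch.
# ---------------------------------------------------------------------------
.elbo_grad <- function(params, ctx, cells, eps, want_grads = TRUE) {
  guide <- params$guide
  sp <- .block_specs(ctx)
  hy <- ctx$hyper
  K <- ctx$K; G <- ctx$G
  B <- length(cells)
  sN <- ctx$N / B

  # ---- transform draws to latent space -------------------------------------
  th <- list(); tr <- list()
  for (nm in names(sp)) {
    loc <- guide[[nm]]$loc; sc <- exp(guide[[nm]]$lsc)
    zeta <- loc + sc * eps[[nm]]
    kind <- sp[[nm]]$kind
    if (kind == "pos") {
      mask <- abs(zeta) < .ZETA_CLAMP
      zeta <- pmin(pmax(zeta, -.ZETA_CLAMP), .ZETA_CLAMP)
      th[[nm]] <- exp(zeta)
      tr[[nm]] <- list(sc = sc, mask = mask)
    } else if (kind == "logit") {
      th[[nm]] <- .sigmoid(zeta)
      tr[[nm]] <- list(sc = sc, mask = TRUE)
    } else {
      th[[nm]] <- zeta
      tr[[nm]] <- list(sc = sc, mask = TRUE)
    }
  }
  gth <- lapply(th, function(x) x * 0)  # grad of log p wrt each latent

  lp <- 0
  # ---- encoder forward ------------------------------------------------------
  fw <- .encoder_forward(params$enc, ctx$features[cells, , drop = FALSE])
  zt <- fw$Zu + fw$Zs * eps$z
  z <- .softmax_rows(zt)

  # ---- likelihood -----------------------------------------------------------
  alpha <- pmax(th$sqrt_alpha^2, .ALPHA_FLOOR)
  g_alpha <- numeric(G)
  gz <- matrix(0, B, K)
  gidx <- ctx$grp$idx[cells]
  for (s in unique(gidx)) {
    rows <- which(gidx == s)
    scores <- switch(ctx$scenario,
      single = sweep(th$w, 2, th$r, "+"),
      multi  = sweep(th$w, 2, th$r, "+") + th$batch_tau %o% th$batch_delta[s, ],
      time   = sweep(matrix(th$w[s, ], K, G), 2, th$r[s, ], "+"))
    beta <- .softmax_rows(scores)
    zs <- z[rows, , drop = FALSE]
    libs <- ctx$lib[cells[rows]]
    xs <- ctx$x[cells[rows], , drop = FALSE]
    mu <- libs * (zs %*% beta)
    aM <- matrix(alpha, length(rows), G, byrow = TRUE)
    size <- 1 / aM
    lp <- lp + sN * sum(lgamma(xs + size) - lgamma(size) - lgamma(xs + 1) +
                          size * log(size / (size + mu)) + xs * log(mu / (size + mu)))
    if (want_grads) {
      Gm <- xs / mu - (1 + aM * xs) / (1 + aM * mu)
      small <- alpha <= 1e-8
      Ga <- .gp_grad_alpha(xs, mu, aM)
      if (any(small)) {
        lim <- ((xs - mu)^2 - xs) / 2
        Ga[, small] <- lim[, small, drop = FALSE]
      }
      g_alpha <- g_alpha + sN * colSums(Ga)
      gz[rows, ] <- gz[rows, ] + sN * ((Gm * libs) %*% t(beta))
      h <- crossprod(zs * libs, Gm)
      q <- beta * (h - rowSums(beta * h))
      if (ctx$scenario == "time") {
        gth$w[s, ] <- gth$w[s, ] + sN * as.vector(q)
        gth$r[s, ] <- gth$r[s, ] + sN * colSums(q)
      } else {
        gth$w <- gth$w + sN * q
        gth$r <- gth$r + sN * colSums(q)
        if (ctx$scenario == "multi") {
          gth$batch_delta[s, ] <- gth$batch_delta[s, ] + sN * colSums(q * th$batch_tau)
          gth$batch_tau <- gth$batch_tau + sN * as.vector(q %*% th$batch_delta[s, ])
        }
      }
    }
  }

  # ---- topic-logit prior MVN(0, UU' + sigma I), scaled by N/B --------------
  Sig <- tcrossprod(th$u) + diag(th$sigma, K)
  ch <- chol(Sig)
  Sinv <- chol2inv(ch)
  ztS <- zt %*% Sinv
  lp <- lp + sN * (-0.5 * sum(ztS * zt) - B * (sum(log(diag(ch))) + 0.5 * K * log(2 * pi)))
  gzt <- -sN * ztS
  if (want_grads) {
    GSig <- sN * 0.5 * (Sinv %*% crossprod(zt) %*% Sinv - B * Sinv)
    gth$u <- gth$u + 2 * (GSig %*% th$u)
    gth$sigma <- gth$sigma + sum(diag(GSig))
  }

  # ---- global priors --------------------------------------------------------
  hc <- hy$half_cauchy_scale
  lp <- lp + sum(stats::dnorm(th$u, 0, 1, log = TRUE))
  gth$u <- gth$u - th$u
  lp <- lp + .dhalfcauchy_log(th$sigma, hc)
  gth$sigma <- gth$sigma + .dhalfcauchy_grad(th$sigma, hc)
  for (nm in c("delta", "tau", "lam", "sqrt_alpha")) {
    lp <- lp + sum(.dhalfcauchy_log(th[[nm]], hc))
    gth[[nm]] <- gth[[nm]] + .dhalfcauchy_grad(th[[nm]], hc)
  }
  gth$sqrt_alpha <- gth$sqrt_alpha + g_alpha * 2 * th$sqrt_alpha
  lp <- lp + .dinvgamma_log(th$c, hy$slab_shape, hy$slab_rate)
  gth$c <- gth$c + .dinvgamma_grad(th$c, hy$slab_shape, hy$slab_rate)
  lp <- lp + sum(stats::dnorm(th$r, ctx$baseline, hy$residual_sd, log = TRUE))
  gth$r <- gth$r - (th$r - ctx$baseline) / hy$residual_sd^2

  # module-score prior under the regularized horseshoe
  D <- matrix(th$delta, K, G, byrow = TRUE)
  Tm <- matrix(th$tau, K, G)
  a <- (D * Tm * th$lam)^2
  c2 <- th$c^2
  v <- c2 * a / (c2 + a)
  if (ctx$scenario == "time") {
    Tn <- ctx$Tn
    vv <- as.vector(v)  # column (k,g) order matches w's columns
    CinvW <- ctx$Cinv %*% th$w
    qf <- colSums(th$w * CinvW)
    lp <- lp - 0.5 * sum(Tn * log(vv) + ctx$ldetC + qf / vv) - 0.5 * Tn * K * G * log(2 * pi)
    Gv <- matrix(-Tn / (2 * vv) + qf / (2 * vv^2), K, G)
    if (want_grads) gth$w <- gth$w - sweep(CinvW, 2, vv, "/")
  } else {
    lp <- lp + sum(-0.5 * log(2 * pi * v) - th$w^2 / (2 * v))
    Gv <- -0.5 / v + th$w^2 / (2 * v^2)
    if (want_grads) gth$w <- gth$w - th$w / v
  }
  if (want_grads) {
    Gva <- Gv * (c2 / (c2 + a))^2
    gth$delta <- gth$delta + colSums(Gva * 2 * a / D)
    gth$tau <- gth$tau + rowSums(Gva * 2 * a / Tm)
    gth$lam <- gth$lam + Gva * 2 * a / th$lam
    gth$c <- gth$c + sum(Gv * a^2 / (c2 + a)^2) * 2 * th$c
  }

  if (ctx$scenario == "multi") {
    lp <- lp + sum(.dstudent_log(th$batch_delta, hy$batch_t_df, hy$batch_t_sd)) +
      sum(.dbeta_log(th$batch_tau, hy$batch_beta_a, hy$batch_beta_b))
    gth$batch_delta <- gth$batch_delta + .dstudent_grad(th$batch_delta, hy$batch_t_df, hy$batch_t_sd)
    gth$batch_tau <- gth$batch_tau + .dbeta_grad(th$batch_tau, hy$batch_beta_a, hy$batch_beta_b)
  }

  # ---- entropies ------------------------------------------------------------
  ent <- sN * (sum(log(fw$Zs)) + B * K * .CST_NORM)
  for (nm in names(sp)) {
    len <- length(guide[[nm]]$loc)
    ent <- ent + sum(guide[[nm]]$lsc) + len * .CST_NORM
    if (sp[[nm]]$kind == "pos") ent <- ent + sum(guide[[nm]]$loc)
    if (sp[[nm]]$kind == "logit") ent <- ent + sum(log(th[[nm]] * (1 - th[[nm]])))
  }
  elbo <- lp + ent
  if (!want_grads) return(list(elbo = elbo))

  # ---- back to unconstrained guide parameters ------------------------------
  ggd <- vector("list", length(sp)); names(ggd) <- names(sp)
  for (nm in names(sp)) {
    kind <- sp[[nm]]$kind
    g <- gth[[nm]]
    if (kind == "pos") {
      gzeta <- g * th[[nm]] * tr[[nm]]$mask
      ggd[[nm]] <- list(loc = gzeta + 1, lsc = gzeta * tr[[nm]]$sc * eps[[nm]] + 1)
    } else if (kind == "logit") {
      gzeta <- g * th[[nm]] * (1 - th[[nm]]) + (1 - 2 * th[[nm]])
      ggd[[nm]] <- list(loc = gzeta, lsc = gzeta * tr[[nm]]$sc * eps[[nm]] + 1)
    } else {
      ggd[[nm]] <- list(loc = g, lsc = g * tr[[nm]]$sc * eps[[nm]] + 1)
    }
  }

  # encoder backprop: z-logit gradient = likelihood + prior + entropy paths
  gzt_total <- gzt + z * (gz - rowSums(gz * z))
  dZu <- gzt_total
  dZs <- gzt_total * eps$z + sN / fw$Zs
  genc <- .encoder_backward(params$enc, fw, dZu, dZs)

  list(elbo = elbo, grads = list(guide = ggd, enc = genc))
}

# ---------------------------------------------------------------------------
# Adam over the nested parameter list.
# ---------------------------------------------------------------------------
.tree_zero <- function(p) if (is.list(p)) lapply(p, .tree_zero) else p * 0

.adam_step <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (nm in names(p)) {
      r <- .adam_step(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p + lr * mh / (sqrt(vh) + eps), m = m, v = v)  # ascent on the ELBO
}

.flatten_params <- function(p) {
  if (!is.list(p)) return(as.numeric(p))
  unlist(lapply(p, .flatten_params), use.names = FALSE)
}

.unflatten_params <- function(vec, skel) {
  i <- 0
  rec <- function(s) {
    if (!is.list(s)) {
      n <- length(s)
      out <- vec[(i + 1):(i + n)]
      i <<- i + n
      dim(out) <- dim(s)
      return(out)
    }
    lapply(s, rec)
  }
  rec(skel)
}

#' Fit the model by amortized stochastic variational inference
#'
#' Trains the mean-field guides and the graph-convolution encoder jointly by
#' maximizing a reparameterized Monte-Carlo estimate of the ELBO with Adam
#' over minibatches of cells. All randomness (initialization, minibatch
#' order, Monte-Carlo draws) derives from \code{config$seed}.
#'
#' @param ds a filtered \code{expression_dataset} (no zero-count cells;
#'   batch labels required for the multi scenario, time labels for time).
#' @param graph the \code{spatial_graph} over the same cells.
#' @param config a \code{\link{train_config}}.
#' @param hyper prior hyperparameters, see \code{\link{prior_hyperparameters}}.
#' @param verbose print progress every 50 epochs.
#' @return an object of class \code{stm_fit}: guide + encoder parameters,
#'   the config and hyperparameters, the per-epoch ELBO trace, the stored
#'   encoder outputs \code{Zu}/\code{Zsigma} on the training data, and a data
#'   fingerprint.
#' @export
fit_stm <- function(ds, graph, config, hyper = prior_hyperparameters(), verbose = FALSE) {
  .assert(config$n_topics <= ncol(ds$counts), "more topics (%d) than genes (%d)",
          config$n_topics, ncol(ds$counts))
  .assert(nrow(graph$adjacency) == nrow(ds$counts), "graph/dataset cell-count mismatch")
  ctx <- .build_ctx(ds, graph, config, hyper)
  n_restarts <- if (is.null(config$n_restarts)) 1L else config$n_restarts
  best <- NULL
  restart_elbos <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    fit_r <- .fit_once(ds, ctx, config, hyper, seed = config$seed + 997L * (r - 1L),
                       verbose = verbose)
    restart_elbos[r] <- mean(utils::tail(fit_r$elbo_trace, 10))
    if (is.null(best) || restart_elbos[r] > mean(utils::tail(best$elbo_trace, 10))) {
      best <- fit_r
    }
  }
  best$restart_elbos <- restart_elbos
  best
}

.fit_once <- function(ds, ctx, config, hyper, seed, verbose = FALSE) {
  set.seed(seed)
  params <- .init_params(ctx)
  m <- .tree_zero(params); v <- .tree_zero(params)
  n_steps_per_epoch <- max(1L, ceiling(ctx$N / config$minibatch))
  total_steps <- config$epochs * n_steps_per_epoch
  trace <- numeric(config$epochs)
  t <- 0
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(ctx$N)
    acc <- 0
    for (b in seq_len(n_steps_per_epoch)) {
      cells <- perm[seq((b - 1) * config$minibatch + 1, min(b * config$minibatch, ctx$N))]
      t <- t + 1
      lr <- config$lr_end + 0.5 * (config$lr - config$lr_end) * (1 + cos(pi * (t - 1) / total_steps))
      val <- 0; gsum <- NULL
      for (pidx in seq_len(config$mc_particles)) {
        eps <- .draw_eps(ctx, length(cells))
        res <- .elbo_grad(params, ctx, cells, eps)
        val <- val + res$elbo / config$mc_particles
        gsum <- if (is.null(gsum)) res$grads else
          .tree_map2(gsum, res$grads, `+`)
      }
      if (config$mc_particles > 1) gsum <- .tree_map1(gsum, function(x) x / config$mc_particles)
      if (!is.finite(val)) {
        .stopf("ELBO diverged (non-finite) at epoch %d, step %d", ep, b)
      }
      upd <- .adam_step(params, gsum, m, v, lr, t)
      params <- upd$p; m <- upd$m; v <- upd$v
      acc <- acc + val
    }
    trace[ep] <- acc / n_steps_per_epoch
    if (verbose && (ep %% 50 == 0 || ep == 1)) {
      message(sprintf("epoch %4d  elbo %.1f", ep, trace[ep]))
    }
  }
  enc_out <- encode(ctx$features, params$enc)
  structure(list(params = params, config = config, hyper = hyper,
                 elbo_trace = trace,
                 Zu = enc_out$Zu, Zsigma = enc_out$Zsigma,
                 fingerprint = list(n = ctx$N, g = ctx$G, gene_ids = ds$gene_ids)),
            class = "stm_fit")
}

.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- .tree_map2(a[[nm]], b[[nm]], f)
    return(a)
  }
  f(a, b)
}

.tree_map1 <- function(a, f) {
  if (is.list(a)) return(lapply(a, .tree_map1, f = f))
  f(a)
}

#' @export
print.stm_fit <- function(x, ...) {
  cat(sprintf("stm_fit: K = %d topics, scenario '%s', %d cells x %d genes\n",
              x$config$n_topics, x$config$scenario, x$fingerprint$n, x$fingerprint$g))
  cat(sprintf("  %d epochs, final ELBO %.1f\n", x$config$epochs, utils::tail(x$elbo_trace, 1)))
  invisible(x)
}

#' Monte-Carlo ELBO estimate for a fitted (or freshly initialized) model
#'
#' Recomputes the evidence lower bound on the given data with a stated number
#' of reparameterized particles. Identical \code{seed} and particle count
#' yield an identical value. When \code{cells} is a subset, the minibatch
#' objective (local terms scaled by N/B) is returned; per-cell draws are
#' generated for the full dataset first and sliced, so a partition of the
#' cells averages exactly to the full-data estimate under the same seed.
#'
#' @param ds,graph data and spatial graph, as in \code{\link{fit_stm}}.
#' @param fitted an \code{stm_fit} (or a bare params list with matching
#'   config/hyper supplied via attributes of the fit).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param mc_particles number of particles, default 32.
#' @param cells optional integer subset of cells.
#' @return scalar ELBO estimate.
#' @export
elbo_estimate <- function(ds, graph, fitted, seed = 0L, mc_particles = 32L, cells = NULL) {
  ctx <- .build_ctx(ds, graph, fitted$config, fitted$hyper)
  if (is.null(cells)) cells <- seq_len(ctx$N)
  set.seed(seed)
  vals <- numeric(mc_particles)
  for (p in seq_len(mc_particles)) {
    eps <- .draw_eps(ctx, ctx$N)
    eps$z <- eps$z[cells, , drop = FALSE]
    vals[p] <- .elbo_grad(fitted$params, ctx, cells, eps, want_grads = FALSE)$elbo
  }
  val <- mean(vals)
  if (!is.finite(val)) .stopf("non-finite ELBO estimate")
  val
}
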