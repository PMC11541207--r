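# Amortization network: hop features -> linear -> layer norm -> GELU ->
# two linear heads (topic-logit mean and positive scale). Forward and
# backward passes are written out explicitly; gradients are verified against
# finite differences in the test suite.

.gelu <- function(x) x * stats::pnorm(x)
.gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

.LN_EPS <- 1e-5
.SCALE_FLOOR <- 1e-4

#' Initialize encoder weights
#' @param n_in input width ((l+1) * genes).
#' @param n_hidden hidden width.
#' @param n_topics number of topics K.
#' @return named list of weight matrices/vectors (phi).
#' @keywords internal
#' @noRd
.encoder_init <- function(n_in, n_hidden, n_topics) {
  gl <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(2 / (a + b))), a, b)
  list(W1 = gl(n_in, n_hidden), b1 = numeric(n_hidden),
       g1 = rep(1, n_hidden), be1 = numeric(n_hidden),
       Wu = gl(n_hidden, n_topics), bu = numeric(n_topics),
       Ws = gl(n_hidden, n_topics), bs = numeric(n_topics))
}

# forward pass keeping intermediates for backprop
.encoder_forward <- function(phi, X) {
  H1 <- X %*% phi$W1
  H1 <- sweep(H1, 2, phi$b1, "+")
  mu <- rowMeans(H1)
  xc <- H1 - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + .LN_EPS)
  Hhat <- xc * inv
  H2 <- sweep(Hhat * rep(phi$g1, each = nrow(H1)), 2, phi$be1, "+")
  Hg <- .gelu(H2)
  Zu <- sweep(Hg %*% phi$Wu, 2, phi$bu, "+")
  pre <- sweep(Hg %*% phi$Ws, 2, phi$bs, "+")
  Zs <- .softplus(pre) + .SCALE_FLOOR
  list(X = X, H1 = H1, inv = inv, Hhat = Hhat, H2 = H2, Hg = Hg,
       Zu = Zu, pre = pre, Zs = Zs)
}

# backward pass: gradients of a scalar objective wrt phi given dZu, dZs
.encoder_backward <- function(phi, fw, dZu, dZs) {
  dpre <- dZs * .sigmoid(fw$pre)
  dHg <- tcrossprod(dZu, phi$Wu) + tcrossprod(dpre, phi$Ws)
  dH2 <- dHg * .gelu_grad(fw$H2)
  dHhat <- dH2 * rep(phi$g1, each = nrow(dH2))
  # layer-norm backward (per row, means over the hidden dimension)
  m1 <- rowMeans(dHhat)
  m2 <- rowMeans(dHhat * fw$Hhat)
  dH1 <- fw$inv * (dHhat - m1 - fw$Hhat * m2)
  # same element order as the phi list, so flattened trees align
  list(W1 = crossprod(fw$X, dH1), b1 = colSums(dH1),
       g1 = colSums(dH2 * fw$Hhat), be1 = colSums(dH2),
       Wu = crossprod(fw$Hg, dZu), bu = colSums(dZu),
       Ws = crossprod(fw$Hg, dpre), bs = colSums(dpre))
}

#' Encode cells into topic-logit posteriors
#'
#' Deterministic map from precomputed hop features to the per-cell mean and
#' scale of the variational distribution over topic logits.
#'
#' @param features cells x ((l+1) * genes) matrix from
#'   \code{\link{hop_features}}.
#' @param phi encoder weights (from a fitted model, \code{fitted$params$enc}).
#' @return list with \code{Zu} (N x K means) and \code{Zsigma} (N x K
#'   positive scales).
#' @export
encode <- function(features, phi) {
  features <- as.matrix(features)
  .assert(ncol(features) == nrow(phi$W1),
          "feature width %d != encoder input width %d", ncol(features), nrow(phi$W1))
  fw <- .encoder_forward(phi, features)
  list(Zu = fw$Zu, Zsigma = fw$Zs)
}
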