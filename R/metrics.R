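# Topic-quality metrics: NPMI module coherence, rank-biased-overlap module
# diversity, and Moran's I spatial autocorrelation.

#' Binary gene-presence matrix
#'
#' A gene counts as present in a cell when its expression is positive and at
#' or above the gene's empirical \code{quantile} across cells (default: the
#' top quarter of cells for that gene). Restricting presence to the
#' highest-expression cells keeps ubiquitous background genes from dominating
#' co-occurrence probabilities.
#'
#' @param expr cells x genes non-negative matrix (typically raw counts).
#' @param quantile per-gene cutoff quantile, default 0.75.
#' @return list with binary \code{presence} (cells x genes) and
#'   \code{threshold_quantile}.
#' @export
presence_matrix <- function(expr, quantile = 0.75) {
  expr <- as.matrix(expr)
  .assert(all(expr >= 0), "expression must be non-negative")
  qs <- apply(expr, 2, .quantile7, p = quantile)
  pres <- (expr >= rep(qs, each = nrow(expr))) & (expr > 0)
  storage.mode(pres) <- "integer"
  dimnames(pres) <- dimnames(expr)
  list(presence = pres, threshold_quantile = quantile)
}

# NPMI of one gene pair from presence probabilities (base-2 logs).
# Conventions: never co-occurring -> -1; deterministically co-occurring -> 1.
.npmi_pair <- function(pi, pj, pij) {
  if (pij == 0) return(-1)
  if (pij >= 1) return(1)
  log2(pij / (pi * pj)) / (-log2(pij))
}

#' Module coherence (mean NPMI over top-gene pairs)
#'
#' For each topic's top \code{m} genes (default 20), averages the normalized
#' pointwise mutual information over all \code{choose(m, 2)} unordered pairs
#' (190 pairs at m = 20), then averages over topics. Probabilities are cell
#' frequencies taken from the presence matrix. Result lies in [-1, 1]; higher
#' means the module's genes co-occur in the same cells.
#'
#' @param modules list of K character vectors (ordered gene lists).
#' @param occ a presence matrix from \code{\link{presence_matrix}} whose
#'   columns are named by gene.
#' @param m number of top genes per module used, default 20.
#' @return scalar coherence.
#' @export
module_coherence <- function(modules, occ, m = 20L) {
  P <- occ$presence
  vals <- vapply(modules, function(gl) {
    gl <- gl[seq_len(min(m, length(gl)))]
    missing <- setdiff(gl, colnames(P))
    if (length(missing)) .stopf("module genes absent from presence matrix: %s",
                                paste(missing, collapse = ", "))
    sub <- P[, gl, drop = FALSE]
    p <- colMeans(sub)
    if (any(p == 0)) .stopf("gene(s) never present: %s", paste(gl[p == 0], collapse = ", "))
    joint <- crossprod(sub) / nrow(sub)
    n <- length(gl)
    s <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) s <- s + .npmi_pair(p[i], p[j], joint[i, j])
    }
    s / (n * (n - 1) / 2)
  }, numeric(1))
  mean(vals)
}

#' Rank-biased overlap of two gene rankings
#'
#' Truncated RBO at the given depth,
#' \eqn{(1-p) \sum_{d=1}^{D} p^{d-1} |top_d(a) \cap top_d(b)| / d},
#' normalized by its identical-list maximum \eqn{1 - p^D} so that identical
#' rankings score exactly 1 and disjoint ones 0. Top-weighted: agreement near
#' the head of the lists counts more.
#'
#' @param list_a,list_b ordered character vectors, length >= \code{depth}.
#' @param p persistence parameter in (0, 1), default 0.9.
#' @param depth truncation depth, default 20.
#' @return scalar in [0, 1].
#' @export
rbo <- function(list_a, list_b, p = 0.9, depth = 20L) {
  .assert(length(list_a) >= depth && length(list_b) >= depth,
          "both lists must have length >= depth (%d)", depth)
  s <- 0
  for (d in seq_len(depth)) {
    ov <- length(intersect(list_a[seq_len(d)], list_b[seq_len(d)]))
    s <- s + p^(d - 1) * ov / d
  }
  (1 - p) * s / (1 - p^depth)
}

#' Module diversity (mean per-topic minimum 1 - RBO)
#'
#' For each module, finds its most similar other module by RBO and scores
#' \code{1 - RBO}; the diversity is the mean of these per-topic minima.
#' 0 when all modules are identical, 1 when every module is disjoint from
#' all others.
#'
#' @param modules list of K >= 2 ordered gene vectors.
#' @param p,depth RBO parameters, see \code{\link{rbo}}.
#' @return scalar in [0, 1].
#' @export
module_diversity <- function(modules, p = 0.9, depth = 20L) {
  K <- length(modules)
  .assert(K >= 2, "need at least 2 modules")
  mins <- vapply(seq_len(K), function(i) {
    min(vapply(setdiff(seq_len(K), i), function(j) {
      1 - rbo(modules[[i]], modules[[j]], p, depth)
    }, numeric(1)))
  }, numeric(1))
  mean(mins)
}

#' Moran's I spatial autocorrelation
#'
#' \eqn{I = (N/\sum_{ij} w_{ij}) \sum_{ij} w_{ij} (v_i - \bar v)(v_j - \bar v)
#' / \sum_i (v_i - \bar v)^2} with the graph adjacency as weights. Positive
#' values mean spatially smooth fields, values near \eqn{-1/(N-1)} no spatial
#' structure.
#'
#' @param values per-cell numeric vector (non-constant).
#' @param graph a \code{spatial_graph} (its adjacency supplies the weights).
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, graph) {
  A <- graph$adjacency
  n <- length(values)
  .assert(n == nrow(A), "values length != graph size")
  d <- values - mean(values)
  ss <- sum(d^2)
  .assert(ss > 0, "zero variance: values are constant")
  num <- sum(d * as.numeric(A %*% d))
  (n / sum(A)) * num / ss
}

#' Score a topic result
#'
#' Convenience wrapper computing module coherence, module diversity and the
#' per-topic Moran's I of the topic proportions.
#'
#' @param res a \code{topic_result}.
#' @param ds the matching \code{expression_dataset} (raw counts feed the
#'   presence matrix).
#' @param graph the matching \code{spatial_graph}.
#' @param m top genes per module, default 20 (capped at G).
#' @return list with \code{coherence}, \code{diversity},
#'   \code{morans_i} (length-K vector).
#' @export
score_topics <- function(res, ds, graph, m = 20L) {
  m <- min(m, length(res$gene_ids))
  occ <- presence_matrix(as.matrix(ds$counts))
  rk <- if (res$scenario == "time") res$rankings[[1]] else res$rankings
  rk <- lapply(rk, function(g) g[seq_len(m)])
  list(coherence = module_coherence(rk, occ, m),
       diversity = module_diversity(rk, depth = m),
       morans_i = vapply(seq_len(ncol(res$z)), function(k) morans_i(res$z[, k], graph), numeric(1)))
}
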