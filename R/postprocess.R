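# Turning a fitted model into topic proportions, gene modules, rescored
# rankings and hard labels.

#' Extract topic proportions and gene modules from a fitted model
#'
#' Topic proportions default to the deterministic summary
#' \code{softmax(Z_u)} of the encoder means; module scores are the guide
#' locations of q(w); the residual baseline is returned on the expression
#' scale, \code{rho_g = exp(E_q[r_g])}. An optional Monte-Carlo mode averages
#' \code{softmax(Z_u + Z_sigma * eps)} over a stated number of particles.
#'
#' @param fitted an \code{stm_fit}.
#' @param ds the \code{expression_dataset} the model was trained on.
#' @param graph the matching \code{spatial_graph}.
#' @param mc_particles 0 (deterministic, default) or a particle count for the
#'   Monte-Carlo posterior mean of the topic proportions.
#' @param seed seed for the Monte-Carlo mode.
#' @param rescore_quantile epsilon quantile of the rescoring, default 0.10.
#' @param top_n length of the per-topic gene rankings, default
#'   \code{min(20, G)}.
#' @return a \code{topic_result}: \code{z} (N x K), \code{w} (K x G),
#'   \code{r_baseline} (G, expression scale), \code{w_new} (K x G rescored),
#'   \code{rankings} (list of ordered gene vectors), \code{labels}
#'   (per-cell topic index). For the time scenario \code{w}/\code{w_new} are
#'   T x K x G arrays and rankings are per-time lists.
#' @export
extract_results <- function(fitted, ds, graph, mc_particles = 0L, seed = 0L,
                            rescore_quantile = 0.10, top_n = NULL) {
  fp <- fitted$fingerprint
  .assert(nrow(ds$counts) == fp$n && ncol(ds$counts) == fp$g &&
            identical(ds$gene_ids, fp$gene_ids),
          "dataset does not match the fitted model's fingerprint")
  K <- fitted$config$n_topics
  G <- fp$g
  if (is.null(top_n)) top_n <- min(20L, G)
  if (mc_particles > 0) {
    set.seed(seed)
    z <- 0
    for (p in seq_len(mc_particles)) {
      z <- z + .softmax_rows(fitted$Zu + fitted$Zsigma *
                               matrix(stats::rnorm(fp$n * K), fp$n, K))
    }
    z <- z / mc_particles
  } else {
    z <- .softmax_rows(fitted$Zu)
  }
  guide <- fitted$params$guide
  scenario <- fitted$config$scenario
  if (scenario == "time") {
    Tn <- nrow(guide$r$loc)
    w <- array(0, c(Tn, K, G))
    w_new <- w
    rankings <- vector("list", Tn)
    rho_t <- exp(guide$r$loc)  # T x G
    for (tt in seq_len(Tn)) {
      wt <- matrix(guide$w$loc[tt, ], K, G)
      w[tt, , ] <- wt
      wn <- rescore_modules(wt, rho_t[tt, ], rescore_quantile)
      w_new[tt, , ] <- wn
      rankings[[tt]] <- rank_genes(wn, ds$gene_ids, top_n)
    }
    rho <- colMeans(rho_t)
  } else {
    w <- guide$w$loc
    rho <- exp(as.vector(guide$r$loc))
    w_new <- rescore_modules(w, rho, rescore_quantile)
    rankings <- rank_genes(w_new, ds$gene_ids, top_n)
  }
  structure(list(z = z, w = w, r_baseline = rho, w_new = w_new,
                 rankings = rankings, labels = binarize_topics(z),
                 gene_ids = ds$gene_ids, cell_ids = ds$cell_ids,
                 scenario = scenario),
            class = "topic_result")
}

#' @export
print.topic_result <- function(x, ...) {
  cat(sprintf("topic_result: %d cells x %d topics (%s scenario)\n",
              nrow(x$z), ncol(x$z), x$scenario))
  invisible(x)
}

#' Rescore gene modules to downweight lowly expressed genes
#'
#' Adds \code{log(rho_g / (rho_g + eps))} to every module score of gene g,
#' where \code{rho} is the expression-scale residual baseline and \code{eps}
#' is its empirical \code{epsilon_quantile} quantile (linear interpolation).
#' The adjustment is always <= 0 and more negative for smaller baselines, so
#' genes with little background expression fall down the rankings while
#' well-expressed genes are left nearly untouched.
#'
#' @param w K x G module scores.
#' @param rho length-G positive baselines.
#' @param epsilon_quantile quantile defining eps, default 0.10.
#' @param epsilon explicit eps overriding the quantile rule.
#' @return K x G rescored scores.
#' @export
rescore_modules <- function(w, rho, epsilon_quantile = 0.10, epsilon = NULL) {
  w <- as.matrix(w)
  .assert(all(rho > 0), "rho must be positive")
  .assert(length(rho) == ncol(w), "rho length %d != %d genes", length(rho), ncol(w))
  eps <- if (is.null(epsilon)) .quantile7(rho, epsilon_quantile) else epsilon
  sweep(w, 2, log(rho / (rho + eps)), "+")
}

#' Rank genes within each topic
#'
#' @param w_new K x G (rescored) module scores.
#' @param gene_ids gene identifiers, one per column.
#' @param top_n ranking length, <= G.
#' @return list of K character vectors, sorted by score descending, ties
#'   broken by lexicographic gene id.
#' @export
rank_genes <- function(w_new, gene_ids, top_n = ncol(w_new)) {
  w_new <- as.matrix(w_new)
  .assert(top_n <= ncol(w_new), "top_n (%d) exceeds gene count (%d)", top_n, ncol(w_new))
  lapply(seq_len(nrow(w_new)), function(k) {
    ord <- order(-w_new[k, ], gene_ids)
    gene_ids[ord[seq_len(top_n)]]
  })
}

#' Hard topic labels
#'
#' Assigns every cell its highest-proportion topic; ties go to the smallest
#' topic index.
#' @param z N x K matrix with simplex rows.
#' @return integer vector of topic indices in 1..K.
#' @export
binarize_topics <- function(z) {
  as.integer(apply(as.matrix(z), 1L, which.max))
}

#' Write a topic result to disk
#'
#' Emits \code{topics.csv} (cells x topics), \code{modules.csv} (topics x
#' genes, rescored), \code{rankings.tsv} (topic, rank, gene, score) and
#' \code{labels.csv}.
#' @param res a \code{topic_result}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_topic_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  K <- ncol(res$z)
  zt <- as.data.frame(res$z)
  names(zt) <- paste0("topic", seq_len(K))
  utils::write.csv(cbind(cell_id = res$cell_ids, zt), file.path(dir, "topics.csv"), row.names = FALSE)
  wn <- if (res$scenario == "time") apply(res$w_new, c(2, 3), mean) else res$w_new
  mo <- as.data.frame(wn)
  names(mo) <- res$gene_ids
  utils::write.csv(cbind(topic = paste0("topic", seq_len(K)), mo),
                   file.path(dir, "modules.csv"), row.names = FALSE)
  rk <- if (res$scenario == "time") res$rankings[[1]] else res$rankings
  tab <- do.call(rbind, lapply(seq_along(rk), function(k) {
    g <- rk[[k]]
    data.frame(topic = k, rank = seq_along(g), gene = g,
               score = wn[k, match(g, res$gene_ids)])
  }))
  utils::write.table(tab, file.path(dir, "rankings.tsv"), sep = "\t", row.names = FALSE)
  utils::write.csv(data.frame(cell_id = res$cell_ids, topic = res$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(file.path(dir, c("topics.csv", "modules.csv", "rankings.tsv", "labels.csv")))
}
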