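# Comparing inferred topics against planted ground truth.

#' Match inferred topics to reference patterns
#'
#' Computes the Pearson correlation between every inferred topic-proportion
#' column and every reference column, then finds the bijective assignment
#' maximizing total correlation (Hungarian algorithm). Used to evaluate
#' recovery of planted patterns, where topic order is arbitrary.
#'
#' @param z_est N x K inferred topic proportions.
#' @param z_ref N x K reference proportions or binary pattern indicators.
#' @return list with \code{perm} (reference column j is matched by inferred
#'   topic \code{perm[j]}), \code{cors} (per-reference matched correlation)
#'   and the full correlation \code{matrix}.
#' @export
match_topics <- function(z_est, z_ref) {
  z_est <- as.matrix(z_est); z_ref <- as.matrix(z_ref)
  .assert(nrow(z_est) == nrow(z_ref), "row mismatch")
  .assert(ncol(z_est) == ncol(z_ref), "column mismatch: %d vs %d", ncol(z_est), ncol(z_ref))
  cm <- stats::cor(z_est, z_ref)  # rows: est, cols: ref
  cm[!is.finite(cm)] <- 0
  sol <- clue::solve_LSAP(t(pmax(cm, -1) + 1), maximum = TRUE)  # shift >= 0 for the solver
  perm <- as.integer(sol)  # ref j -> est perm[j]
  cors <- cm[cbind(perm, seq_len(ncol(cm)))]
  list(perm = perm, cors = cors, matrix = cm)
}

#' Fraction of planted module genes recovered in the top rankings
#'
#' For each topic (after matching), the fraction of its planted genes that
#' appear within the top-\code{|planted|} rescored ranking.
#'
#' @param rankings per-topic ordered gene lists (from
#'   \code{\link{extract_results}}).
#' @param module_genes list of planted gene index vectors (truth).
#' @param gene_ids gene identifiers indexing \code{module_genes}.
#' @param perm topic matching from \code{\link{match_topics}}.
#' @return per-reference-topic recovery fractions.
#' @export
module_recovery <- function(rankings, module_genes, gene_ids, perm = seq_along(module_genes)) {
  vapply(seq_along(module_genes), function(k) {
    planted <- gene_ids[module_genes[[k]]]
    top <- rankings[[perm[k]]][seq_len(length(planted))]
    mean(planted %in% top)
  }, numeric(1))
}
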