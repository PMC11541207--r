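# Reading, validating, filtering and normalizing expression data.

#' Construct an expression dataset
#'
#' The central container: a cells-by-genes matrix of non-negative integer
#' counts with per-cell 2-D spatial coordinates and optional batch / time
#' labels. All downstream functions consume this object.
#'
#' @param counts cells x genes matrix of non-negative integers. Dense base
#'   matrix or a \pkg{Matrix} sparse matrix.
#' @param coords cells x 2 numeric matrix of spatial positions (x, y).
#' @param gene_ids unique gene identifiers, one per column.
#' @param cell_ids unique cell identifiers, one per row.
#' @param batch optional per-cell batch label (factor or character).
#' @param time optional per-cell numeric time label.
#' @return an object of class \code{expression_dataset}.
#' @export
expression_dataset <- function(counts, coords,
                               gene_ids = colnames(counts),
                               cell_ids = rownames(counts),
                               batch = NULL, time = NULL) {
  counts <- .as_csparse(counts)
  n <- nrow(counts); g <- ncol(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(g))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  .assert(length(gene_ids) == g, "gene_ids length (%d) != number of genes (%d)", length(gene_ids), g)
  .assert(length(cell_ids) == n, "cell_ids length (%d) != number of cells (%d)", length(cell_ids), n)
  .assert(!anyDuplicated(gene_ids), "duplicate gene_ids")
  .assert(!anyDuplicated(cell_ids), "duplicate cell_ids")
  v <- counts@x
  if (any(v < 0)) .stopf("negative counts found (first at entry %d)", which(v < 0)[1])
  if (any(v != round(v))) .stopf("non-integer counts found (first at entry %d)", which(v != round(v))[1])
  coords <- as.matrix(coords)
  .assert(ncol(coords) == 2, "coords must have 2 columns")
  if (nrow(coords) != n) {
    .stopf("coordinate/cell mismatch: %d coordinate rows for %d cells", nrow(coords), n)
  }
  .assert(all(is.finite(coords)), "coords must be finite")
  if (!is.null(batch)) {
    .assert(length(batch) == n, "batch labels: %d values for %d cells", length(batch), n)
    batch <- as.factor(batch)
  }
  if (!is.null(time)) {
    .assert(length(time) == n, "time labels: %d values for %d cells", length(time), n)
    .assert(is.numeric(time) && all(is.finite(time)), "time labels must be finite numerics")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, coords = coords, gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids), batch = batch, time = time),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$batch)) cat(sprintf("  batches: %s\n", paste(levels(x$batch), collapse = ", ")))
  if (!is.null(x$time)) cat(sprintf("  time points: %s\n", paste(sort(unique(x$time)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$counts)

#' Subset an expression dataset by cells and/or genes
#' @param x an \code{expression_dataset}.
#' @param cells,genes integer or logical indices; missing keeps all.
#' @return an \code{expression_dataset}.
#' @export
subset_dataset <- function(x, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  expression_dataset(x$counts[cells, genes, drop = FALSE],
                     x$coords[cells, , drop = FALSE],
                     gene_ids = x$gene_ids[genes], cell_ids = x$cell_ids[cells],
                     batch = if (!is.null(x$batch)) droplevels(x$batch[cells]),
                     time = x$time[cells])
}

#' Load a count matrix (with coordinates) from disk
#'
#' Two on-disk layouts are supported. \code{format = "mtx"}: a MatrixMarket
#' triplet file whose rows are cells and columns are genes, accompanied by
#' \code{<path>.genes.tsv} and \code{<path>.cells.tsv} (one id per line), or
#' explicit paths via \code{genes_path}/\code{cells_path}.
#' \code{format = "csv"}: a dense table whose header row holds gene names and
#' whose first column holds cell ids. Coordinates come either from
#' \code{coords_path} (CSV with columns \code{cell_id,x,y}) or must be
#' attached later.
#'
#' @param path path to the matrix file.
#' @param format one of \code{"mtx"}, \code{"csv"}.
#' @param coords_path optional coordinates CSV (columns cell_id, x, y).
#' @param genes_path,cells_path optional id files for mtx input.
#' @param batch_path,time_path optional two-column CSVs (cell_id, value).
#' @return an \code{expression_dataset}.
#' @export
load_counts <- function(path, format = c("mtx", "csv"), coords_path = NULL,
                        genes_path = NULL, cells_path = NULL,
                        batch_path = NULL, time_path = NULL) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    if (is.null(genes_path)) genes_path <- paste0(path, ".genes.tsv")
    if (is.null(cells_path)) cells_path <- paste0(path, ".cells.tsv")
    .assert(file.exists(genes_path), "gene id file not found: %s", genes_path)
    .assert(file.exists(cells_path), "cell id file not found: %s", cells_path)
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    counts <- .as_csparse(m)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, row.names = 1)
    counts <- .as_csparse(as.matrix(tab))
    gene_ids <- colnames(tab)
    cell_ids <- rownames(tab)
  }
  coords <- NULL
  if (!is.null(coords_path)) {
    .assert(file.exists(coords_path), "coordinates file not found: %s", coords_path)
    ct <- utils::read.csv(coords_path)
    if (nrow(ct) != nrow(counts)) {
      .stopf("coordinate/cell mismatch: %d coordinate rows for %d cells", nrow(ct), nrow(counts))
    }
    if ("cell_id" %in% names(ct)) {
      .assert(setequal(ct$cell_id, cell_ids), "coordinate cell_ids do not match matrix cell ids")
      ct <- ct[match(cell_ids, ct$cell_id), ]
      coords <- as.matrix(ct[, c("x", "y")])
    } else {
      coords <- as.matrix(ct[, 1:2])
    }
  } else {
    coords <- matrix(0, nrow(counts), 2)  # placeholder; graph construction requires real coords
  }
  read_label <- function(p) {
    if (is.null(p)) return(NULL)
    .assert(file.exists(p), "label file not found: %s", p)
    lt <- utils::read.csv(p)
    .assert(nrow(lt) == nrow(counts), "label file %s: %d rows for %d cells", p, nrow(lt), nrow(counts))
    lt[match(cell_ids, lt[[1]]), 2]
  }
  expression_dataset(counts, coords, gene_ids = gene_ids, cell_ids = cell_ids,
                     batch = read_label(batch_path),
                     time = {tv <- read_label(time_path); if (!is.null(tv)) as.numeric(tv)})
}

#' Write a dataset to disk as MatrixMarket + side tables
#'
#' Writes \code{<prefix>.mtx}, \code{<prefix>.mtx.genes.tsv},
#' \code{<prefix>.mtx.cells.tsv} and \code{<prefix>.coords.csv}
#' (plus batch/time CSVs when present), in the layout \code{load_counts}
#' reads back.
#'
#' @param ds an \code{expression_dataset}.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_counts <- function(ds, prefix) {
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(ds$counts, mtx)
  writeLines(ds$gene_ids, paste0(mtx, ".genes.tsv"))
  writeLines(ds$cell_ids, paste0(mtx, ".cells.tsv"))
  cp <- paste0(prefix, ".coords.csv")
  utils::write.csv(data.frame(cell_id = ds$cell_ids, x = ds$coords[, 1], y = ds$coords[, 2]),
                   cp, row.names = FALSE)
  paths <- c(mtx, cp)
  if (!is.null(ds$batch)) {
    bp <- paste0(prefix, ".batch.csv")
    utils::write.csv(data.frame(cell_id = ds$cell_ids, batch = as.character(ds$batch)), bp, row.names = FALSE)
    paths <- c(paths, bp)
  }
  if (!is.null(ds$time)) {
    tp <- paste0(prefix, ".time.csv")
    utils::write.csv(data.frame(cell_id = ds$cell_ids, time = ds$time), tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Filter cells and genes
#'
#' Cells are filtered first: a cell is kept when it has at least
#' \code{min_genes_per_cell} detected genes (count > 0) and at least
#' \code{min_counts_per_cell} total counts. Genes are then kept when detected
#' in at least \code{min_frac_cells_per_gene} of the retained cells. The
#' defaults mirror common spatial-data practice (genes in >= 1% of cells,
#' cells with >= 100 genes).
#'
#' @param ds an \code{expression_dataset}.
#' @param min_genes_per_cell integer threshold on detected genes per cell.
#' @param min_frac_cells_per_gene fraction in [0, 1].
#' @param min_counts_per_cell integer threshold on per-cell total counts.
#' @return the filtered \code{expression_dataset}, order preserved.
#' @export
filter_dataset <- function(ds, min_genes_per_cell = 100,
                           min_frac_cells_per_gene = 0.01,
                           min_counts_per_cell = 0) {
  .assert(min_genes_per_cell >= 0 && min_frac_cells_per_gene >= 0 && min_counts_per_cell >= 0,
          "thresholds must be non-negative")
  detected <- Matrix::rowSums(ds$counts > 0)
  totals <- Matrix::rowSums(ds$counts)
  keep_cells <- detected >= min_genes_per_cell & totals >= min_counts_per_cell
  if (!any(keep_cells)) .stopf("no cells retained by the cell filter (min_genes=%d, min_counts=%d)",
                               min_genes_per_cell, min_counts_per_cell)
  sub <- ds$counts[keep_cells, , drop = FALSE]
  frac <- Matrix::colSums(sub > 0) / nrow(sub)
  keep_genes <- frac >= min_frac_cells_per_gene
  if (!any(keep_genes)) .stopf("no genes retained by the gene filter (min_frac=%g)", min_frac_cells_per_gene)
  subset_dataset(ds, cells = which(keep_cells), genes = which(keep_genes))
}

#' Log-normalize counts
#'
#' Per-cell total-count scaling to \code{target_sum} followed by natural
#' log1p: \code{lognorm[n, g] = log1p(target_sum * x[n, g] / l_n)} with
#' \code{l_n} the cell's total count. Also returns the per-gene baseline
#' \code{log(mean_n lognorm[, g] + epsilon)} used to center the background
#' residual prior.
#'
#' @param ds an \code{expression_dataset}.
#' @param target_sum per-cell scale target, default 1e4.
#' @param epsilon positivity guard for the baseline log, default 1e-8.
#' @return list with \code{lognorm} (dense cells x genes matrix),
#'   \code{baseline_log_mean} (per gene), \code{epsilon_prior}, and when time
#'   labels are present \code{baseline_log_mean_by_time} (times x genes).
#' @export
lognormalize <- function(ds, target_sum = 1e4, epsilon = 1e-8) {
  l <- Matrix::rowSums(ds$counts)
  if (any(l == 0)) .stopf("cell '%s' has zero total count; filter first", ds$cell_ids[which(l == 0)[1]])
  ln <- log1p(as.matrix(ds$counts / l) * target_sum)
  base <- log(colMeans(ln) + epsilon)
  out <- list(lognorm = ln, baseline_log_mean = base, epsilon_prior = epsilon)
  if (!is.null(ds$time)) {
    tp <- sort(unique(ds$time))
    out$baseline_log_mean_by_time <- t(vapply(tp, function(tt) {
      log(colMeans(ln[ds$time == tt, , drop = FALSE]) + epsilon)
    }, numeric(ncol(ln))))
    rownames(out$baseline_log_mean_by_time) <- tp
  }
  out
}

#' Select genes by log-normalized variance
#'
#' Fallback selector when no externally curated gene list is supplied: ranks
#' genes by the variance of their log-normalized expression and keeps the top
#' \code{n_genes}.
#'
#' @param ds an \code{expression_dataset}.
#' @param n_genes number of genes to keep.
#' @param target_sum passed to \code{\link{lognormalize}}.
#' @return filtered \code{expression_dataset} in original gene order.
#' @export
select_genes_by_variance <- function(ds, n_genes, target_sum = 1e4) {
  .assert(n_genes >= 1 && n_genes <= ncol(ds$counts), "n_genes out of range")
  v <- apply(lognormalize(ds, target_sum)$lognorm, 2, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n_genes)])
  subset_dataset(ds, genes = keep)
}
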