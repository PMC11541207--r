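# Internal numeric helpers shared across modules.

#' Row-wise numerically stabilized softmax
#'
#' @param x numeric matrix.
#' @return matrix of the same shape whose rows are simplexes.
#' @keywords internal
#' @noRd
.softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) if (!isTRUE(cond)) .stopf(fmt, ...)

# softplus and its inverse, used by the encoder positivity transform
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.sigmoid <- function(x) 1 / (1 + exp(-x))

# linear-interpolation empirical quantile (type 7), the package convention
.quantile7 <- function(x, p) unname(stats::quantile(x, probs = p, type = 7))

# coerce dense or sparse input to a column-compressed sparse matrix
.as_csparse <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  methods::as(x, "CsparseMatrix")
}
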