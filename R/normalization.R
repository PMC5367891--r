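#' Quantile normalization across samples
#'
#' Forces every column of the matrix to share the identical sorted value
#' vector — the across-column mean of order statistics. Ties within a
#' column receive the mean of the reference values they span (the classic
#' microarray convention, deterministic under heavy zero inflation).
#' Delegates to \code{limma::normalizeQuantiles(ties = TRUE)}, which
#' implements exactly this rule.
#'
#' @param em Raw-scale \code{\link{expression_matrix}} with at least two
#'   columns.
#' @return \code{ExpressionMatrix} with
#'   \code{scale_tag = "quantile_normalized"}.
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale_tag != "raw")
    stop("quantile normalization expects a raw-scale matrix, got '",
         em$scale_tag, "'")
  v <- em$values
  if (ncol(v) < 2L) stop("quantile normalization needs at least 2 columns")
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  expression_matrix(out, "quantile_normalized")
}

#' Elementwise log2(x + 1)
#'
#' Variance-stabilizing transform applied before all linear-model and PCA
#' analyses; 0 maps to 0 so undetected transcripts stay at zero.
#'
#' @param em \code{ExpressionMatrix} on the raw or quantile-normalized scale.
#' @return \code{ExpressionMatrix} with \code{scale_tag = "log2p1"}.
#' @export
log2p1 <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!em$scale_tag %in% c("raw", "quantile_normalized"))
    stop("log2p1 expects raw or quantile_normalized scale, got '",
         em$scale_tag, "'")
  out <- em
  out$values <- log2(em$values + 1)
  out$scale_tag <- "log2p1"
  out
}

#' Row mean centering
#'
#' Subtracts each feature's (row's) mean, as done before principal
#' component analysis. Idempotent.
#'
#' @param em An \code{ExpressionMatrix}.
#' @return \code{ExpressionMatrix} with \code{scale_tag = "centered"}.
#' @export
mean_center <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  out <- em
  out$values <- em$values - rowMeans(em$values)
  out$scale_tag <- "centered"
  out
}

#' Principal component analysis of a centered expression matrix
#'
#' Features are rows, samples columns. Scores and loadings come from the
#' singular value decomposition of the row-centered matrix: loadings are
#' the left singular vectors, sample scores the right singular vectors
#' scaled by the singular values. Sign convention: the largest-magnitude
#' loading of each component is positive, making results deterministic.
#' No unit-variance scaling is applied (only mean centering).
#'
#' @param em A mean-centered \code{ExpressionMatrix} (rows centered; other
#'   scales are centered on the fly with a message).
#' @param k Number of components; must not exceed \code{min(dim)}.
#' @return List of class \code{PcaResult} with \code{scores}
#'   (samples x k), \code{loadings} (features x k) and
#'   \code{explained_variance_fraction} (length k, non-increasing).
#' @export
pca <- function(em, k = 2L) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale_tag != "centered") {
    message("pca: centering rows (input scale was '", em$scale_tag, "')")
    em <- mean_center(em)
  }
  v <- em$values
  if (k > min(dim(v)))
    stop("k = ", k, " exceeds min(dim) = ", min(dim(v)))
  sv <- svd(v, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    u <- sv$u[, j]
    if (u[which.max(abs(u))] < 0) -1 else 1
  }, numeric(1L))
  loadings <- sweep(sv$u, 2L, flip, "*")
  scores <- sweep(sv$v, 2L, flip * sv$d[seq_len(k)], "*")
  rownames(loadings) <- rownames(v)
  rownames(scores) <- colnames(v)
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_fraction =
                   (sv$d^2 / sum(sv$d^2))[seq_len(k)]),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat(sprintf("PcaResult: %d samples, %d components; explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%",
                            100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}
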