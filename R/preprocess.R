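.check_matrix <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(mat))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicated sample ids")
  if (anyNA(mat)) stop("expression matrix contains missing values")
  invisible(mat)
}

#' Exclude poor-quality samples on 3'/5' signal ratios
#'
#' Samples whose beta-actin or GAPDH 3'/5' signal ratio exceeds the
#' threshold are considered degraded targets and removed. The rule is a
#' strict inequality: a ratio exactly at the threshold is retained. Values
#' of retained samples are untouched and their order preserved.
#'
#' @param mat Expression matrix, genes x samples.
#' @param qc Data frame with columns `sample_id`, `actin_ratio`,
#'   `gapdh_ratio` covering every sample in `mat`.
#' @param threshold Exclusion threshold for either ratio (default 3.0).
#' @return List with `matrix` (retained samples) and `excluded`
#'   (character vector of removed sample ids).
#' @export
qc_filter <- function(mat, qc, threshold = 3.0) {
  .check_matrix(mat)
  stopifnot(all(c("sample_id", "actin_ratio", "gapdh_ratio") %in% names(qc)))
  missing <- setdiff(colnames(mat), qc$sample_id)
  if (length(missing))
    stop("samples missing from QC table: ", paste(missing, collapse = ", "))
  if (any(qc$actin_ratio <= 0 | qc$gapdh_ratio <= 0))
    stop("QC ratios must be positive")
  qc <- qc[match(colnames(mat), qc$sample_id), ]
  fail <- qc$actin_ratio > threshold | qc$gapdh_ratio > threshold
  list(matrix = mat[, !fail, drop = FALSE],
       excluded = colnames(mat)[fail])
}

#' Row-wise z-score transformation
#'
#' Standardizes each gene to mean 0 and sample standard deviation 1
#' (denominator n - 1) across samples. Constant rows cannot be scaled; they
#' are set to all zeros with a warning rather than dropped, so gene indices
#' stay aligned with annotation.
#'
#' @param mat Expression matrix, genes x samples.
#' @return Matrix of the same shape.
#' @export
zscore_transform <- function(mat) {
  .check_matrix(mat)
  mu <- rowMeans(mat)
  centred <- mat - mu
  sds <- sqrt(rowSums(centred^2) / (ncol(mat) - 1L))
  const <- sds < .Machine$double.eps^0.5
  if (any(const)) {
    warning(sum(const), " constant gene row(s) set to zero")
    centred[const, ] <- 0
    sds[const] <- 1
  }
  centred / sds
}

#' Per-gene log2 ratio to the mean expression level
#'
#' Subtracts each gene's row mean from its log2 values, i.e. expresses every
#' measurement as a log2 ratio with respect to the gene's mean expression
#' level — the transform used for signature heat maps.
#'
#' @param mat Expression matrix on the log2 scale.
#' @return Matrix of the same shape; every row sums to zero.
#' @export
log2_ratio_to_mean <- function(mat) {
  .check_matrix(mat)
  mat - rowMeans(mat)
}

#' Principal-component scores of the samples
#'
#' Projects gene-centred samples onto the top eigenvectors of the sample
#' covariance matrix (samples are observations, genes variables; no
#' rescaling beyond centring, so the canonical pipeline z-scores first).
#' Components are ordered by decreasing explained variance. For
#' reproducibility the sign of each component is fixed so that its
#' largest-magnitude gene loading is positive.
#'
#' @param mat Expression matrix, genes x samples; needs at least
#'   `n_components + 1` samples.
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `var_explained`
#'   (fractions for the returned components), `eigenvalues` and `loadings`.
#' @export
pca_scores <- function(mat, n_components = 2L) {
  .check_matrix(mat)
  if (ncol(mat) < n_components + 1L)
    stop("need at least n_components + 1 samples")
  pr <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > max(pr$sdev) * 1e-9)
  if (n_components > rank)
    stop("n_components exceeds the achievable rank (", rank, ")")
  idx <- seq_len(n_components)
  scores <- pr$x[, idx, drop = FALSE]
  loadings <- pr$rotation[, idx, drop = FALSE]
  for (j in idx) {
    k <- which.max(abs(loadings[, j]))
    if (loadings[k, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pr$sdev^2
  list(scores = scores,
       var_explained = ev[idx] / sum(ev),
       eigenvalues = ev[idx],
       loadings = loadings)
}

#' Leaf order from hierarchical clustering
#'
#' Agglomerative hierarchical clustering with Euclidean distance on genes or
#' samples; returns the dendrogram leaf order, the ordering used to lay out
#' signature heat maps. Linkage defaults to complete and is configurable.
#'
#' @param mat Expression matrix, genes x samples.
#' @param axis Cluster `"samples"` (columns) or `"genes"` (rows).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return Character vector of ids in dendrogram leaf order.
#' @export
cluster_order <- function(mat, axis = c("samples", "genes"),
                          linkage = "complete") {
  .check_matrix(mat)
  axis <- match.arg(axis)
  items <- if (axis == "samples") t(mat) else mat
  if (nrow(items) < 2L) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(items, method = "euclidean"),
                      method = linkage)
  rownames(items)[hc$order]
}
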