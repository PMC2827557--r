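.class_levels <- c("non_inflammatory", "inflammatory")

.as_class_factor <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% .class_levels))
    stop("labels must be 'inflammatory' or 'non_inflammatory'")
  factor(labels, levels = .class_levels)
}

#' Train a bagged classification forest on expression data
#'
#' Grows `n_trees` classification trees, each on an independent bootstrap
#' sample of the training samples (sampling with replacement, size equal to
#' the number of training samples — one bootstrap per tree), with
#' `mtry` candidate genes per split and the Gini impurity criterion, grown
#' to purity (minimum node size 1). Tree growing is delegated to
#' \pkg{randomForest}; bootstrap membership and the fitted trees are kept so
#' that out-of-bag error and Gini importance can be recomputed from first
#' principles.
#'
#' @param x Expression matrix, genes x training samples.
#' @param labels Class per sample, `"inflammatory"`/`"non_inflammatory"`.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Candidate genes per split; default `floor(sqrt(n_genes))`.
#' @param seed Integer seed; the model is reproducible from it.
#' @param replace Bootstrap with replacement (default). `replace = FALSE`
#'   with `sampsize` equal to the sample count trains every tree on the full
#'   sample (no out-of-bag set), useful for exact hand-checked examples.
#' @param sampsize Per-tree sample size; defaults to the number of samples.
#' @param min_node Minimum terminal-node size (default 1, growth to purity).
#' @return An object of class `"dc_forest"`.
#' @seealso [oob_error()], [gini_importance()], [predict.dc_forest()]
#' @export
dc_forest <- function(x, labels, n_trees = 1000L, mtry = NULL, seed = 1L,
                      replace = TRUE, sampsize = NULL, min_node = 1L) {
  .check_matrix(x)
  y <- .as_class_factor(labels)
  if (length(y) != ncol(x)) stop("labels must match the matrix samples")
  tab <- table(y)
  if (any(tab == 0L)) stop("degenerate labels: only one class present")
  if (any(tab < 2L)) stop("need at least 2 samples per class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(nrow(x))))
  if (is.null(sampsize)) sampsize <- ncol(x)

  set.seed(seed)
  rf <- randomForest::randomForest(
    x = t(x), y = y, ntree = n_trees, mtry = mtry, nodesize = min_node,
    replace = replace, sampsize = sampsize,
    keep.forest = TRUE, keep.inbag = TRUE)

  structure(list(rf = rf, gene_ids = rownames(x),
                 sample_ids = colnames(x), y = y,
                 x_samples = t(x), n_trees = n_trees, mtry = mtry,
                 seed = seed, replace = replace),
            class = "dc_forest")
}

#' @export
print.dc_forest <- function(x, ...) {
  cat(sprintf("Bagged classification forest: %d trees, %d genes, %d samples (mtry %d)\n",
              x$n_trees, length(x$gene_ids), length(x$y), x$mtry))
  e <- oob_error(x)
  cat(sprintf("  out-of-bag error: %.4f (%d sample(s) never out of bag)\n",
              as.numeric(e), attr(e, "n_never_oob")))
  invisible(x)
}

# Per-tree class votes for the rows of `newx` (samples x genes).
.tree_votes <- function(model, newx) {
  pred <- stats::predict(model$rf, newx, predict.all = TRUE)$individual
  matrix(pred == "inflammatory", nrow = nrow(newx))
}

#' Classify samples by majority vote of the forest
#'
#' Each tree votes for a class; the majority decides. An exactly even vote
#' is resolved toward `non_inflammatory` (conservative toward the steady
#' state). Genes required by the model but absent from `newdata` are an
#' error listing them.
#'
#' @param object A [dc_forest()] model.
#' @param newdata Expression matrix, genes x samples, covering the model's
#'   genes.
#' @param ... Unused.
#' @return Data frame with `sample_id`, predicted `class` and
#'   `vote_inflammatory` (fraction of trees voting inflammatory).
#' @export
predict.dc_forest <- function(object, newdata, ...) {
  .check_matrix(newdata)
  missing <- setdiff(object$gene_ids, rownames(newdata))
  if (length(missing))
    stop("genes missing from newdata: ", paste(missing, collapse = ", "))
  newx <- t(newdata[object$gene_ids, , drop = FALSE])
  votes_inf <- rowMeans(.tree_votes(object, newx))
  data.frame(sample_id = colnames(newdata),
             class = ifelse(votes_inf > 0.5, "inflammatory",
                            "non_inflammatory"),
             vote_inflammatory = unname(votes_inf),
             stringsAsFactors = FALSE)
}

#' Out-of-bag classification error
#'
#' For every training sample, takes the majority vote among the trees whose
#' bootstrap sample excluded it, and reports the fraction misclassified.
#' Even votes resolve to `non_inflammatory`. Samples that were in-bag for
#' every tree cannot be assessed; they are skipped and counted in the
#' `n_never_oob` attribute.
#'
#' @param model A [dc_forest()] model.
#' @return The error rate in \[0, 1\], with attributes `n_evaluated` and
#'   `n_never_oob`.
#' @export
oob_error <- function(model) {
  stopifnot(inherits(model, "dc_forest"))
  oob <- model$rf$inbag == 0L
  votes <- .tree_votes(model, model$x_samples)
  n_oob <- rowSums(oob)
  inf_votes <- rowSums(votes & oob)
  pred <- ifelse(inf_votes > n_oob / 2, "inflammatory", "non_inflammatory")
  use <- n_oob > 0L
  err <- if (any(use)) mean(pred[use] != as.character(model$y[use])) else NA_real_
  structure(err, n_evaluated = sum(use), n_never_oob = sum(!use))
}

.gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Walks one stored tree, routing the tree's in-bag training samples (with
# bootstrap multiplicity) down the splits, and accumulates per-gene impurity
# decreases weighted by the node sample fraction.
.tree_importance <- function(tree, x_samples, y_int, inbag_counts) {
  p <- ncol(x_samples)
  imp <- numeric(p)
  n_total <- sum(inbag_counts)
  # stack of (node index, member weights)
  stack <- list(list(node = 1L, w = inbag_counts))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (tree[node, "status"] == -1L) next  # terminal
    w <- top$w
    v <- tree[node, "split var"]
    s <- tree[node, "split point"]
    left <- x_samples[, v] <= s
    wl <- w * left
    wr <- w * !left
    cnt <- function(wt) c(sum(wt[y_int == 1L]), sum(wt[y_int == 2L]))
    cn <- cnt(w); cl <- cnt(wl); cr <- cnt(wr)
    nn <- sum(cn); nl <- sum(cl); nr <- sum(cr)
    dec <- (nn * .gini(cn) - nl * .gini(cl) - nr * .gini(cr)) / n_total
    imp[v] <- imp[v] + dec
    stack[[length(stack) + 1L]] <- list(node = tree[node, "left daughter"], w = wl)
    stack[[length(stack) + 1L]] <- list(node = tree[node, "right daughter"], w = wr)
  }
  imp
}

#' Mean decrease in Gini impurity per gene
#'
#' For each gene, sums over all tree nodes splitting on that gene the
#' decrease in Gini impurity — (parent impurity minus weighted child
#' impurity) times the node's fraction of the tree's bootstrap sample — and
#' averages over trees. Computed by walking the stored trees with their
#' bootstrap membership, so a gene never used in any split scores exactly 0.
#'
#' @param model A [dc_forest()] model.
#' @return Named non-negative numeric vector, one entry per gene.
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "dc_forest"))
  y_int <- as.integer(model$y)
  imp <- numeric(length(model$gene_ids))
  for (k in seq_len(model$rf$ntree)) {
    tree <- randomForest::getTree(model$rf, k, labelVar = FALSE)
    imp <- imp + .tree_importance(tree, model$x_samples, y_int,
                                  model$rf$inbag[, k])
  }
  stats::setNames(imp / model$rf$ntree, model$gene_ids)
}
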