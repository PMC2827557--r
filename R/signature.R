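#' Assign regulation directions to genes
#'
#' A gene is `up` if its mean expression in inflammatory samples exceeds its
#' mean in non-inflammatory samples, otherwise `down`. The margin (mean
#' difference, inflammatory minus non-inflammatory) is recorded; an exact
#' tie is reported as `up` with zero margin and a warning.
#'
#' @param x Expression matrix, genes x samples.
#' @param labels Class per sample.
#' @param gene_ids Genes to annotate (must be present in `x`).
#' @return Data frame (gene_id, direction, margin).
#' @export
assign_direction <- function(x, labels, gene_ids = rownames(x)) {
  .check_matrix(x)
  y <- .as_class_factor(labels)
  if (length(y) != ncol(x)) stop("labels must match the matrix samples")
  if (!all(levels(y) %in% unique(as.character(y))))
    stop("both classes must be present")
  missing <- setdiff(gene_ids, rownames(x))
  if (length(missing))
    stop("genes not in matrix: ", paste(missing, collapse = ", "))
  sub <- x[gene_ids, , drop = FALSE]
  margin <- rowMeans(sub[, y == "inflammatory", drop = FALSE]) -
    rowMeans(sub[, y == "non_inflammatory", drop = FALSE])
  if (any(margin == 0))
    warning("tied class means for ",
            paste(gene_ids[margin == 0], collapse = ", "),
            "; direction set to 'up' with zero margin")
  data.frame(gene_id = gene_ids,
             direction = ifelse(margin >= 0, "up", "down"),
             margin = unname(margin), stringsAsFactors = FALSE)
}

#' Select an inflammation gene signature by random-forest backward elimination
#'
#' The fitting function of the package. Starting from all genes, it
#' repeatedly (i) trains a bagged classification forest ([dc_forest()]) on
#' the current gene set, (ii) records the out-of-bag (OOB) error, and (iii)
#' drops the `drop_fraction` of genes with lowest Gini importance, until two
#' genes remain. The selected signature is the smallest gene set along this
#' trajectory whose OOB error does not exceed the minimum observed OOB error
#' plus `se_rule` times the binomial standard error of that minimum — the
#' published default of the backward-elimination gene-selection method the
#' analysis follows. Regulation directions are then assigned by class-mean
#' comparison ([assign_direction()]).
#'
#' Each round trains with a sub-seed derived deterministically from `seed`,
#' so the whole selection path is reproducible. Setting `top_k` skips the
#' OOB stopping rule and forces a signature of fixed size: the `top_k` genes
#' with highest Gini importance in the initial full-gene forest.
#'
#' @param x Expression matrix, genes x training samples.
#' @param labels Class per sample (`"inflammatory"`/`"non_inflammatory"`).
#' @param n_trees Trees per forest (default 1000).
#' @param mtry Candidate genes per split; default `floor(sqrt(p))`,
#'   recomputed as the gene set shrinks.
#' @param drop_fraction Fraction of genes dropped per round, in (0, 1).
#' @param se_rule Multiplier of the binomial standard error in the stopping
#'   rule (0 picks the smallest set attaining the minimum OOB error).
#' @param seed Integer seed for the whole selection path.
#' @param top_k Optional forced signature size.
#' @return An object of class `"dc_signature"`: a list with `genes` (gene_id,
#'   direction, importance, margin, rank), `forest` (the selected round's
#'   model, used by [predict.dc_signature()]), `trajectory` (round, n_genes,
#'   oob_error, n_evaluated), `oob_error`, `selected_round` and the call
#'   parameters.
#' @export
#' @examples
#' sim <- simulate_expression(synthetic_config(
#'   n_genes = 60, n_signature_up = 4, n_signature_down = 2, seed = 3))
#' fit <- dc_signature(sim$expression, sim$sheet$class,
#'                     n_trees = 50, seed = 3)
#' print(fit)
dc_signature <- function(x, labels, n_trees = 1000L, mtry = NULL,
                         drop_fraction = 0.2, se_rule = 1.0, seed = 1L,
                         top_k = NULL) {
  .check_matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 genes")
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("invalid configuration: `drop_fraction` must lie in (0, 1)")
  y <- .as_class_factor(labels)

  genes <- rownames(x)
  traj <- list()
  round_genes <- list()
  round_imp <- list()
  r <- 0L
  repeat {
    r <- r + 1L
    m <- if (is.null(mtry)) max(1L, floor(sqrt(length(genes)))) else
      min(mtry, length(genes))
    fit <- dc_forest(x[genes, , drop = FALSE], y, n_trees = n_trees,
                     mtry = m, seed = .derive_seed(seed, r))
    err <- oob_error(fit)
    imp <- gini_importance(fit)
    traj[[r]] <- data.frame(round = r, n_genes = length(genes),
                            oob_error = as.numeric(err),
                            n_evaluated = attr(err, "n_evaluated"))
    round_genes[[r]] <- genes
    round_imp[[r]] <- imp
    if (length(genes) <= 2L || !is.null(top_k)) break
    keep_n <- max(2L, length(genes) - max(1L, floor(drop_fraction * length(genes))))
    ord <- order(-imp, genes)  # ties broken by gene id for determinism
    genes <- genes[ord][seq_len(keep_n)]
  }
  trajectory <- do.call(rbind, traj)

  if (!is.null(top_k)) {
    if (top_k < 1L || top_k > nrow(x)) stop("top_k out of range")
    imp1 <- round_imp[[1L]]
    ord <- order(-imp1, round_genes[[1L]])
    sel_genes <- round_genes[[1L]][ord][seq_len(top_k)]
    sel_round <- NA_integer_
    sel_fit <- dc_forest(x[sel_genes, , drop = FALSE], y, n_trees = n_trees,
                         mtry = if (is.null(mtry))
                           max(1L, floor(sqrt(length(sel_genes)))) else
                             min(mtry, length(sel_genes)),
                         seed = .derive_seed(seed, 0L))
    sel_err <- oob_error(sel_fit)
    sel_imp <- gini_importance(sel_fit)
  } else {
    errs <- trajectory$oob_error
    i_min <- which.min(errs)
    e_min <- errs[i_min]
    se_min <- sqrt(e_min * (1 - e_min) / trajectory$n_evaluated[i_min])
    ok <- which(errs <= e_min + se_rule * se_min)
    sel_round <- ok[which.min(trajectory$n_genes[ok])]
    sel_genes <- round_genes[[sel_round]]
    # rebuild the selected round's forest (same sub-seed => identical model)
    sel_fit <- dc_forest(x[sel_genes, , drop = FALSE], y, n_trees = n_trees,
                         mtry = if (is.null(mtry))
                           max(1L, floor(sqrt(length(sel_genes)))) else
                             min(mtry, length(sel_genes)),
                         seed = .derive_seed(seed, sel_round))
    sel_err <- trajectory$oob_error[sel_round]
    sel_imp <- round_imp[[sel_round]]
  }

  dirs <- assign_direction(x, y, sel_genes)
  ord <- order(-sel_imp[sel_genes], sel_genes)
  genes_df <- data.frame(gene_id = sel_genes,
                         direction = dirs$direction,
                         importance = unname(sel_imp[sel_genes]),
                         margin = dirs$margin,
                         stringsAsFactors = FALSE)[ord, ]
  genes_df$rank <- seq_len(nrow(genes_df))
  rownames(genes_df) <- NULL

  structure(list(genes = genes_df, forest = sel_fit,
                 trajectory = trajectory, oob_error = as.numeric(sel_err),
                 selected_round = sel_round,
                 params = list(n_trees = n_trees, mtry = mtry,
                               drop_fraction = drop_fraction,
                               se_rule = se_rule, seed = seed,
                               top_k = top_k)),
            class = "dc_signature")
}

# Deterministic per-stage/per-round sub-seed, kept below 2^31.
.derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2011L + 7L * as.integer(k) %% 2011L
}

#' @export
print.dc_signature <- function(x, ...) {
  n_up <- sum(x$genes$direction == "up")
  n_down <- sum(x$genes$direction == "down")
  cat(sprintf("Inflammation signature: %d genes (%d up, %d down)\n",
              nrow(x$genes), n_up, n_down))
  cat(sprintf("  out-of-bag error %.4f", x$oob_error))
  if (!is.na(x$selected_round))
    cat(sprintf(" at elimination round %d of %d",
                x$selected_round, nrow(x$trajectory)))
  cat("\n  top genes:",
      paste(utils::head(x$genes$gene_id, 5L), collapse = ", "),
      if (nrow(x$genes) > 5L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.dc_signature <- function(object, ...) {
  structure(list(genes = object$genes, trajectory = object$trajectory,
                 oob_error = object$oob_error,
                 selected_round = object$selected_round,
                 params = object$params),
            class = "summary.dc_signature")
}

#' @export
print.summary.dc_signature <- function(x, ...) {
  cat("Backward-elimination trajectory (", nrow(x$trajectory), " rounds):\n",
      sep = "")
  print(x$trajectory, row.names = FALSE)
  cat("\nSelected signature (round ",
      ifelse(is.na(x$selected_round), "forced top-k", x$selected_round),
      ", OOB error ", sprintf("%.4f", x$oob_error), "):\n", sep = "")
  print(x$genes, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dc_signature <- function(object, ...) {
  stats::setNames(object$genes$importance, object$genes$gene_id)
}

#' Classify new samples with a fitted signature
#'
#' Applies the selected round's forest to a test matrix; majority vote over
#' trees, even votes resolved toward `non_inflammatory`.
#'
#' @param object A [dc_signature()] fit.
#' @param newdata Expression matrix, genes x samples, containing the
#'   signature genes (on the same scale as the training matrix).
#' @param ... Unused.
#' @return Data frame (sample_id, class, vote_inflammatory).
#' @export
predict.dc_signature <- function(object, newdata, ...) {
  predict(object$forest, newdata)
}

#' Plot the backward-elimination OOB trajectory
#'
#' OOB error against the number of retained genes (log scale), with the
#' selected signature size marked.
#'
#' @param x A [dc_signature()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dc_signature <- function(x, ...) {
  tr <- x$trajectory
  graphics::plot(tr$n_genes, tr$oob_error, log = "x", type = "b", pch = 16,
                 xlab = "genes retained", ylab = "out-of-bag error",
                 main = "Backward-elimination trajectory", ...)
  if (!is.na(x$selected_round))
    graphics::abline(v = tr$n_genes[x$selected_round], lty = 2)
  invisible(x)
}
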