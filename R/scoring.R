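.check_ct <- function(ct) {
  need <- c("gene_id", "condition", "replicate", "ct_target", "ct_18s")
  if (!is.data.frame(ct) || !all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_18s)))
    stop("Ct values must be finite")
  if (any(ct$ct_target <= 0) || any(ct$ct_18s <= 0))
    stop("Ct values must be positive")
  invisible(ct)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, dCt = Ct_target - Ct_housekeeping; ddCt subtracts the
#' gene's reference (untreated) dCt, averaged over the reference replicates;
#' the fold change is `2^-ddCt`. Each gene x condition cell is the
#' arithmetic mean of its replicate fold changes. The reference condition's
#' column is 1 by construction.
#'
#' @param ct Ct table (gene_id, condition, replicate, ct_target, ct_18s;
#'   optionally claimed_class), e.g. from [simulate_ct_table()] or
#'   [read_ct()].
#' @param reference Label of the untreated reference condition; defaults to
#'   the table's `"reference"` attribute, else `"untreated"`.
#' @return An object of class `"dc_fc"`: list with `fold` (genes x
#'   conditions matrix), `n_replicates` (same shape), `reference`, and
#'   `claimed_class` (named by condition, when present in `ct`).
#' @export
#' @examples
#' ct <- data.frame(gene_id = "g1",
#'                  condition = c("untreated", "lps"),
#'                  replicate = 1L, ct_target = c(26, 25), ct_18s = 12)
#' fold_change(ct)$fold  # lps column: one cycle earlier = fold 2
fold_change <- function(ct, reference = NULL) {
  .check_ct(ct)
  if (is.null(reference))
    reference <- attr(ct, "reference") %||% "untreated"
  genes <- unique(ct$gene_id)
  conds <- unique(ct$condition)
  if (!reference %in% conds)
    stop("reference condition '", reference, "' absent from the Ct table")
  conds <- c(reference, setdiff(conds, reference))

  dct <- ct$ct_target - ct$ct_18s
  ref_rows <- ct$condition == reference
  no_ref <- setdiff(genes, unique(ct$gene_id[ref_rows]))
  if (length(no_ref))
    stop("gene(s) lacking reference Ct: ", paste(no_ref, collapse = ", "))
  ref_dct <- tapply(dct[ref_rows], ct$gene_id[ref_rows], mean)

  fold_rep <- 2^-(dct - ref_dct[ct$gene_id])
  key <- list(gene = factor(ct$gene_id, levels = genes),
              cond = factor(ct$condition, levels = conds))
  fold <- tapply(fold_rep, key, mean)
  nrep <- tapply(fold_rep, key, length)
  nrep[is.na(nrep)] <- 0L
  if (any(nrep[, -1L] == 0L))
    stop("every gene x condition cell needs at least one replicate")
  fold[, reference] <- 1  # exact, by definition of the reference

  claimed <- NULL
  if ("claimed_class" %in% names(ct)) {
    cc <- unique(ct[, c("condition", "claimed_class")])
    claimed <- stats::setNames(cc$claimed_class, cc$condition)[conds]
  }
  structure(list(fold = fold, n_replicates = nrep,
                 reference = reference, claimed_class = claimed),
            class = "dc_fc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dc_fc <- function(x, ...) {
  cat(sprintf("Fold-change table: %d genes x %d conditions (reference '%s')\n",
              nrow(x$fold), ncol(x$fold), x$reference))
  print(utils::head(round(x$fold, 3)))
  invisible(x)
}

.fc_matrix <- function(fc) {
  if (inherits(fc, "dc_fc")) fc$fold else as.matrix(fc)
}

#' Per-gene classification thresholds from reference stimuli
#'
#' For each gene, takes the median fold change over the known inflammatory
#' reference conditions and the median over the known non-inflammatory
#' ones; the gene's threshold is the arithmetic mean of the two medians.
#' The untreated reference condition is excluded from the computation.
#'
#' @param fc A [fold_change()] result (or a genes x conditions matrix).
#' @param reference_conditions Named character vector mapping condition
#'   labels to their known class; both classes must be represented.
#' @param directions Named character vector gene -> `"up"`/`"down"`,
#'   covering every gene of `fc` (e.g. from a fitted [dc_signature()]).
#' @return Data frame (gene_id, direction, median_inflammatory,
#'   median_noninflammatory, threshold).
#' @export
derive_thresholds <- function(fc, reference_conditions, directions) {
  m <- .fc_matrix(fc)
  if (inherits(fc, "dc_fc") &&
      fc$reference %in% names(reference_conditions)) {
    warning("untreated reference condition excluded from threshold derivation")
    reference_conditions <-
      reference_conditions[setdiff(names(reference_conditions), fc$reference)]
  }
  unknown <- setdiff(names(reference_conditions), colnames(m))
  if (length(unknown))
    stop("reference conditions absent from fold changes: ",
         paste(unknown, collapse = ", "))
  inf_conds <- names(reference_conditions)[reference_conditions == "inflammatory"]
  ninf_conds <- names(reference_conditions)[reference_conditions == "non_inflammatory"]
  if (!length(inf_conds) || !length(ninf_conds))
    stop("need at least one reference condition per class")
  uncovered <- setdiff(rownames(m), names(directions))
  if (length(uncovered))
    stop("directions missing for: ", paste(uncovered, collapse = ", "))

  med_inf <- apply(m[, inf_conds, drop = FALSE], 1L, stats::median)
  med_ninf <- apply(m[, ninf_conds, drop = FALSE], 1L, stats::median)
  if (any(med_inf == med_ninf))
    warning("zero threshold margin for ",
            paste(rownames(m)[med_inf == med_ninf], collapse = ", "))
  data.frame(gene_id = rownames(m),
             direction = unname(directions[rownames(m)]),
             median_inflammatory = unname(med_inf),
             median_noninflammatory = unname(med_ninf),
             threshold = unname((med_inf + med_ninf) / 2),
             stringsAsFactors = FALSE)
}

.score_one <- function(value, threshold, direction, claimed_class) {
  above <- value > threshold
  below <- value < threshold
  if (direction == "up") {
    as.integer((claimed_class == "inflammatory" && above) ||
               (claimed_class == "non_inflammatory" && below))
  } else {
    as.integer((claimed_class == "inflammatory" && below) ||
               (claimed_class == "non_inflammatory" && above))
  }
}

#' Direction-aware 0/1 scoring of one stimulus
#'
#' Scores each signature gene for a queried condition under a claimed
#' class. An up-regulated gene scores 1 when its fold change exceeds its
#' threshold and the condition is claimed inflammatory, or lies below the
#' threshold under a non-inflammatory claim; for down-regulated (repressed)
#' genes the rule is reversed. All other cases — including a value exactly
#' at the threshold — score 0.
#'
#' @param values Named numeric vector, gene -> mean fold change for the
#'   condition (one column of a [fold_change()] table).
#' @param thresholds Data frame from [derive_thresholds()] covering the
#'   genes.
#' @param claimed_class `"inflammatory"` or `"non_inflammatory"`.
#' @return Data frame (gene_id, direction, value, threshold, score).
#' @export
score_condition <- function(values, thresholds, claimed_class) {
  claimed_class <- match.arg(claimed_class, .class_levels)
  unknown <- setdiff(names(values), thresholds$gene_id)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  th <- thresholds[match(names(values), thresholds$gene_id), ]
  score <- mapply(.score_one, values, th$threshold, th$direction,
                  MoreArgs = list(claimed_class = claimed_class))
  data.frame(gene_id = names(values), direction = th$direction,
             value = unname(values), threshold = th$threshold,
             score = unname(score), stringsAsFactors = FALSE)
}

#' Concordance of a score vector
#'
#' Fraction of genes scoring 1, the percent rounded half-up to the nearest
#' integer, and the printed "k/n" form.
#'
#' @param scores 0/1 vector, or a [score_condition()] data frame.
#' @return List with `fraction`, `percent` and `k_of_n`.
#' @export
#' @examples
#' concordance(c(rep(1, 51), rep(0, 3)))$percent  # 94
concordance <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  stopifnot(length(scores) >= 1L, all(scores %in% c(0L, 1L)))
  k <- sum(scores)
  n <- length(scores)
  list(fraction = k / n,
       percent = .round_half_up(100 * k / n),
       k_of_n = sprintf("%d/%d", as.integer(k), n))
}

#' Majority-vote class call for one stimulus
#'
#' Each gene votes inflammatory when its fold change lies on the
#' inflammatory side of its threshold (above for up-regulated genes, below
#' for down-regulated ones), else non-inflammatory; the call is the
#' majority, with exact ties resolved to `non_inflammatory`.
#'
#' @inheritParams score_condition
#' @return List with `class`, `margin` (absolute vote difference over n)
#'   and the per-gene `votes`.
#' @export
call_class <- function(values, thresholds) {
  inf_scores <- score_condition(values, thresholds, "inflammatory")$score
  k_inf <- sum(inf_scores)
  n <- length(inf_scores)
  list(class = if (k_inf > n / 2) "inflammatory" else "non_inflammatory",
       margin = abs(k_inf - (n - k_inf)) / n,
       votes = stats::setNames(ifelse(inf_scores == 1L, "inflammatory",
                                      "non_inflammatory"), names(values)))
}

#' Scorecard for one condition
#'
#' Convenience wrapper assembling the full validation readout for a
#' queried stimulus: per-gene scores under the claimed class, the
#' concordance, and the threshold-vote class call.
#'
#' @param fc A [fold_change()] result.
#' @param condition Condition (column) to score.
#' @param thresholds From [derive_thresholds()].
#' @param claimed_class Claimed class; `"auto"` uses the class call.
#' @return An object of class `"dc_scorecard"`: list with `condition`,
#'   `claimed_class`, `genes` (per-gene table), `concordance` and `call`.
#' @export
scorecard <- function(fc, condition, thresholds, claimed_class = "auto") {
  m <- .fc_matrix(fc)
  if (!condition %in% colnames(m)) stop("unknown condition: ", condition)
  if (inherits(fc, "dc_fc") && condition == fc$reference)
    stop("the untreated reference condition is not scored")
  values <- m[, condition]
  cl <- call_class(values, thresholds)
  if (identical(claimed_class, "auto")) claimed_class <- cl$class
  genes <- score_condition(values, thresholds, claimed_class)
  structure(list(condition = condition, claimed_class = claimed_class,
                 genes = genes, concordance = concordance(genes),
                 call = cl),
            class = "dc_scorecard")
}

#' @export
print.dc_scorecard <- function(x, ...) {
  cat(sprintf("Condition '%s' claimed %s: concordance %s (%d%%); class call %s (margin %.2f)\n",
              x$condition, x$claimed_class, x$concordance$k_of_n,
              x$concordance$percent, x$call$class, x$call$margin))
  invisible(x)
}
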