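.round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test partition of the sample sheet
#'
#' Assigns samples to training and testing sets, stratified by class (or
#' stimulus): within each stratum, `round(train_fraction * n)` samples
#' (rounding half up) are drawn without replacement into the training set.
#' If the per-stratum rounding misses the rounded global target, the largest
#' strata are adjusted by one sample each until totals agree. Sampling is
#' keyed on sorted sample ids, so the assignment is invariant to the row
#' order of the sheet. With the default 115-sample design and fraction 2/3
#' this yields 77 training and 38 testing samples.
#'
#' `override_counts` fixes the training count per stratum explicitly (e.g.
#' `c(inflammatory = 50, non_inflammatory = 27)` reproduces the historical
#' realized split, which is not the proportional one); no global adjustment
#' is applied to overridden strata.
#'
#' @param sheet Sample sheet with `sample_id` and the stratification column.
#' @param train_fraction Fraction of samples assigned to training (0, 1).
#' @param stratify_by `"class"` or `"stimulus"`.
#' @param seed Integer seed; the split is deterministic given it.
#' @param override_counts Optional named vector, stratum -> training count.
#' @return Data frame (sample_id, role) with attributes `seed`,
#'   `train_fraction` and `stratum_counts` (stratum, n, n_train).
#' @export
stratified_split <- function(sheet, train_fraction = 2 / 3,
                             stratify_by = c("class", "stimulus"),
                             seed = 1L, override_counts = NULL) {
  stratify_by <- match.arg(stratify_by)
  stopifnot(is.data.frame(sheet), "sample_id" %in% names(sheet),
            stratify_by %in% names(sheet))
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample ids")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")

  strata <- split(sheet$sample_id, sheet[[stratify_by]])
  strata <- strata[order(names(strata))]
  sizes <- vapply(strata, length, integer(1))
  counts <- .round_half_up(train_fraction * sizes)

  overridden <- rep(FALSE, length(strata))
  if (!is.null(override_counts)) {
    unknown <- setdiff(names(override_counts), names(strata))
    if (length(unknown))
      stop("override_counts names unknown strata: ",
           paste(unknown, collapse = ", "))
    too_big <- override_counts > sizes[names(override_counts)]
    if (any(too_big))
      stop("override count exceeds stratum size for: ",
           paste(names(override_counts)[too_big], collapse = ", "))
    counts[names(override_counts)] <- override_counts
    overridden[match(names(override_counts), names(strata))] <- TRUE
  }

  # reconcile with the rounded global target, adjusting largest strata first
  if (!any(overridden)) {
    target <- .round_half_up(train_fraction * sum(sizes))
    diff <- target - sum(counts)
    ord <- order(sizes, decreasing = TRUE)
    i <- 1L
    while (diff != 0L && i <= 10L * length(strata)) {
      s <- ord[((i - 1L) %% length(strata)) + 1L]
      step <- sign(diff)
      if (counts[s] + step >= 0L && counts[s] + step <= sizes[s]) {
        counts[s] <- counts[s] + step
        diff <- diff - step
      }
      i <- i + 1L
    }
  }

  set.seed(seed)
  train_ids <- unlist(lapply(seq_along(strata), function(i) {
    ids <- sort(strata[[i]])
    ids[sample.int(length(ids), counts[i])]
  }), use.names = FALSE)

  out <- data.frame(sample_id = sheet$sample_id,
                    role = ifelse(sheet$sample_id %in% train_ids,
                                  "train", "test"),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "train_fraction") <- train_fraction
  attr(out, "stratum_counts") <- data.frame(
    stratum = names(strata), n = unname(sizes), n_train = unname(counts),
    stringsAsFactors = FALSE)
  out
}
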