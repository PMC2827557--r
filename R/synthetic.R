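#' Stimulus composition of the emulated dendritic-cell compendium
#'
#' Default design of the simulated expression dataset: 12 stimulus groups
#' totalling 115 arrays, 79 labelled inflammatory and 36 non-inflammatory.
#' Group sizes follow the study-design enumeration (10 Listeria arrays, the
#' reading consistent with the 79 + 36 = 115 totals).
#'
#' @return A data frame with columns `stimulus`, `n` (number of arrays) and
#'   `class` (`"inflammatory"` or `"non_inflammatory"`).
#' @export
#' @examples
#' sum(dc_group_table()$n)  # 115
dc_group_table <- function() {
  data.frame(
    stimulus = c("untreated", "dexamethasone", "leishmania_amastigote",
                 "schistosoma_sla", "cpg", "leishmania_promastigote",
                 "listeria", "lps", "pam3cys", "polyic", "schistosoma_eggs",
                 "zymosan"),
    n = c(14L, 6L, 8L, 8L, 10L, 8L, 10L, 8L, 10L, 10L, 8L, 15L),
    class = c(rep("non_inflammatory", 4L), rep("inflammatory", 8L)),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic expression dataset
#'
#' Bundles and validates all parameters of the generator. Defaults emulate
#' the study conditions: a two-class design of 115 arrays (79 inflammatory /
#' 36 non-inflammatory) with a planted signature of 36 up- and 18
#' down-regulated genes. `n_genes` defaults to 2000 for tractable testing;
#' the full-scale array has 12488 probe sets.
#'
#' @param n_genes Number of simulated probe sets.
#' @param group_sizes Data frame with columns `stimulus`, `n`, `class`
#'   (see [dc_group_table()]).
#' @param n_signature_up,n_signature_down Number of planted genes shifted up
#'   (respectively down) in inflammatory samples.
#' @param effect_size Mean log2 shift of planted genes in the inflammatory
#'   class, in units of `noise_sd` (so the per-gene standardized separation
#'   equals `effect_size`).
#' @param noise_sd Within-group standard deviation on the log2 scale.
#' @param qc_fail_fraction Probability that a sample's 3'/5' signal ratio
#'   exceeds the 3.0 quality threshold.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return An object of class `"synthetic_config"` (a validated list).
#' @export
synthetic_config <- function(n_genes = 2000L,
                             group_sizes = dc_group_table(),
                             n_signature_up = 36L,
                             n_signature_down = 18L,
                             effect_size = 2,
                             noise_sd = 0.5,
                             qc_fail_fraction = 0,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
              n_signature_up = as.integer(n_signature_up),
              n_signature_down = as.integer(n_signature_down),
              effect_size = effect_size, noise_sd = noise_sd,
              qc_fail_fraction = qc_fail_fraction, seed = as.integer(seed))
  .check_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

.check_synthetic_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid configuration: `", field, "` ", why, call. = FALSE)
  }
  if (!is.numeric(cfg$n_genes) || length(cfg$n_genes) != 1L || cfg$n_genes < 1)
    bad("n_genes", "must be a positive count")
  gs <- cfg$group_sizes
  if (!is.data.frame(gs) || !all(c("stimulus", "n", "class") %in% names(gs)))
    bad("group_sizes", "must be a data frame with stimulus, n, class columns")
  if (any(gs$n < 1)) bad("group_sizes", "must have positive counts")
  if (anyDuplicated(gs$stimulus)) bad("group_sizes", "has duplicated stimuli")
  if (!all(gs$class %in% c("inflammatory", "non_inflammatory")))
    bad("group_sizes", "classes must be inflammatory/non_inflammatory")
  if (cfg$n_signature_up < 0) bad("n_signature_up", "must be non-negative")
  if (cfg$n_signature_down < 0) bad("n_signature_down", "must be non-negative")
  if (cfg$n_signature_up + cfg$n_signature_down > cfg$n_genes)
    bad("n_signature_up", "+ `n_signature_down` exceed `n_genes`")
  if (!is.numeric(cfg$effect_size) || cfg$effect_size < 0)
    bad("effect_size", "must be >= 0")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    bad("noise_sd", "must be > 0")
  if (cfg$qc_fail_fraction < 0 || cfg$qc_fail_fraction > 1)
    bad("qc_fail_fraction", "must lie in [0, 1]")
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  gs <- x$group_sizes
  n_inf <- sum(gs$n[gs$class == "inflammatory"])
  cat("Synthetic dataset configuration\n")
  cat(sprintf("  %d genes x %d samples (%d inflammatory / %d non-inflammatory)\n",
              x$n_genes, sum(gs$n), n_inf, sum(gs$n) - n_inf))
  cat(sprintf("  planted signature: %d up + %d down, effect %.2g sd, noise sd %.2g\n",
              x$n_signature_up, x$n_signature_down, x$effect_size, x$noise_sd))
  cat(sprintf("  qc fail fraction %.2g, seed %d\n", x$qc_fail_fraction, x$seed))
  invisible(x)
}

# Time-point/replicate layout within a stimulus group, mirroring the study's
# enumeration (e.g. n = 10 -> 2/4/8/12/24 h in duplicate, n = 15 in
# triplicate, n = 8 -> 4/8/12/24 h in duplicate, n = 6 -> 4/8/24 h).
.design_rows <- function(stimulus, n) {
  if (stimulus == "untreated")
    return(data.frame(timepoint_h = rep(0, n), replicate = seq_len(n)))
  if (n %% 5L == 0L && n %/% 5L <= 3L) {
    tps <- c(2, 4, 8, 12, 24); r <- n %/% 5L
  } else if (n %% 4L == 0L && n %/% 4L <= 2L) {
    tps <- c(4, 8, 12, 24); r <- n %/% 4L
  } else if (n %% 3L == 0L && n %/% 3L <= 2L) {
    tps <- c(4, 8, 24); r <- n %/% 3L
  } else {
    tps <- rep_len(c(2, 4, 8, 12, 24), n)
    return(data.frame(timepoint_h = tps,
                      replicate = stats::ave(tps, tps, FUN = seq_along)))
  }
  data.frame(timepoint_h = rep(tps, each = r),
             replicate = rep(seq_len(r), times = length(tps)))
}

.build_sample_sheet <- function(group_sizes) {
  rows <- lapply(seq_len(nrow(group_sizes)), function(i) {
    g <- group_sizes[i, ]
    d <- .design_rows(g$stimulus, g$n)
    data.frame(sample_id = sprintf("%s_t%02d_r%d", g$stimulus,
                                   as.integer(d$timepoint_h), d$replicate),
               stimulus = g$stimulus, timepoint_h = d$timepoint_h,
               class = g$class, replicate = as.integer(d$replicate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an expression compendium with a planted inflammation signature
#'
#' Draws a log2-scale expression matrix whose statistical structure matches
#' what the downstream analysis assumes: per-gene baseline means uniform on
#' 4-12 (expression-index range), additive Gaussian noise of sd `noise_sd`,
#' and planted signature genes shifted by `+/- effect_size * noise_sd` in
#' inflammatory samples. Non-signature genes are identically distributed
#' across classes. Per-sample 3'/5' QC ratios are drawn so that an expected
#' `qc_fail_fraction` of samples exceeds the 3.0 threshold.
#'
#' @param config A [synthetic_config()] object.
#' @return A list with components:
#'   \describe{
#'     \item{expression}{numeric matrix, genes x samples, log2 scale.}
#'     \item{sheet}{sample sheet (sample_id, stimulus, timepoint_h, class,
#'       replicate).}
#'     \item{qc}{per-sample QC metrics (sample_id, actin_ratio, gapdh_ratio).}
#'     \item{truth}{ground truth: `signature` (gene_id, direction) and
#'       `classes` (named by sample_id) for recovery tests.}
#'   }
#' @export
#' @examples
#' sim <- simulate_expression(synthetic_config(n_genes = 100, seed = 7))
#' dim(sim$expression)
simulate_expression <- function(config) {
  if (!inherits(config, "synthetic_config")) .check_synthetic_config(config)
  set.seed(config$seed)
  sheet <- .build_sample_sheet(config$group_sizes)
  ng <- config$n_genes
  n <- nrow(sheet)
  gene_ids <- sprintf("%d_at", 100000L + seq_len(ng))

  baseline <- stats::runif(ng, 4, 12)
  mat <- baseline + matrix(stats::rnorm(ng * n, 0, config$noise_sd), ng, n)
  dimnames(mat) <- list(gene_ids, sheet$sample_id)

  n_up <- config$n_signature_up
  n_down <- config$n_signature_down
  sig_idx <- sample.int(ng, n_up + n_down)
  up_idx <- sig_idx[seq_len(n_up)]
  down_idx <- sig_idx[setdiff(seq_len(n_up + n_down), seq_len(n_up))]
  shift <- config$effect_size * config$noise_sd
  inf <- sheet$class == "inflammatory"
  if (n_up > 0) mat[up_idx, inf] <- mat[up_idx, inf] + shift
  if (n_down > 0) mat[down_idx, inf] <- mat[down_idx, inf] - shift

  fails <- stats::runif(n) < config$qc_fail_fraction
  qc <- data.frame(
    sample_id = sheet$sample_id,
    actin_ratio = ifelse(fails, stats::runif(n, 3.2, 6), stats::runif(n, 0.8, 2.4)),
    gapdh_ratio = stats::runif(n, 0.8, 2.4),
    stringsAsFactors = FALSE
  )

  truth <- list(
    signature = data.frame(
      gene_id = gene_ids[c(up_idx, down_idx)],
      direction = rep(c("up", "down"), c(n_up, n_down)),
      stringsAsFactors = FALSE),
    classes = stats::setNames(sheet$class, sheet$sample_id)
  )
  list(expression = mat, sheet = sheet, qc = qc, truth = truth)
}

#' Simulate a qRT-PCR Ct table consistent with planted directions
#'
#' Emits target and 18s housekeeping Ct values per gene x condition x
#' replicate such that the implied 2^-ddCt fold change is centred at
#' `2^log2_fc` for an up-regulated gene under an inflammatory condition and
#' at `2^-log2_fc` under a non-inflammatory one (reversed for down-regulated
#' genes). An untreated reference condition with expected fold change 1 is
#' always included. The 18s Ct is held constant (the normalizer's noise is
#' not separately identifiable in 2^-ddCt); replicate noise of sd `noise_sd`
#' is placed on the target Ct, so `noise_sd = 0` makes the planted fold
#' changes exactly recoverable.
#'
#' @param config A [synthetic_config()] (supplies seed and default noise).
#' @param truth Ground truth from [simulate_expression()] (or any list with a
#'   `signature` data frame of gene_id/direction).
#' @param conditions Named character vector: names are condition labels,
#'   values their class (`"inflammatory"` or `"non_inflammatory"`).
#' @param n_replicates Replicates per gene x condition.
#' @param log2_fc Planted absolute log2 fold change of consistent
#'   gene/condition pairs.
#' @param noise_sd Standard deviation of target-Ct noise in cycles;
#'   defaults to `config$noise_sd`, may be 0.
#' @param reference Label of the untreated reference condition.
#' @param gene_ids Genes to include; defaults to all planted signature genes.
#'   Ids absent from the truth are an error.
#' @return A data frame with columns gene_id, condition, claimed_class,
#'   replicate, ct_target, ct_18s, carrying the reference label as attribute
#'   `"reference"`.
#' @export
simulate_ct_table <- function(config, truth, conditions,
                              n_replicates = 3L, log2_fc = 3,
                              noise_sd = config$noise_sd,
                              reference = "untreated",
                              gene_ids = NULL) {
  stopifnot(is.character(conditions), !is.null(names(conditions)))
  if (!all(conditions %in% c("inflammatory", "non_inflammatory")))
    stop("every condition must claim a class (inflammatory/non_inflammatory)")
  if (noise_sd < 0) stop("invalid configuration: `noise_sd` must be >= 0")
  sig <- truth$signature
  if (is.null(gene_ids)) gene_ids <- sig$gene_id
  unknown <- setdiff(gene_ids, sig$gene_id)
  if (length(unknown))
    stop("unknown gene id: ", paste(unknown, collapse = ", "))
  direction <- stats::setNames(sig$direction, sig$gene_id)[gene_ids]

  set.seed(config$seed + 7919L)  # independent stream from the array simulation
  ct_18s <- 12
  base_dct <- stats::setNames(stats::runif(length(gene_ids), 2, 10), gene_ids)

  cond_labels <- c(setdiff(reference, names(conditions)), names(conditions))
  cond_class <- c(stats::setNames(rep("unknown", length(setdiff(reference, names(conditions)))),
                                  setdiff(reference, names(conditions))),
                  conditions)

  grid <- expand.grid(gene_id = gene_ids, condition = cond_labels,
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sgn <- ifelse(direction[grid$gene_id] == "up", 1, -1) *
    ifelse(cond_class[grid$condition] == "inflammatory", 1,
           ifelse(cond_class[grid$condition] == "non_inflammatory", -1, 0))
  lfc <- ifelse(grid$condition == reference, 0, sgn * log2_fc)
  noise <- if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0
  out <- data.frame(
    gene_id = grid$gene_id,
    condition = grid$condition,
    claimed_class = unname(cond_class[grid$condition]),
    replicate = grid$replicate,
    ct_target = ct_18s + base_dct[grid$gene_id] - lfc + noise,
    ct_18s = ct_18s,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  out
}
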