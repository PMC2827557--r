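#' Configuration of the end-to-end pipeline
#'
#' Collects every stage parameter with its documented default. Inputs are
#' either file paths (`matrix_path`, `sheet_path`, `qc_path`, `ct_path`) or,
#' when these are `NULL`, simulated from `sim`. The master `seed`
#' deterministically derives per-stage sub-seeds, so each stage is
#' independently reproducible.
#'
#' @param sim A [synthetic_config()] used when no input paths are given.
#' @param matrix_path,sheet_path,qc_path,ct_path Optional input files
#'   (expression TSV, sample sheet TSV, QC TSV, Ct CSV).
#' @param qc_threshold 3'/5' ratio exclusion threshold.
#' @param train_fraction,stratify_by,override_counts Split parameters, see
#'   [stratified_split()].
#' @param n_trees,mtry,drop_fraction,se_rule,top_k Selection parameters,
#'   see [dc_signature()].
#' @param reference_conditions Named vector condition -> class used for
#'   threshold derivation (the known in vitro panel).
#' @param query_conditions Named vector condition -> claimed class to score.
#' @param ct_log2_fc,ct_replicates Planted log2 fold change and replicate
#'   count of the simulated qRT-PCR panel.
#' @param seed Master integer seed.
#' @return A list of class `"dc_config"`.
#' @export
dc_config <- function(sim = synthetic_config(),
                      matrix_path = NULL, sheet_path = NULL,
                      qc_path = NULL, ct_path = NULL,
                      qc_threshold = 3.0,
                      train_fraction = 2 / 3,
                      stratify_by = "class",
                      override_counts = NULL,
                      n_trees = 1000L, mtry = NULL,
                      drop_fraction = 0.2, se_rule = 1.0, top_k = NULL,
                      reference_conditions = c(
                        lps = "inflammatory", polyic = "inflammatory",
                        zymosan = "inflammatory",
                        dexamethasone = "non_inflammatory",
                        il10 = "non_inflammatory",
                        vitamin_d = "non_inflammatory"),
                      query_conditions = c(
                        listeria = "inflammatory",
                        nimesulide = "non_inflammatory"),
                      ct_log2_fc = 3, ct_replicates = 3L,
                      seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "dc_config"
  cfg
}

#' Run the full signature pipeline
#'
#' Executes the analysis end to end: (a) load or simulate the expression
#' compendium; (b) exclude poor-quality samples and z-score the matrix;
#' (c) stratified train/test partition; (d) backward-elimination signature
#' selection on the training set and classification of the held-out test
#' set; (e) qRT-PCR-style validation — fold changes, per-gene thresholds
#' from the reference panel, and a scorecard per query condition. All
#' randomness flows from the master seed through documented per-stage
#' sub-seeds, so re-running the same configuration reproduces the report.
#'
#' @param config A [dc_config()].
#' @return An object of class `"dc_run_report"`: a list with the
#'   configuration echo, per-stage seeds, QC exclusions, split counts, the
#'   fitted [dc_signature()], test-set predictions, confusion counts and
#'   accuracy, fold changes, thresholds and scorecards, plus the matrices
#'   needed to render outputs.
#' @export
run_pipeline <- function(config = dc_config()) {
  stopifnot(inherits(config, "dc_config"))
  seeds <- list(simulate = .derive_seed(config$seed, 101L),
                split = .derive_seed(config$seed, 102L),
                select = .derive_seed(config$seed, 103L),
                ct = .derive_seed(config$seed, 104L))
  warnings <- character()

  # (a) inputs
  if (is.null(config$matrix_path)) {
    sim_cfg <- config$sim
    sim_cfg$seed <- seeds$simulate
    sim <- simulate_expression(sim_cfg)
    mat <- sim$expression; sheet <- sim$sheet; qc <- sim$qc
    truth <- sim$truth
  } else {
    mat <- read_expression_tsv(config$matrix_path)
    sheet <- read_sample_sheet(config$sheet_path)
    qc <- if (is.null(config$qc_path)) NULL else read_qc(config$qc_path)
    truth <- NULL
  }

  # (b) QC + z-score
  if (!is.null(qc)) {
    kept <- qc_filter(mat, qc, config$qc_threshold)
    mat <- kept$matrix
    excluded <- kept$excluded
  } else excluded <- character()
  sheet <- sheet[sheet$sample_id %in% colnames(mat), ]
  z <- withCallingHandlers(
    zscore_transform(mat),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  # (c) partition
  split <- stratified_split(sheet, config$train_fraction,
                            config$stratify_by, seed = seeds$split,
                            override_counts = config$override_counts)
  train_ids <- split$sample_id[split$role == "train"]
  test_ids <- split$sample_id[split$role == "test"]
  classes <- stats::setNames(sheet$class, sheet$sample_id)

  # (d) selection + test classification
  sig <- dc_signature(z[, train_ids, drop = FALSE], classes[train_ids],
                      n_trees = config$n_trees, mtry = config$mtry,
                      drop_fraction = config$drop_fraction,
                      se_rule = config$se_rule, seed = seeds$select,
                      top_k = config$top_k)
  pred <- predict(sig, z[, test_ids, drop = FALSE])
  confusion <- table(truth = classes[test_ids],
                     predicted = factor(pred$class, levels = .class_levels))
  accuracy <- mean(pred$class == classes[test_ids])

  # (e) qRT-PCR-style validation
  directions <- stats::setNames(sig$genes$direction, sig$genes$gene_id)
  all_conditions <- c(config$reference_conditions, config$query_conditions)
  if (is.null(config$ct_path)) {
    ct_truth <- list(signature = data.frame(
      gene_id = sig$genes$gene_id, direction = sig$genes$direction,
      stringsAsFactors = FALSE))
    ct_cfg <- config$sim
    ct_cfg$seed <- seeds$ct
    ct <- simulate_ct_table(ct_cfg, ct_truth, all_conditions,
                            n_replicates = config$ct_replicates,
                            log2_fc = config$ct_log2_fc)
  } else {
    ct <- read_ct(config$ct_path)
    ct <- ct[ct$gene_id %in% c(sig$genes$gene_id,
                               ct$gene_id[ct$condition == attr(ct, "reference")]), ]
  }
  fc <- fold_change(ct)
  thresholds <- derive_thresholds(fc, config$reference_conditions, directions)
  scorecards <- lapply(names(config$query_conditions), function(cond) {
    scorecard(fc, cond, thresholds, config$query_conditions[[cond]])
  })
  names(scorecards) <- names(config$query_conditions)

  structure(list(
    config = config, seeds = seeds,
    qc_excluded = excluded,
    split = split,
    signature = sig,
    test_predictions = pred,
    confusion = confusion,
    test_accuracy = accuracy,
    fold_changes = fc,
    thresholds = thresholds,
    scorecards = scorecards,
    truth = truth,
    matrix = mat, zmatrix = z, sheet = sheet,
    warnings = warnings,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "dc_run_report")
}

#' @export
print.dc_run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat(sprintf("  samples: %d after QC (%d excluded); train %d / test %d\n",
              ncol(x$matrix), length(x$qc_excluded),
              sum(x$split$role == "train"), sum(x$split$role == "test")))
  print(x$signature)
  cat(sprintf("  test accuracy %.3f\n", x$test_accuracy))
  for (sc in x$scorecards) print(sc)
  invisible(x)
}

#' Write the pipeline artifacts to disk
#'
#' Renders the run report into plain-text files: the signature TSV, the
#' elimination-trajectory CSV, the split TSV, PCA score TSV, a heat-map
#' matrix TSV (signature genes as log2 ratio to the gene mean, rows and
#' columns in hierarchical-cluster leaf order), one scorecard TSV per query
#' condition, and a JSON summary of the run.
#'
#' @param report A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named list of written paths.
#' @export
render_outputs <- function(report, outdir) {
  stopifnot(inherits(report, "dc_run_report"))
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop("cannot create output directory: ", outdir)
  paths <- list()

  paths$signature <- file.path(outdir, "signature.tsv")
  write_signature(report$signature, paths$signature)

  paths$trajectory <- file.path(outdir, "selection_trajectory.csv")
  utils::write.csv(report$signature$trajectory, paths$trajectory,
                   quote = FALSE, row.names = FALSE)

  paths$split <- file.path(outdir, "split.tsv")
  write_tsv(report$split, paths$split)

  pca <- pca_scores(report$zmatrix, 2L)
  paths$pca <- file.path(outdir, "pca_scores.tsv")
  write_tsv(data.frame(sample_id = rownames(pca$scores),
                       pc1 = pca$scores[, 1L], pc2 = pca$scores[, 2L],
                       class = report$sheet$class[
                         match(rownames(pca$scores), report$sheet$sample_id)],
                       stringsAsFactors = FALSE), paths$pca)

  hm <- log2_ratio_to_mean(
    report$matrix[report$signature$genes$gene_id, , drop = FALSE])
  hm <- hm[cluster_order(hm, "genes"), cluster_order(hm, "samples")]
  paths$heatmap <- file.path(outdir, "heatmap_matrix.tsv")
  write_expression_tsv(hm, paths$heatmap)

  for (cond in names(report$scorecards)) {
    p <- file.path(outdir, paste0("scorecard_", cond, ".tsv"))
    write_tsv(report$scorecards[[cond]]$genes, p)
    paths[[paste0("scorecard_", cond)]] <- p
  }

  summary_json <- list(
    seed = report$config$seed,
    seeds = report$seeds,
    parameters = list(
      qc_threshold = report$config$qc_threshold,
      train_fraction = report$config$train_fraction,
      n_trees = report$config$n_trees,
      drop_fraction = report$config$drop_fraction,
      se_rule = report$config$se_rule),
    qc_excluded = report$qc_excluded,
    n_train = sum(report$split$role == "train"),
    n_test = sum(report$split$role == "test"),
    signature = report$signature$genes,
    oob_error = report$signature$oob_error,
    confusion = as.data.frame(report$confusion),
    test_accuracy = report$test_accuracy,
    scorecards = lapply(report$scorecards, function(sc) list(
      condition = sc$condition, claimed_class = sc$claimed_class,
      concordance = sc$concordance, class_call = sc$call$class,
      margin = sc$call$margin)),
    warnings = report$warnings,
    timestamp = report$timestamp)
  paths$report <- file.path(outdir, "report.json")
  jsonlite::write_json(summary_json, paths$report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
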