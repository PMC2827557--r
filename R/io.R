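#' Read and write pipeline tables
#'
#' Plain-text readers and writers for every table the pipeline exchanges:
#' the expression matrix TSV (first column `gene_id`, remaining columns
#' sample ids), the sample sheet TSV, the per-sample QC TSV, the qRT-PCR Ct
#' CSV, the split TSV and the signature TSV. All files carry header rows.
#'
#' @param path File path.
#' @name dc_io
NULL

#' @rdname dc_io
#' @param mat Expression matrix, genes x samples.
#' @export
write_expression_tsv <- function(mat, path) {
  .check_matrix(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dc_io
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  .check_matrix(mat)
}

#' @rdname dc_io
#' @param df Data frame to write.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dc_io
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "stimulus", "class")
  if (!all(need %in% names(sheet)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(sheet$class), .class_levels)
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  sheet
}

#' @rdname dc_io
#' @export
read_qc <- function(path) {
  qc <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "actin_ratio", "gapdh_ratio")
  if (!all(need %in% names(qc)))
    stop("QC table needs columns: ", paste(need, collapse = ", "))
  qc
}

#' @rdname dc_io
#' @param reference Reference condition label stored on the returned table.
#' @export
read_ct <- function(path, reference = "untreated") {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(ct, "reference") <- reference
  .check_ct(ct)
}

#' @rdname dc_io
#' @param ct Ct table to write (CSV).
#' @export
write_ct <- function(ct, path) {
  utils::write.csv(ct, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname dc_io
#' @param sig A [dc_signature()] fit or its `genes` data frame.
#' @export
write_signature <- function(sig, path) {
  if (inherits(sig, "dc_signature")) sig <- sig$genes
  write_tsv(sig, path)
}

#' @rdname dc_io
#' @export
read_signature <- function(path) {
  sig <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "direction") %in% names(sig)))
    stop("signature table needs gene_id and direction columns")
  sig
}

#' The reference 54-gene dendritic-cell inflammation signature
#'
#' The curated 54-probe-set signature distributed with the package
#' (MG-U74Av2 identifiers with gene symbols): 36 probe sets up-regulated by
#' inflammatory stimulation and 18 down-regulated. Useful as a fixture for
#' the scoring module and for concordance bookkeeping.
#'
#' @return Data frame (affy_id, symbol, direction).
#' @export
#' @examples
#' table(dc54_signature()$direction)
dc54_signature <- function() {
  path <- system.file("extdata", "dc54_signature.tsv",
                      package = "dcsignature", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
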