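# Tab-separated, UTF-8, mandatory header, "." decimal mark throughout.
# Probe/gene ids are opaque strings.

#' Write / read an expression matrix as TSV
#'
#' First column `probe_id`, one column per sample.
#'
#' @param mat numeric matrix (probes x samples) with dimnames.
#' @param path file path.
#' @return `read_expression` returns the matrix; writers return the path
#'   invisibly.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(probe_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stop("expression file must start with a 'probe_id' column")
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id(s): ",
         paste(head(unique(df$probe_id[duplicated(df$probe_id)]), 5),
               collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity values in ", path)
  rownames(m) <- df$probe_id
  m
}

#' Write / read the sample sheet
#'
#' Columns `sample_id`, `organ`, `genotype`, `condition`, `replicate` with
#' the fixed factor levels leaf/root, tolerant/sensitive, control/drought.
#'
#' @param samples sample sheet data frame.
#' @param path file path.
#' @param matrix_columns optional character vector of expression matrix
#'   column names that the sheet must cover.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path, matrix_columns = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "organ", "genotype", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in sample sheet")
  for (col in c("organ", "genotype", "condition")) {
    levels <- switch(col, organ = .ORGANS, genotype = .GENOTYPES,
                     condition = .CONDITIONS)
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad))
      stop("unknown ", col, " level(s): ", paste(bad, collapse = ", "),
           " (expected ", paste(levels, collapse = "/"), ")")
  }
  if (!is.null(matrix_columns)) {
    uncovered <- setdiff(matrix_columns, df$sample_id)
    if (length(uncovered))
      stop("sample sheet does not describe matrix column(s): ",
           paste(head(uncovered, 5), collapse = ", "))
  }
  df
}

#' Write / read the probe-to-gene map
#'
#' Two columns `probe_id`, `gene_id`; a probe may appear at most once.
#'
#' @param probe_map data frame `probe_id`, `gene_id`.
#' @param path file path.
#' @export
write_probe_map <- function(probe_map, path) {
  write.table(probe_map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_map
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("probe_id", "gene_id"), names(df))
  if (length(miss)) stop("probe map missing column(s): ",
                         paste(miss, collapse = ", "))
  dup <- unique(df$probe_id[duplicated(df$probe_id)])
  if (length(dup))
    stop("mapping error: probe(s) mapped to more than one gene: ",
         paste(head(dup, 5), collapse = ", "))
  df
}

#' Write / read a well-level qPCR table
#'
#' Columns `well`, `amplicon`, `organ`, `genotype`, `condition`,
#' `replicate`, `ct`.
#'
#' @param plate well-level data frame.
#' @param path file path.
#' @export
write_qpcr <- function(plate, path) {
  write.table(plate, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qpcr
#' @export
read_qpcr <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("well", "amplicon", "condition", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("qPCR table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(df$ct) || any(!is.finite(df$ct)))
    stop("non-numeric or non-finite Ct values")
  df
}

#' Write the ground-truth labels of a simulated dataset
#'
#' @param truth truth component of a [simulate_dataset()] result.
#' @param path file path.
#' @export
write_truth_labels <- function(truth, path) {
  write.table(truth$labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits the same TSV formats the pipeline readers accept, plus the
#' truth-labels table.
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if absent).
#' @return named character vector of the files written.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.tsv"),
    probe_map = file.path(dir, "probe_map.tsv"),
    truth = file.path(dir, "truth_labels.tsv"))
  write_expression(ds$raw, paths[["expression"]])
  write_sample_sheet(ds$samples, paths[["samples"]])
  write_probe_map(ds$probe_map, paths[["probe_map"]])
  write_truth_labels(ds$truth, paths[["truth"]])
  paths
}
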