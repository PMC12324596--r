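#' Construct a proteomic RFU matrix
#'
#' The central data container of the package: a samples x analytes matrix of
#' relative fluorescence units (RFU) or normalized intensities, with `NA`
#' marking missing measurements, plus per-sample batch and panel annotations.
#'
#' @param values Numeric matrix, samples in rows, analytes in columns. Row and
#'   column names are used as sample and analyte identifiers; if absent they
#'   are generated. `NA` entries denote missing measurements.
#' @param batch Character or factor vector of per-sample batch/cohort keys
#'   (length `nrow(values)`). Batchwise z-scoring in [normalize_matrix()]
#'   groups on this key. Defaults to a single batch.
#' @param panel Character vector of per-sample assay panel versions (e.g.
#'   "7k", "5k"). Defaults to `"panel1"`.
#'
#' @return An object of class `proteomic_matrix`: a list with elements
#'   `values`, `batch`, `panel`.
#' @examples
#' m <- proteomic_matrix(matrix(runif(20, 100, 1000), 4, 5))
#' dim(m)
#' @export
proteomic_matrix <- function(values,
                             batch = rep("batch1", nrow(values)),
                             panel = rep("panel1", nrow(values))) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(dimnames(values)))
    dimnames(values) <- list(NULL, NULL)
  if (is.null(rownames(values)) && nrow(values) > 0)
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  if (is.null(colnames(values)) && ncol(values) > 0)
    colnames(values) <- paste0("analyte", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("sample identifiers must be unique")
  if (anyDuplicated(colnames(values)))
    stop("analyte identifiers must be unique")
  batch <- as.character(batch)
  panel <- as.character(panel)
  if (length(batch) != nrow(values) || length(panel) != nrow(values))
    stop("'batch' and 'panel' must have one entry per sample")
  structure(list(values = values, batch = batch, panel = panel),
            class = "proteomic_matrix")
}

#' @export
dim.proteomic_matrix <- function(x) dim(x$values)

#' @export
print.proteomic_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("proteomic_matrix: %d samples x %d analytes\n", nrow(v), ncol(v)))
  cat(sprintf("  batches: %s\n", paste(unique(x$batch), collapse = ", ")))
  cat(sprintf("  panels:  %s\n", paste(unique(x$panel), collapse = ", ")))
  cat(sprintf("  missing: %.1f%% of entries\n", 100 * mean(is.na(v))))
  invisible(x)
}

#' Sample identifiers of a proteomic matrix
#' @param m A [proteomic_matrix()].
#' @return Character vector.
#' @export
sample_ids <- function(m) rownames(m$values)

#' Analyte identifiers of a proteomic matrix
#' @param m A [proteomic_matrix()].
#' @return Character vector.
#' @export
analyte_ids <- function(m) colnames(m$values)

#' Subset a proteomic matrix
#'
#' Subsets samples (`i`) and/or analytes (`j`) while keeping the batch and
#' panel annotations congruent with the sample set.
#'
#' @param m A [proteomic_matrix()].
#' @param i Sample indices (integer); default all.
#' @param j Analyte indices (integer); default all.
#' @return A [proteomic_matrix()].
#' @export
pm_subset <- function(m, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(m$values))
  if (is.null(j)) j <- seq_len(ncol(m$values))
  proteomic_matrix(m$values[i, j, drop = FALSE],
                   batch = m$batch[i], panel = m$panel[i])
}

#' Per-analyte and per-sample call rates
#'
#' Call rate is the fraction of non-missing measurements: across samples for
#' an analyte, across analytes for a sample.
#'
#' @param m A [proteomic_matrix()].
#' @return List with numeric vectors `analyte` and `sample`.
#' @export
call_rates <- function(m) {
  ok <- !is.na(m$values)
  list(analyte = colMeans(ok), sample = rowMeans(ok))
}

#' Read / write an RFU matrix as TSV
#'
#' Plain-text interchange: samples in rows (first column `sample_id`),
#' analytes in columns. Batch/panel annotations travel in optional
#' `batch`/`panel` columns.
#'
#' @param path File path.
#' @param m A [proteomic_matrix()] (for writing).
#' @return `read_rfu_tsv` returns a [proteomic_matrix()];
#'   `write_rfu_tsv` returns `path` invisibly.
#' @export
read_rfu_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(df))
  batch <- if ("batch" %in% names(df)) df$batch else rep("batch1", nrow(df))
  panel <- if ("panel" %in% names(df)) df$panel else rep("panel1", nrow(df))
  keep <- setdiff(names(df), c("sample_id", "batch", "panel"))
  v <- as.matrix(df[, keep, drop = FALSE])
  rownames(v) <- df$sample_id
  proteomic_matrix(v, batch = batch, panel = panel)
}

#' @rdname read_rfu_tsv
#' @export
write_rfu_tsv <- function(m, path) {
  df <- data.frame(sample_id = sample_ids(m), batch = m$batch,
                   panel = m$panel, check.names = FALSE)
  df <- cbind(df, as.data.frame(m$values, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
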