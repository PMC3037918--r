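#' Construct an expression dataset
#'
#' Bundles one study's gene-by-sample expression matrix with its
#' per-sample annotations: the disease concept the study addresses, each
#' sample's state (disease or normal) and the tissue of origin.
#'
#' @param dataset_id Dataset identifier.
#' @param matrix Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). At least 2 genes.
#' @param annotations Data frame with one row per column of `matrix`, in
#'   matrix column order, and columns `sample_id`, `disease_concept`,
#'   `state` (each `"disease"` or `"normal"`) and `tissue`.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, matrix, annotations) {
  stopifnot(is.matrix(matrix), is.numeric(matrix), is.data.frame(annotations))
  if (nrow(matrix) < 2L) {
    stop("an expression dataset needs at least 2 genes", call. = FALSE)
  }
  need <- c("sample_id", "disease_concept", "state", "tissue")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) {
    stop("annotations missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(annotations) != ncol(matrix)) {
    stop("annotation rows must match matrix columns", call. = FALSE)
  }
  if (!all(annotations$state %in% c("disease", "normal"))) {
    stop("sample state must be 'disease' or 'normal'", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (!identical(colnames(matrix), as.character(annotations$sample_id))) {
    stop("matrix column names must equal annotations$sample_id in order",
         call. = FALSE)
  }
  structure(list(dataset_id = dataset_id, matrix = matrix,
                 annotations = annotations),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  ann <- x$annotations
  cat(sprintf("Expression dataset '%s': %d genes x %d samples (%d disease, %d normal)\n",
              x$dataset_id, nrow(x$matrix), ncol(x$matrix),
              sum(ann$state == "disease"), sum(ann$state == "normal")))
  cat(sprintf("  disease concept(s): %s\n",
              paste(unique(ann$disease_concept), collapse = ", ")))
  invisible(x)
}

#' Write / read an expression dataset as TSV
#'
#' The on-disk form is a pair of tab-separated files: `<stem>.tsv` holding
#' the matrix (first column `gene`, one column per sample) and
#' `<stem>.samples.tsv` holding the annotation table (`sample_id`,
#' `disease_concept`, `state`, `tissue`).
#'
#' @param dataset An [expression_dataset()].
#' @param stem Path stem (no extension) to write to / read from.
#' @return `write_expression_dataset` invisibly returns the two paths;
#'   `read_expression_dataset` returns the reconstructed
#'   [expression_dataset()].
#' @export
write_expression_dataset <- function(dataset, stem) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mat_path <- paste0(stem, ".tsv")
  ann_path <- paste0(stem, ".samples.tsv")
  df <- data.frame(gene = rownames(dataset$matrix), dataset$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$annotations, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix = mat_path, annotations = ann_path))
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(stem) {
  df <- utils::read.delim(paste0(stem, ".tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  ann <- utils::read.delim(paste0(stem, ".samples.tsv"),
                           stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$gene
  expression_dataset(basename(stem), mat, ann)
}
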