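#' Rank-normalize one sample's expression values
#'
#' Maps a vector of expression values measured in a single sample to
#' normalized ranks on \[0, 1\]: the lowest-expressed gene maps to 0, the
#' highest to 1, and ties receive the average rank. Formally the output is
#' `(r - 1) / (G - 1)` where `r` is the 1-based average rank of each value
#' among the `G` genes of the sample.
#'
#' Normalizing within each sample (rather than within each gene across
#' samples) puts arrays from different platforms and dynamic ranges on a
#' common scale, which is what makes cross-dataset aggregation of the
#' change measure meaningful.
#'
#' @param values Numeric vector of expression values for `G >= 2` genes,
#'   all finite.
#' @return Numeric vector of the same length and order, with values in
#'   \[0, 1\].
#' @examples
#' rank_normalize_sample(c(5, 1, 3))   # 1.0 0.0 0.5
#' rank_normalize_sample(c(2, 2))      # ties -> 0.5 0.5
#' @export
rank_normalize_sample <- function(values) {
  if (!is.numeric(values)) {
    stop("`values` must be numeric", call. = FALSE)
  }
  g <- length(values)
  if (g < 2L) {
    stop("rank normalization needs at least 2 genes per sample", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("non-finite expression value in sample", call. = FALSE)
  }
  (rank(values, ties.method = "average") - 1) / (g - 1)
}

#' Rank-normalized expression change of one gene in one dataset
#'
#' The change measure Delta for a gene is the mean of its rank-normalized
#' expression over the disease samples minus the mean over the normal
#' samples of the same dataset. It is bounded in \[-1, +1\]: +1 means the
#' gene moves from the lowest measured expression in every normal sample
#' to the highest in every disease sample, -1 the reverse, and 0 no shift
#' in within-sample rank.
#'
#' @param dataset An [expression_dataset()].
#' @param gene Gene identifier (must be a row of the matrix; an absent
#'   gene returns `NA_real_`, a "not measured" marker distinct from 0).
#' @param disease Disease-concept label selecting the contrast; disease
#'   samples are those annotated to this concept with state `"disease"`,
#'   normals those with state `"normal"`.
#' @return A single numeric Delta in \[-1, +1\], or `NA_real_` if the gene
#'   is not measured in this dataset.
#' @export
gene_delta <- function(dataset, gene, disease) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!gene %in% rownames(dataset$matrix)) {
    return(NA_real_)
  }
  idx <- contrast_columns(dataset, disease)
  rn <- apply(dataset$matrix, 2L, rank_normalize_sample)
  mean(rn[gene, idx$disease]) - mean(rn[gene, idx$normal])
}

# Column indices of the disease/normal samples for a contrast; errors if
# either group is empty.
contrast_columns <- function(dataset, disease) {
  ann <- dataset$annotations
  dis <- which(ann$disease_concept == disease & ann$state == "disease")
  nrm <- which(ann$disease_concept == disease & ann$state == "normal")
  if (length(dis) == 0L || length(nrm) == 0L) {
    stop(sprintf("dataset '%s' has an empty disease or normal group for '%s'",
                 dataset$dataset_id, disease), call. = FALSE)
  }
  list(disease = dis, normal = nrm)
}

# Per-gene Delta for every gene of one dataset (vectorized form of
# gene_delta; one ranking pass per sample).
dataset_deltas <- function(dataset, disease) {
  idx <- contrast_columns(dataset, disease)
  rn <- apply(dataset$matrix, 2L, rank_normalize_sample)
  if (is.null(dim(rn))) rn <- matrix(rn, nrow = 1L, dimnames = list(rownames(dataset$matrix), NULL))
  delta <- rowMeans(rn[, idx$disease, drop = FALSE]) -
    rowMeans(rn[, idx$normal, drop = FALSE])
  list(delta = delta,
       n_disease = length(idx$disease),
       n_normal = length(idx$normal))
}

#' Aggregate per-gene rank-normalized changes across datasets
#'
#' Computes Delta for every gene in every dataset annotated to `disease`
#' (with both a disease and a normal group) and combines the per-dataset
#' values per gene. The default aggregate is the sample-size-weighted mean
#' of the per-dataset Deltas, the weight being the number of samples the
#' dataset contributes to the contrast; an unweighted mean is available.
#' Genes absent from a dataset's platform simply contribute nothing there
#' — no zero-imputation, which would bias Delta toward 0 for genes on
#' sparse platforms.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param disease Disease-concept label to score.
#' @param weighted If `TRUE` (default) weight each dataset's Delta by its
#'   contrast sample count; if `FALSE` use the plain mean.
#' @return A `gene_delta_table`: a data frame with columns `gene`,
#'   `disease`, `delta`, `n_datasets`, `n_disease_samples`,
#'   `n_normal_samples`, one row per gene measured in at least one
#'   qualifying dataset, sorted by gene identifier. Empty (with a warning)
#'   if no dataset qualifies.
#' @export
aggregate_deltas <- function(datasets, disease, weighted = TRUE) {
  if (inherits(datasets, "expression_dataset")) datasets <- list(datasets)
  per <- list()
  for (ds in datasets) {
    ann <- ds$annotations
    has_both <- any(ann$disease_concept == disease & ann$state == "disease") &&
      any(ann$disease_concept == disease & ann$state == "normal")
    if (!has_both) next
    per[[length(per) + 1L]] <- dataset_deltas(ds, disease)
  }
  if (length(per) == 0L) {
    warning(sprintf("no dataset provides a disease/normal contrast for '%s'",
                    disease), call. = FALSE)
    return(empty_gene_delta_table())
  }
  genes <- sort(unique(unlist(lapply(per, function(p) names(p$delta)))))
  num <- den <- nds <- ndis <- nnrm <- stats::setNames(numeric(length(genes)), genes)
  for (p in per) {
    g <- names(p$delta)
    w <- if (weighted) p$n_disease + p$n_normal else 1
    num[g] <- num[g] + w * p$delta
    den[g] <- den[g] + w
    nds[g] <- nds[g] + 1
    ndis[g] <- ndis[g] + p$n_disease
    nnrm[g] <- nnrm[g] + p$n_normal
  }
  out <- data.frame(
    gene = genes,
    disease = disease,
    delta = unname(num / den),
    n_datasets = as.integer(unname(nds)),
    n_disease_samples = as.integer(unname(ndis)),
    n_normal_samples = as.integer(unname(nnrm)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_delta_table", "data.frame")
  out
}

empty_gene_delta_table <- function() {
  out <- data.frame(
    gene = character(), disease = character(), delta = numeric(),
    n_datasets = integer(), n_disease_samples = integer(),
    n_normal_samples = integer(), stringsAsFactors = FALSE
  )
  class(out) <- c("gene_delta_table", "data.frame")
  out
}

#' Write / read a gene delta table as TSV
#'
#' Columns: `gene`, `disease`, `delta`, `n_datasets`,
#' `n_disease_samples`, `n_normal_samples`.
#'
#' @param deltas A `gene_delta_table` from [aggregate_deltas()].
#' @param path TSV file path.
#' @return `write_gene_delta_table` invisibly returns `path`;
#'   `read_gene_delta_table` returns the `gene_delta_table`.
#' @export
write_gene_delta_table <- function(deltas, path) {
  stopifnot(inherits(deltas, "gene_delta_table"))
  utils::write.table(as.data.frame(deltas), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_delta_table
#' @export
read_gene_delta_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("gene_delta_table", "data.frame")
  out
}

#' @export
print.gene_delta_table <- function(x, ...) {
  cat(sprintf("Gene delta table: %d genes, disease '%s'\n",
              nrow(x), if (nrow(x)) x$disease[1L] else "<none>"))
  if (nrow(x)) {
    ord <- order(-x$delta, x$gene)
    print.data.frame(utils::head(x[ord, , drop = FALSE], 10L), row.names = FALSE)
    if (nrow(x) > 10L) cat(sprintf("... and %d more genes\n", nrow(x) - 10L))
  }
  invisible(x)
}
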