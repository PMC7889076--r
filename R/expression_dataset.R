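#' Expression dataset container
#'
#' One study's gene-by-sample log2 expression matrix together with its
#' per-sample covariates and the covariate-availability mask.
#'
#' @param dataset_id character identifier.
#' @param matrix numeric gene-by-sample matrix (log2 scale) with gene row
#'   names and sample column names.
#' @param covariates data frame with a `sample` column matching the matrix
#'   columns plus any of `sex` (0 female / 1 male), `ga` (weeks), `bw`
#'   (grams), `ppbmi` (ordinal 0-3).
#' @param availability character subset of `c("sex","ga","bw","ppbmi")`
#'   present in `covariates`.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, matrix, covariates,
                               availability = intersect(names(covariates),
                                                        c("sex", "ga", "bw", "ppbmi"))) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("matrix must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(matrix))) stop("expression values must be finite", call. = FALSE)
  if (is.null(rownames(matrix))) stop("matrix needs gene row names", call. = FALSE)
  if (anyDuplicated(rownames(matrix))) {
    stop("duplicate gene identifiers; collapse probes first", call. = FALSE)
  }
  if (nrow(covariates) != ncol(matrix)) {
    stop("covariate rows must match matrix columns", call. = FALSE)
  }
  availability <- as.character(availability)
  if (!all(availability %in% names(covariates))) {
    stop("availability names a covariate absent from the metadata", call. = FALSE)
  }
  structure(list(dataset_id = as.character(dataset_id),
                 genes = rownames(matrix),
                 matrix = matrix,
                 covariates = covariates,
                 availability = availability),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset", x$dataset_id, ":", nrow(x$matrix), "genes x",
      ncol(x$matrix), "samples; covariates:",
      paste(x$availability, collapse = ", "), "\n")
  invisible(x)
}

#' Preprocess a raw expression matrix into an analysis-ready dataset
#'
#' Applies the standard microarray preprocessing used before meta-analysis:
#' quantile normalization across samples followed by `log2(x + 1)` (skipped
#' when the data arrive already normalized), then collapses multiple rows
#' mapping to one gene by keeping the row with the largest mean.
#'
#' @param raw numeric matrix, rows = probes/genes, columns = samples; must be
#'   non-negative when `normalized = FALSE`.
#' @param covariates per-sample covariate data frame (see
#'   [expression_dataset()]).
#' @param dataset_id identifier for the resulting dataset.
#' @param gene_ids character vector mapping rows to gene identifiers;
#'   defaults to `rownames(raw)`. Rows sharing a gene id are collapsed.
#' @param normalized set `TRUE` when the matrix is already quantile
#'   normalized and log-scaled.
#' @param availability covariate-availability mask; defaults to the
#'   perinatal covariates present in `covariates`.
#' @return an [expression_dataset()].
#' @export
preprocess_dataset <- function(raw, covariates, dataset_id,
                               gene_ids = rownames(raw),
                               normalized = FALSE,
                               availability = intersect(names(covariates),
                                                        c("sex", "ga", "bw", "ppbmi"))) {
  if (!is.matrix(raw) || !is.numeric(raw)) stop("raw must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids)) stop("gene identifiers are required", call. = FALSE)
  if (length(gene_ids) != nrow(raw)) stop("gene_ids must match rows", call. = FALSE)
  if (stats::sd(raw) == 0) stop("degenerate expression", call. = FALSE)
  if (!normalized) {
    if (any(raw < 0)) stop("raw intensities must be non-negative", call. = FALSE)
    raw <- limma::normalizeQuantiles(raw)
    raw <- log2(raw + 1)
  }
  # probe -> gene collapse: keep the max-mean row per gene
  means <- rowMeans(raw)
  keep <- unlist(lapply(split(seq_along(gene_ids), gene_ids),
                        function(ix) ix[which.max(means[ix])]),
                 use.names = FALSE)
  keep <- sort(keep)
  mat <- raw[keep, , drop = FALSE]
  rownames(mat) <- gene_ids[keep]
  if (is.null(colnames(mat))) colnames(mat) <- covariates$sample
  expression_dataset(dataset_id, mat, covariates, availability)
}
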