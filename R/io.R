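# Plain TSV writers/readers for the pipeline's on-disk interchange format:
# expression matrices have gene ids in the first column and sample ids as
# the header; tables are written verbatim with a header row.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_matrix_tsv <- function(mat, path, id_col = "gene") {
  d <- data.frame(rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  write_tsv(d, path)
}

read_matrix_tsv <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a simulated study collection to disk
#'
#' Persists every simulated input the pipeline consumes as plain TSV:
#' `expr_<k>.tsv` (genes x samples) and `meta_<k>.tsv` per microarray
#' dataset, `truth.tsv` (planted gene signs), `counts.tsv` and
#' `rnaseq_meta.tsv` for the replication cohort, `cohort.tsv` for the
#' outcome cohort, and a `manifest.yaml` recording files and the generating
#' configuration.
#'
#' @param dir output directory (created if absent).
#' @param collection output of [simulate_microarray_collection()].
#' @param rnaseq output of [simulate_rnaseq_cohort()] (optional).
#' @param cohort output of [simulate_outcome_cohort()] (optional).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(dir, collection, rnaseq = NULL, cohort = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (k in seq_along(collection$datasets)) {
    ds <- collection$datasets[[k]]
    fe <- sprintf("expr_%02d.tsv", k)
    fm <- sprintf("meta_%02d.tsv", k)
    write_matrix_tsv(ds$matrix, file.path(dir, fe))
    write_tsv(ds$covariates, file.path(dir, fm))
    files <- c(files, fe, fm)
  }
  truth <- data.frame(gene = names(collection$truth$signs),
                      sign = as.integer(collection$truth$signs))
  write_tsv(truth, file.path(dir, "truth.tsv"))
  files <- c(files, "truth.tsv")
  if (!is.null(rnaseq)) {
    write_matrix_tsv(rnaseq$counts, file.path(dir, "counts.tsv"))
    write_tsv(rnaseq$covariates, file.path(dir, "rnaseq_meta.tsv"))
    files <- c(files, "counts.tsv", "rnaseq_meta.tsv")
  }
  if (!is.null(cohort)) {
    write_tsv(cohort, file.path(dir, "cohort.tsv"))
    files <- c(files, "cohort.tsv")
  }
  cfg <- collection$truth$config
  manifest <- list(files = as.list(files),
                   config = lapply(unclass(cfg), function(v) {
                     if (is.list(v)) lapply(v, as.character) else v
                   }))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a simulated study collection from disk
#'
#' Inverse of [write_simulation()] for the microarray part: reads every
#' `expr_*.tsv`/`meta_*.tsv` pair back into [expression_dataset()] objects.
#'
#' @param dir directory written by [write_simulation()].
#' @return list of [expression_dataset()] objects.
#' @export
read_expression_collection <- function(dir) {
  fe <- sort(list.files(dir, pattern = "^expr_\\d+\\.tsv$"))
  lapply(fe, function(f) {
    k <- sub("^expr_(\\d+)\\.tsv$", "\\1", f)
    mat <- read_matrix_tsv(file.path(dir, f))
    meta <- read_tsv(file.path(dir, sprintf("meta_%s.tsv", k)))
    expression_dataset(sprintf("sim%s", k), mat, meta)
  })
}
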