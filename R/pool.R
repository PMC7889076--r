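#' Pooled asthma-risk z-score
#'
#' Combines the four univariate meta-analysis z-score vectors into one
#' risk-oriented score per gene:
#' `z_pooled = ((z_male + z_ppbmi) - (z_ga + z_bw)) / 4`.
#' Negative component z's for gestational age and birthweight are
#' protective, so they enter with a minus sign; the denominator stays 4
#' even when components are missing — a gene absent from an analysis
#' contributes a z of zero (and is recorded in `missing_components`), which
#' deliberately shrinks pooled scores for sparsely measured genes.
#'
#' @param sex,ga,bw,ppbmi data frames with columns `gene` and `z` (the
#'   output of [meta_analyze()] works directly); any subset may be `NULL`.
#' @return data frame with columns `gene`, `z_male`, `z_ppbmi`, `z_ga`,
#'   `z_bw`, `n_missing`, `missing_components` (comma-joined names),
#'   `z_pooled`.
#' @examples
#' s <- data.frame(gene = "g1", z = 4)
#' pooled_z(sex = s)  # z_pooled = 1, three missing components
#' @export
pooled_z <- function(sex = NULL, ga = NULL, bw = NULL, ppbmi = NULL) {
  tabs <- list(male = sex, ppbmi = ppbmi, ga = ga, bw = bw)
  supplied <- !vapply(tabs, is.null, logical(1))
  if (!any(supplied)) stop("at least one covariate table is required", call. = FALSE)
  genes <- sort(unique(unlist(lapply(tabs[supplied], `[[`, "gene"))))
  if (length(genes) == 0) stop("empty gene universe", call. = FALSE)
  comp <- matrix(0, length(genes), 4,
                 dimnames = list(genes, c("male", "ppbmi", "ga", "bw")))
  present <- matrix(FALSE, length(genes), 4,
                    dimnames = dimnames(comp))
  for (nm in names(tabs)) {
    t <- tabs[[nm]]
    if (is.null(t)) next
    ix <- match(t$gene, genes)
    z <- t$z
    ok <- is.finite(z)
    comp[ix[ok], nm] <- z[ok]
    present[ix[ok], nm] <- TRUE
  }
  miss <- apply(!present, 1, function(m) paste(colnames(present)[m], collapse = ","))
  data.frame(gene = genes,
             z_male = comp[, "male"], z_ppbmi = comp[, "ppbmi"],
             z_ga = comp[, "ga"], z_bw = comp[, "bw"],
             n_missing = rowSums(!present),
             missing_components = miss,
             z_pooled = ((comp[, "male"] + comp[, "ppbmi"]) -
                           (comp[, "ga"] + comp[, "bw"])) / 4,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Representativeness diagnostics for the pooled score
#'
#' Spearman correlation of each component z-score with (a) the pooled score
#' and (b) the mean of all other components, over a common gene universe.
#' Ties receive average ranks. A constant component yields `NA` with a
#' warning.
#'
#' @param components numeric matrix or data frame (genes x components).
#' @param pooled numeric vector of pooled scores, same gene order.
#' @return data frame with columns `component`, `rho_pooled`, `rho_others`.
#' @export
correlation_diagnostics <- function(components, pooled) {
  components <- as.matrix(components)
  if (ncol(components) < 2) stop("need at least 2 component vectors", call. = FALSE)
  if (nrow(components) != length(pooled)) {
    stop("components and pooled must share the gene universe", call. = FALSE)
  }
  p <- ncol(components)
  rho_pooled <- rho_others <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    x <- components[, j]
    if (stats::sd(x) == 0) {
      warning("component ", colnames(components)[j] %||% j,
              " is constant; correlation undefined")
      next
    }
    rho_pooled[j] <- stats::cor(x, pooled, method = "spearman")
    others <- rowMeans(components[, -j, drop = FALSE])
    if (stats::sd(others) > 0) {
      rho_others[j] <- stats::cor(x, others, method = "spearman")
    }
  }
  data.frame(component = colnames(components) %||% paste0("c", seq_len(p)),
             rho_pooled = rho_pooled, rho_others = rho_others,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
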