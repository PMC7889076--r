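#' Hedges' g standardized mean difference
#'
#' Small-sample-corrected standardized mean difference between two groups,
#' with its large-sample sampling variance:
#' `g = J * (mean1 - mean0) / s_pooled`, `J = 1 - 3/(4 df - 1)` with
#' `df = n1 + n0 - 2`, and
#' `var = (n1 + n0)/(n1 n0) + g^2 / (2 (n1 + n0))`.
#'
#' @param x1,x0 numeric vectors of observations in group 1 (e.g. male) and
#'   group 0.
#' @return list with `effect`, `variance`, `n`.
#' @examples
#' hedges_g(rnorm(10, 1), rnorm(10, 0))
#' @export
hedges_g <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  if (n1 < 2 || n0 < 2 || n1 + n0 < 4) stop("insufficient data", call. = FALSE)
  df <- n1 + n0 - 2
  sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / df
  if (sp2 <= 0) stop("insufficient data", call. = FALSE)
  J <- 1 - 3 / (4 * df - 1)
  g <- J * (mean(x1) - mean(x0)) / sqrt(sp2)
  v <- (n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0))
  list(effect = g, variance = v, n = n1 + n0)
}

#' Fisher z-transformed correlation effect
#'
#' Pearson correlation mapped to Fisher's z (`atanh(r)`) with sampling
#' variance `1/(n - 3)`.
#'
#' @param x covariate vector; `y` expression vector.
#' @param y numeric vector.
#' @return list with `effect`, `variance`, `n`.
#' @export
fisher_z <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 4) stop("insufficient data", call. = FALSE)
  r <- stats::cor(x[ok], y[ok])
  if (!is.finite(r)) stop("insufficient data", call. = FALSE)
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  list(effect = atanh(r), variance = 1 / (n - 3), n = n)
}

#' Per-study standardized effect of a covariate on one gene
#'
#' Binary covariates (sex) give Hedges' g (positive = higher expression in
#' males); continuous or ordinal covariates (ga, bw, ppbmi) give the Fisher
#' z-transformed Pearson correlation (positive = expression increases with
#' the covariate). Risk orientation is applied later, when pooling.
#'
#' @param dataset an [expression_dataset()].
#' @param covariate one of `"sex"`, `"ga"`, `"bw"`, `"ppbmi"`.
#' @param gene a gene identifier, or `NULL` for all genes.
#' @return data frame with columns `dataset_id`, `gene`, `covariate`,
#'   `effect`, `variance`, `n`.
#' @export
study_effect <- function(dataset, covariate, gene = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!covariate %in% dataset$availability) {
    stop("covariate '", covariate, "' not available in dataset ",
         dataset$dataset_id, call. = FALSE)
  }
  x <- dataset$covariates[[covariate]]
  mat <- dataset$matrix
  if (!is.null(gene)) {
    if (!gene %in% rownames(mat)) stop("gene not found", call. = FALSE)
    mat <- mat[gene, , drop = FALSE]
  }
  n <- length(x)
  if (n < 4) stop("insufficient data", call. = FALSE)
  if (stats::sd(x) == 0) stop("insufficient data", call. = FALSE)

  if (covariate == "sex") {
    i1 <- which(x == 1); i0 <- which(x == 0)
    if (length(i1) < 2 || length(i0) < 2) stop("insufficient data", call. = FALSE)
    n1 <- length(i1); n0 <- length(i0)
    df <- n1 + n0 - 2
    m1 <- rowMeans(mat[, i1, drop = FALSE])
    m0 <- rowMeans(mat[, i0, drop = FALSE])
    ss1 <- rowSums((mat[, i1, drop = FALSE] - m1)^2)
    ss0 <- rowSums((mat[, i0, drop = FALSE] - m0)^2)
    sp <- sqrt((ss1 + ss0) / df)
    J <- 1 - 3 / (4 * df - 1)
    g <- J * (m1 - m0) / sp
    v <- (n1 + n0) / (n1 * n0) + g^2 / (2 * (n1 + n0))
    eff <- g; nn <- n1 + n0
  } else {
    r <- as.numeric(stats::cor(x, t(mat)))
    r <- pmax(pmin(r, 1 - 1e-12), -1 + 1e-12)
    eff <- atanh(r)
    v <- rep(1 / (n - 3), length(eff))
    nn <- n
  }
  bad <- !is.finite(eff) | !is.finite(v) | v <= 0
  eff[bad] <- NA_real_; v[bad] <- NA_real_
  data.frame(dataset_id = dataset$dataset_id,
             gene = rownames(mat),
             covariate = covariate,
             effect = eff, variance = v, n = nn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects combination
#'
#' Inverse-variance-weighted random-effects pooling of per-study effects.
#' Fixed-effect weights `w_i = 1/v_i` give `Q = sum w_i (e_i - e_FE)^2`;
#' the DerSimonian-Laird between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`; random weights
#' `w*_i = 1/(v_i + tau2)` give `mu = sum(w* e)/sum(w*)`,
#' `se = 1/sqrt(sum w*)`, `z = mu/se` and a two-sided normal p-value.
#' A single study passes through with `tau2 = 0` and `single_study = TRUE`.
#'
#' @param effects numeric vector of per-study effects.
#' @param variances numeric vector of their sampling variances (all > 0).
#' @return list with `k`, `mu`, `se`, `Q`, `tau2`, `z`, `p`, `single_study`.
#' @examples
#' random_effects_combine(c(0, 1), c(0.1, 0.1))  # Q = 5, tau2 = 0.4, z = 1
#' @export
random_effects_combine <- function(effects, variances) {
  if (length(effects) != length(variances) || length(effects) < 1) {
    stop("effects and variances must be equal-length, non-empty", call. = FALSE)
  }
  if (any(!is.finite(variances)) || any(variances <= 0)) {
    stop("invalid variance", call. = FALSE)
  }
  res <- dl_combine(matrix(effects, nrow = 1), matrix(variances, nrow = 1))
  out <- as.list(res[1, c("k", "mu", "se", "Q", "tau2", "z", "p")])
  out$k <- as.integer(out$k)
  out$single_study <- out$k == 1L
  out
}

# Vectorized DL over genes: E and V are gene-by-study matrices, NA marking
# a gene absent from a study. Rows with k = 1 pass through (tau2 = 0).
dl_combine <- function(E, V) {
  use <- is.finite(E) & is.finite(V)
  W <- ifelse(use, 1 / V, 0)
  k <- rowSums(use)
  sw <- rowSums(W)
  fe <- rowSums(W * ifelse(use, E, 0)) / sw
  Q <- rowSums(W * (ifelse(use, E, fe) - fe)^2)
  cc <- sw - rowSums(W^2) / sw
  tau2 <- ifelse(k > 1, pmax(0, (Q - (k - 1)) / cc), 0)
  Ws <- ifelse(use, 1 / (V + tau2), 0)
  sws <- rowSums(Ws)
  mu <- rowSums(Ws * ifelse(use, E, 0)) / sws
  se <- 1 / sqrt(sws)
  z <- mu / se
  data.frame(k = k, mu = mu, se = se, Q = Q, tau2 = tau2, z = z,
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
}

#' Per-gene random-effects meta-analysis across datasets
#'
#' Computes the study-level standardized effect of `covariate` on every gene
#' in every dataset exposing that covariate, then combines them per gene with
#' the DerSimonian-Laird estimator. Genes present in fewer than two such
#' datasets pass through with `single_study = TRUE` and are excluded from the
#' FDR adjustment; Benjamini-Hochberg q-values are appended over the tested
#' (k >= 2) genes.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param covariate one of `"sex"`, `"ga"`, `"bw"`, `"ppbmi"`.
#' @return data frame with columns `gene`, `covariate`, `k`, `mu`, `se`,
#'   `Q`, `tau2`, `z`, `p`, `q`, `single_study`.
#' @export
meta_analyze <- function(datasets, covariate) {
  has <- vapply(datasets, function(d) covariate %in% d$availability, logical(1))
  if (!any(has)) stop("no dataset exposes covariate '", covariate, "'", call. = FALSE)
  if (sum(has) < 2) stop("need at least 2 datasets exposing '", covariate, "'",
                         call. = FALSE)
  effs <- lapply(datasets[has], study_effect, covariate = covariate)
  genes <- sort(unique(unlist(lapply(effs, `[[`, "gene"))))
  K <- length(effs)
  E <- matrix(NA_real_, length(genes), K, dimnames = list(genes, NULL))
  V <- E
  for (j in seq_len(K)) {
    ix <- match(effs[[j]]$gene, genes)
    E[ix, j] <- effs[[j]]$effect
    V[ix, j] <- effs[[j]]$variance
  }
  res <- dl_combine(E, V)
  res <- cbind(gene = genes, covariate = covariate, res,
               stringsAsFactors = FALSE)
  res$single_study <- res$k < 2
  res$q <- NA_real_
  tested <- which(!res$single_study & is.finite(res$p))
  res$q[tested] <- bh_fdr(res$p[tested])
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving and clipped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
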