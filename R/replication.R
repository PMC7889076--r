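#' Count perinatal risk factors per subject
#'
#' Sums the satisfied risk predicates for each subject. Two named presets
#' are provided: `"perinatal"` (gestational age < 37 weeks, birthweight < 3000 g,
#' maternal pre-pregnancy BMI > 30, male) and `"cesarean"` (gestational age <
#' 37 weeks, male, birthweight < 3000 g, cesarean delivery). All
#' inequalities are strict: a subject at exactly 37 weeks, 3000 g or BMI 30
#' does not accrue that factor.
#'
#' @param covariates data frame with the covariates the active rules
#'   reference (`ga` weeks, `bw` grams, `ppbmi` continuous BMI, `sex`
#'   0 female / 1 male, `csection` 0/1).
#' @param preset `"perinatal"` (default) or `"cesarean"`; ignored when `rules` given.
#' @param rules optional named list of predicate functions, each mapping the
#'   covariate data frame to a logical vector.
#' @return integer vector of per-subject counts in `[0, number of rules]`.
#' @examples
#' count_risk_factors(data.frame(ga = 36, bw = 2900, ppbmi = 31, sex = 1))
#' @export
count_risk_factors <- function(covariates, preset = c("perinatal", "cesarean"),
                               rules = NULL) {
  if (is.null(rules)) {
    preset <- match.arg(preset)
    needed <- switch(preset,
                     perinatal = c("ga", "bw", "ppbmi", "sex"),
                     cesarean = c("ga", "sex", "bw", "csection"))
    missing_cov <- setdiff(needed, names(covariates))
    if (length(missing_cov) > 0) {
      stop("missing covariate(s): ", paste(missing_cov, collapse = ", "),
           call. = FALSE)
    }
    rules <- switch(preset,
      perinatal = list(
        preterm = function(d) d$ga < 37,
        low_bw = function(d) d$bw < 3000,
        obese = function(d) d$ppbmi > 30,
        male = function(d) d$sex == 1
      ),
      cesarean = list(
        preterm = function(d) d$ga < 37,
        male = function(d) d$sex == 1,
        low_bw = function(d) d$bw < 3000,
        csection = function(d) d$csection == 1
      ))
  }
  counts <- integer(nrow(covariates))
  for (nm in names(rules)) {
    fired <- rules[[nm]](covariates)
    if (is.null(fired) || any(is.na(fired)) || length(fired) != nrow(covariates)) {
      stop("risk rule '", nm, "' could not be evaluated: missing covariate",
           call. = FALSE)
    }
    counts <- counts + as.integer(fired)
  }
  counts
}

#' Filter and normalize an RNA-seq count matrix
#'
#' Drops genes whose median count across samples is below 10, then rescales
#' each sample by median sum scaling: every sample's counts are multiplied
#' by `median(per-sample totals) / (that sample's total)`, totals taken over
#' the retained genes.
#'
#' @param counts non-negative integer gene-by-sample matrix.
#' @param min_median median-count filter threshold (default 10).
#' @return list with `normalized` (scaled matrix), `kept` (retained gene
#'   ids) and `size_factors` (per-sample total / median total; the factor a
#'   count model should offset by).
#' @export
filter_and_normalize_counts <- function(counts, min_median = 10) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  med <- apply(counts, 1, stats::median)
  kept <- which(med >= min_median)
  if (length(kept) == 0) stop("no genes pass the median-count filter", call. = FALSE)
  mat <- counts[kept, , drop = FALSE]
  totals <- colSums(mat)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(mat)[totals == 0], collapse = ", "), call. = FALSE)
  }
  sf <- totals / stats::median(totals)
  normalized <- sweep(mat, 2, sf, "/")
  list(normalized = normalized, kept = rownames(counts)[kept],
       size_factors = sf)
}

#' Per-gene negative-binomial risk-count z-scores
#'
#' Models each gene's raw counts as negative binomial with
#' `mean = size_factor * exp(b0 + b1 * risk_count)` and reports the Wald
#' z-statistic for `b1` (positive z = expression rises with the number of
#' risk factors). The dispersion is estimated per gene by maximum
#' likelihood; when the MLE diverges (near-Poisson genes) a
#' method-of-moments dispersion is used instead. Genes that still fail to
#' converge are flagged with missing z.
#'
#' @param counts raw integer gene-by-sample matrix of the retained genes.
#' @param risk integer risk-factor count per sample (non-constant).
#' @param size_factors per-sample size factors (see
#'   [filter_and_normalize_counts()]); default all 1.
#' @return data frame with `gene`, `beta`, `se`, `z`, `p`, `dispersion`,
#'   `converged`.
#' @export
rnaseq_z <- function(counts, risk, size_factors = rep(1, ncol(counts))) {
  n <- ncol(counts)
  if (n < 8) stop("need at least 8 subjects", call. = FALSE)
  if (length(risk) != n) stop("risk length must match samples", call. = FALSE)
  if (stats::sd(risk) == 0) stop("risk counts must vary", call. = FALSE)
  off <- log(size_factors)
  G <- nrow(counts)
  beta <- se <- disp <- rep(NA_real_, G)
  conv <- logical(G)
  for (g in seq_len(G)) {
    y <- counts[g, ]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ risk + offset(off))),
      error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged) && is.finite(fit$theta)) {
      sm <- summary(fit)$coefficients
      beta[g] <- sm["risk", "Estimate"]
      se[g] <- sm["risk", "Std. Error"]
      disp[g] <- 1 / fit$theta
      conv[g] <- TRUE
      next
    }
    # fallback: method-of-moments dispersion from a Poisson fit
    pfit <- tryCatch(
      suppressWarnings(stats::glm(y ~ risk + offset(off), family = stats::poisson())),
      error = function(e) NULL)
    if (is.null(pfit)) next
    mu <- stats::fitted(pfit)
    a <- sum((y - mu)^2 - mu) / sum(mu^2)
    a <- max(a, 1e-8)
    nfit <- tryCatch(
      suppressWarnings(stats::glm(y ~ risk + offset(off),
                                  family = MASS::negative.binomial(theta = 1 / a))),
      error = function(e) NULL)
    if (is.null(nfit) || !nfit$converged) next
    sm <- summary(nfit)$coefficients
    beta[g] <- sm["risk", "Estimate"]
    se[g] <- sm["risk", "Std. Error"]
    disp[g] <- a
    conv[g] <- TRUE
  }
  z <- beta / se
  data.frame(gene = rownames(counts), beta = beta, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), dispersion = disp,
             converged = conv, row.names = NULL, stringsAsFactors = FALSE)
}

#' Replication score against an independent cohort
#'
#' For every gene present in both the pooled meta-analysis and the RNA-seq
#' analysis, the replication score is the product of the two z-scores,
#' `rs = z_pooled * z_rnaseq`: large positive values mark genes whose
#' direction replicates (both risk-increasing or both risk-decreasing).
#' Genes pass at `rs > cutoff` (default 3).
#'
#' @param pooled data frame with `gene` and `z_pooled` (see [pooled_z()]).
#' @param rnaseq data frame with `gene` and `z` (see [rnaseq_z()]).
#' @param cutoff replication-score cutoff (default 3).
#' @param use_ranks when `TRUE`, z-scores are replaced by their
#'   signed midranks (sign * rank of |z| / n) before the product; the
#'   default is the plain product of z-scores.
#' @return data frame with `gene`, `z_pooled`, `z_rnaseq`, `rs`, `passes`.
#' @export
replication_score <- function(pooled, rnaseq, cutoff = 3, use_ranks = FALSE) {
  common <- intersect(pooled$gene, rnaseq$gene)
  if (length(common) == 0) stop("empty gene intersection", call. = FALSE)
  zp <- pooled$z_pooled[match(common, pooled$gene)]
  zr <- rnaseq$z[match(common, rnaseq$gene)]
  if (use_ranks) {
    zp <- sign(zp) * rank(abs(zp)) / length(zp)
    zr <- sign(zr) * rank(abs(zr)) / length(zr)
  }
  rs <- zp * zr
  data.frame(gene = common, z_pooled = zp, z_rnaseq = zr, rs = rs,
             passes = !is.na(rs) & rs > cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sweep the replication-score cutoff
#'
#' For each cutoff, counts the passing genes and reports the median p-value
#' among passers in each source analysis, to show how stringency trades
#' gene count against source-analysis support.
#'
#' @param records output of [replication_score()].
#' @param cutoffs increasing numeric vector of cutoffs.
#' @param source_p optional data frame of per-gene p-values, first column
#'   `gene`, remaining columns one per source analysis.
#' @return data frame with `cutoff`, `n_genes`, and one `median_p_*` column
#'   per source analysis.
#' @export
rs_cutoff_sweep <- function(records, cutoffs, source_p = NULL) {
  if (is.unsorted(cutoffs, strictly = FALSE)) {
    stop("cutoffs must be increasing", call. = FALSE)
  }
  rows <- lapply(cutoffs, function(cc) {
    pass <- records$gene[!is.na(records$rs) & records$rs > cc]
    row <- data.frame(cutoff = cc, n_genes = length(pass))
    if (!is.null(source_p)) {
      for (col in setdiff(names(source_p), "gene")) {
        pv <- source_p[[col]][match(pass, source_p$gene)]
        row[[paste0("median_p_", col)]] <-
          if (length(pass)) stats::median(pv, na.rm = TRUE) else NA_real_
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' Per-subject signature score from replicating genes
#'
#' Standardizes each replicating gene across subjects, extracts the first
#' principal component, and orients it so that positive subject scores
#' represent increased expression of the low-risk genes (those with
#' `z_pooled < 0`). Constant genes are dropped with a warning.
#'
#' @param expr numeric gene-by-subject matrix restricted to replicating
#'   genes (normalized expression).
#' @param z_pooled named vector of pooled z-scores used for orientation
#'   (names = genes).
#' @return data frame with `subject` and `score` (mean-centered); attributes
#'   `variance_explained` (fraction for each component, summing to 1) and
#'   `loadings` (oriented first-eigenvector gene loadings).
#' @export
signature_eigenvalue <- function(expr, z_pooled) {
  if (nrow(expr) < 2) stop("need at least 2 passing genes", call. = FALSE)
  if (ncol(expr) < 3) stop("need at least 3 subjects", call. = FALSE)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene row(s)")
    expr <- expr[sds > 0, , drop = FALSE]
    if (nrow(expr) < 2) stop("need at least 2 passing genes", call. = FALSE)
  }
  zt <- t(scale(t(expr)))          # genes standardized across subjects
  pc <- stats::prcomp(t(zt), center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  loading <- pc$rotation[, 1]
  zlow <- z_pooled[rownames(expr)]
  low <- which(is.finite(zlow) & zlow < 0)
  if (length(low) > 0 && mean(loading[low]) < 0) {
    score <- -score
    loading <- -loading
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  subjects <- colnames(expr) %||% sprintf("s%03d", seq_len(ncol(expr)))
  out <- data.frame(subject = subjects, score = as.numeric(score),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "variance_explained") <- ve
  attr(out, "loadings") <- loading
  out
}

#' Correlate a per-subject quantity with the risk-factor count
#'
#' Pearson (or Spearman) correlation with a Fisher-z 95% confidence
#' interval and Bonferroni-adjusted p-value.
#'
#' @param values numeric per-subject values.
#' @param risk risk-factor counts, same subjects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_tests Bonferroni multiplier (e.g. 21 when screening 21 cell
#'   types); default 1.
#' @return list with `r`, `ci` (length-2), `p`, `p_adjusted`, `n`.
#' @export
correlate_with_risk <- function(values, risk, method = c("pearson", "spearman"),
                                n_tests = 1) {
  method <- match.arg(method)
  ok <- is.finite(values) & is.finite(risk)
  n <- sum(ok)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  if (stats::sd(values[ok]) == 0 || stats::sd(risk[ok]) == 0) {
    return(list(r = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                p_adjusted = NA_real_, n = n))
  }
  ct <- stats::cor.test(values[ok], risk[ok], method = method, exact = FALSE)
  r <- unname(ct$estimate)
  if (method == "pearson" && !is.null(ct$conf.int)) {
    ci <- as.numeric(ct$conf.int)
  } else {
    zz <- atanh(r); hw <- stats::qnorm(0.975) / sqrt(n - 3)
    ci <- tanh(c(zz - hw, zz + hw))
  }
  list(r = r, ci = ci, p = ct$p.value,
       p_adjusted = min(1, ct$p.value * n_tests), n = n)
}

#' Centered log-ratio transform of compositions
#'
#' `clr(x)_i = ln(x_i) - mean_j ln(x_j)` per subject; each transformed row
#' sums to zero. Zero parts are handled by an additive pseudo-count of half
#' the smallest non-zero part (configurable); with pseudo-counting disabled
#' a zero part is an error.
#'
#' @param x numeric matrix (subjects x parts) or vector of positive parts
#'   (percentages or proportions).
#' @param pseudocount `NULL` (default) for half the smallest non-zero part
#'   when zeros are present; a number to use that value; `FALSE` to forbid
#'   zeros.
#' @return matrix (or vector) of CLR values.
#' @examples
#' clr_transform(c(0.5, 0.25, 0.25))
#' @export
clr_transform <- function(x, pseudocount = NULL) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (any(m < 0)) stop("compositions must be non-negative", call. = FALSE)
  if (any(m == 0)) {
    if (isFALSE(pseudocount)) {
      stop("zero part with pseudo-counting disabled", call. = FALSE)
    }
    pc <- if (is.null(pseudocount)) min(m[m > 0]) / 2 else pseudocount
    m <- m + pc
  }
  lm_ <- log(m)
  out <- lm_ - rowMeans(lm_)
  if (vec) as.numeric(out) else out
}
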