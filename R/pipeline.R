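#' Run the full signature-discovery pipeline on simulated cohorts
#'
#' Chains every stage end-to-end on data drawn from one [sim_config()]:
#' simulate the microarray collection, run the four univariate
#' DerSimonian-Laird meta-analyses, pool them into the risk z-score,
#' simulate the RNA-seq replication cohort sharing the same planted truth,
#' filter/normalize its counts, fit the per-gene negative-binomial
#' risk-count models, compute replication scores, and summarise the passing
#' genes as an oriented first-principal-component signature correlated with
#' the risk-factor count.
#'
#' @param config a [sim_config()].
#' @param rs_cutoff replication-score cutoff (default 3).
#' @return list with `truth`, `meta` (named list of the four meta-analysis
#'   tables), `pooled`, `diagnostics`, `rnaseq` (covariates, risk counts,
#'   z table), `replication`, `signature` (per-subject scores or `NULL`
#'   when fewer than 2 genes pass) and `risk_correlation`.
#' @export
run_signature_pipeline <- function(config, rs_cutoff = 3) {
  sim <- simulate_microarray_collection(config)
  meta <- lapply(stats::setNames(nm = c("sex", "ga", "bw", "ppbmi")),
                 function(cv) meta_analyze(sim$datasets, cv))
  pooled <- pooled_z(sex = meta$sex, ga = meta$ga, bw = meta$bw,
                     ppbmi = meta$ppbmi)
  # components enter the diagnostics risk-oriented, as they enter Eq. 1:
  # ga and bw are protective, so their z's flip sign
  comp <- cbind(male = pooled$z_male, ppbmi = pooled$z_ppbmi,
                ga = -pooled$z_ga, bw = -pooled$z_bw)
  diagnostics <- correlation_diagnostics(comp, pooled$z_pooled)

  rc <- simulate_rnaseq_cohort(config, truth = sim$truth)
  norm <- filter_and_normalize_counts(rc$counts)
  zr <- rnaseq_z(rc$counts[norm$kept, , drop = FALSE], rc$risk_count,
                 norm$size_factors)
  repl <- replication_score(pooled, zr, cutoff = rs_cutoff)

  signature <- NULL
  risk_correlation <- NULL
  passers <- repl$gene[repl$passes]
  if (length(passers) >= 2) {
    zp <- stats::setNames(pooled$z_pooled, pooled$gene)
    signature <- signature_eigenvalue(
      norm$normalized[passers, , drop = FALSE], zp)
    risk_correlation <- correlate_with_risk(signature$score, rc$risk_count)
  }
  list(truth = sim$truth, meta = meta, pooled = pooled,
       diagnostics = diagnostics,
       rnaseq = list(covariates = rc$covariates, risk_count = rc$risk_count,
                     z = zr, normalized = norm$normalized,
                     size_factors = norm$size_factors),
       replication = repl, signature = signature,
       risk_correlation = risk_correlation)
}

#' Area under the ROC curve for a score against binary labels
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, with average ranks for
#' ties. Used to quantify recovery of planted signal genes.
#'
#' @param score numeric vector (higher = more positive-like).
#' @param label logical or 0/1 vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("need both classes", call. = FALSE)
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
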