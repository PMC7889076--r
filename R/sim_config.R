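#' Simulation configuration
#'
#' Bundles every tunable of the three cohort simulators:
#' the multi-study microarray collection, the RNA-seq replication cohort and
#' the serum-protein outcome cohort. Defaults reproduce the structure of the
#' study being emulated: 11 microarray datasets of sizes 37, 20, 64, 47, 48,
#' 38, 38, 128, 16, 23 and 146 (605 cord-blood samples in total) with the
#' published per-dataset covariate-availability pattern (sex known in 6
#' datasets totalling 386 samples, gestational age in 7/386, birthweight in
#' 5/235, maternal pre-pregnancy BMI in 4/164), an RNA-seq cohort of 30
#' newborns carrying 0-4 perinatal risk factors, and an outcome cohort of
#' 358 children with two cord-serum proteins, asthma outcomes and
#' FEV1/FVC x 100.
#'
#' @param n_datasets number of microarray datasets.
#' @param dataset_sizes integer vector of per-dataset sample counts
#'   (length `n_datasets`, each >= 4).
#' @param availability_mask list of character vectors, one per dataset; each a
#'   non-empty subset of `c("sex", "ga", "bw", "ppbmi")` naming the covariates
#'   recorded in that dataset's metadata. Covariates outside the mask still
#'   drive expression; they are simply not observed.
#' @param n_genes number of simulated genes.
#' @param n_signal_genes number of genes carrying a planted risk signal
#'   (`<= n_genes`).
#' @param signal_effect standardized effect size per risk factor: the
#'   expression shift, in units of `noise_sd`, per 1 SD of each risk-oriented
#'   covariate (microarray) and the log-fold change per additional risk
#'   factor (RNA-seq).
#' @param noise_sd residual SD of simulated log2 expression.
#' @param rnaseq_n RNA-seq cohort size.
#' @param rnaseq_dispersion negative-binomial dispersion (1/size); 0 gives
#'   Poisson counts.
#' @param outcome_n outcome cohort size.
#' @param protein_log_or true log-odds of asthma per 1 SD of the
#'   outcome-linked protein z-score.
#' @param fevfvc_beta true FEV1/FVC x 100 shift (percentage points) per 1 SD
#'   of the outcome-linked protein z-score.
#' @param seed integer seed; every simulator draw is reproducible from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 200, n_signal_genes = 10)
#' cfg$dataset_sizes
#' @export
sim_config <- function(n_datasets = 11,
                       dataset_sizes = c(37, 20, 64, 47, 48, 38, 38, 128, 16, 23, 146),
                       availability_mask = list(
                         "ppbmi",
                         "sex",
                         c("ga", "bw", "ppbmi"),
                         c("ga", "bw", "ppbmi"),
                         c("ga", "bw"),
                         c("sex", "ga", "bw"),
                         c("sex", "ga", "bw"),
                         c("sex", "ga"),
                         c("sex", "ppbmi"),
                         "ga",
                         "sex"
                       ),
                       n_genes = 2000,
                       n_signal_genes = 50,
                       signal_effect = 0.6,
                       noise_sd = 1,
                       rnaseq_n = 30,
                       rnaseq_dispersion = 0.2,
                       outcome_n = 358,
                       protein_log_or = log(0.5),
                       fevfvc_beta = 1.15,
                       seed = 1L) {
  cfg <- list(
    n_datasets = as.integer(n_datasets),
    dataset_sizes = as.integer(dataset_sizes),
    availability_mask = lapply(availability_mask, as.character),
    n_genes = as.integer(n_genes),
    n_signal_genes = as.integer(n_signal_genes),
    signal_effect = as.numeric(signal_effect),
    noise_sd = as.numeric(noise_sd),
    rnaseq_n = as.integer(rnaseq_n),
    rnaseq_dispersion = as.numeric(rnaseq_dispersion),
    outcome_n = as.integer(outcome_n),
    protein_log_or = as.numeric(protein_log_or),
    fevfvc_beta = as.numeric(fevfvc_beta),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_datasets, cfg$n_genes, cfg$rnaseq_n, cfg$outcome_n)
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (length(cfg$dataset_sizes) != cfg$n_datasets) {
    stop("dataset_sizes length must equal n_datasets", call. = FALSE)
  }
  if (any(cfg$dataset_sizes < 4)) {
    stop("dataset sizes < 4 are rejected: no within-study variance estimate possible",
         call. = FALSE)
  }
  if (length(cfg$availability_mask) != cfg$n_datasets) {
    stop("availability_mask must have one entry per dataset", call. = FALSE)
  }
  known <- c("sex", "ga", "bw", "ppbmi")
  for (m in cfg$availability_mask) {
    if (length(m) == 0) stop("availability_mask entries must be non-empty", call. = FALSE)
    if (!all(m %in% known)) {
      stop("availability_mask entries must be subsets of {sex, ga, bw, ppbmi}",
           call. = FALSE)
    }
  }
  if (cfg$n_signal_genes < 0 || cfg$n_signal_genes > cfg$n_genes) {
    stop("n_signal_genes must lie in [0, n_genes]", call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (cfg$rnaseq_dispersion < 0) stop("rnaseq_dispersion must be >= 0", call. = FALSE)
  if (!is.finite(cfg$seed)) stop("seed must be a finite integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_datasets, "datasets (n =",
      paste(x$dataset_sizes, collapse = ", "), ")\n")
  cat("  genes:", x$n_genes, "with", x$n_signal_genes,
      "signal genes at effect", x$signal_effect, "\n")
  cat("  rnaseq n =", x$rnaseq_n, "; outcome n =", x$outcome_n,
      "; seed =", x$seed, "\n")
  invisible(x)
}
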