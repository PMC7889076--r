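# Risk orientation of the four perinatal covariates: expression moving with
# male sex or higher maternal pre-pregnancy BMI is risk-increasing; moving
# with higher gestational age or birthweight is risk-decreasing. This is the
# sign convention the pooled z-score is built on.
RISK_ORIENTATION <- c(sex = 1, ppbmi = 1, ga = -1, bw = -1)

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

# Perinatal covariates shared by all simulators. Marginals are typical
# obstetric ranges: GA ~ N(39.2, 1.8) weeks truncated to [24, 42],
# birthweight ~ N(3400, 500) g with corr ~0.5 to GA, maternal PP BMI either
# as the ordinal 0-3 coding (<18.5 / 18.5-25 / 25-30 / >=30) or as a
# continuous BMI for cohorts where the >30 risk rule applies.
draw_covariates <- function(n, ppbmi = c("ordinal", "bmi"), ga_bw_cor = 0.5) {
  ppbmi <- match.arg(ppbmi)
  sex <- stats::rbinom(n, 1, 0.5)
  ga <- rnorm_trunc(n, 39.2, 1.8, 24, 42)
  zga <- (ga - 39.2) / 1.8
  bw <- 3400 + 500 * (ga_bw_cor * zga +
                        sqrt(1 - ga_bw_cor^2) * stats::rnorm(n))
  bw <- pmax(bw, 400)
  out <- data.frame(sample = sprintf("s%03d", seq_len(n)),
                    sex = sex, ga = ga, bw = bw,
                    stringsAsFactors = FALSE)
  if (ppbmi == "ordinal") {
    out$ppbmi <- sample(0:3, n, replace = TRUE, prob = c(0.05, 0.50, 0.25, 0.20))
  } else {
    out$ppbmi <- rnorm_trunc(n, 25.5, 5.2, 16, 55)
    out$csection <- stats::rbinom(n, 1, 0.22)
  }
  out
}

#' Simulate a multi-study microarray expression collection
#'
#' Generates `n_datasets` gene-by-sample log2 expression matrices with
#' per-sample perinatal covariates and a planted asthma-risk signature.
#' Signal genes receive a sign `s` in \{-1, +1\}: a `+1` (high-risk) gene
#' increases with male sex and maternal PP BMI and decreases with gestational
#' age and birthweight; a `-1` (low-risk) gene does the opposite. Covariates
#' outside a dataset's availability mask are withheld from its metadata but
#' still drive expression, mirroring the reality that availability is a
#' property of the deposited metadata, not of biology.
#'
#' @param config a [sim_config()].
#' @return A list with elements `datasets` (list of [expression_dataset()])
#'   and `truth` (list with `signal_genes`, per-gene `signs` in \{-1, 0, +1\},
#'   and the generating config).
#' @examples
#' sim <- simulate_microarray_collection(sim_config(n_genes = 100,
#'                                                  n_signal_genes = 5))
#' length(sim$datasets)
#' table(sim$truth$signs)
#' @export
simulate_microarray_collection <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  genes <- sprintf("g%05d", seq_len(G))
  signs <- integer(G)
  signal_idx <- sort(sample.int(G, config$n_signal_genes))
  if (length(signal_idx) > 0) {
    signs[signal_idx] <- sample(rep_len(c(1L, -1L), length(signal_idx)))
  }
  baseline <- stats::rnorm(G, 7, 1)

  datasets <- vector("list", config$n_datasets)
  for (k in seq_len(config$n_datasets)) {
    n <- config$dataset_sizes[k]
    covs <- draw_covariates(n, ppbmi = "ordinal")
    covs$sample <- sprintf("d%02d_s%03d", k, seq_len(n))
    shift <- stats::rnorm(1, 0, 0.3)
    expr <- matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n)
    expr <- expr + baseline + shift
    # planted effects: every covariate drives expression regardless of mask
    for (cv in names(RISK_ORIENTATION)) {
      x <- covs[[cv]]
      if (stats::sd(x) == 0) next
      xs <- as.numeric(scale(x))
      beta <- signs * config$signal_effect * RISK_ORIENTATION[[cv]]
      expr <- expr + outer(beta, xs)
    }
    rownames(expr) <- genes
    colnames(expr) <- covs$sample
    avail <- config$availability_mask[[k]]
    meta <- covs[, c("sample", avail), drop = FALSE]
    datasets[[k]] <- expression_dataset(
      dataset_id = sprintf("sim%02d", k),
      matrix = expr,
      covariates = meta,
      availability = avail
    )
  }
  truth <- list(signal_genes = genes[signal_idx],
                signs = stats::setNames(signs, genes),
                config = config)
  list(datasets = datasets, truth = truth)
}

#' Simulate an RNA-seq replication cohort
#'
#' Generates an integer count matrix for `rnaseq_n` newborns whose per-gene
#' log-mean is linear in the subject's perinatal risk-factor count
#' (gestational age < 37 weeks, birthweight < 3000 g, maternal PP BMI > 30,
#' male), with negative-binomial noise and library sizes varying over a
#' 2-fold range. Signal genes inherit the collection's planted signs: a
#' high-risk (`+1`) gene rises with the risk count at log-slope
#' `signal_effect`, a low-risk gene falls.
#'
#' @param config a [sim_config()].
#' @param truth optional ground truth from
#'   [simulate_microarray_collection()]; when supplied the same genes and
#'   signs are reused so replication can be scored against the pooled
#'   signature. When omitted a fresh truth is drawn.
#' @return list with `counts` (gene-by-sample integer matrix), `covariates`
#'   (data frame with sex, ga, bw, continuous ppbmi), and `truth`.
#' @examples
#' cfg <- sim_config(n_genes = 100, n_signal_genes = 5)
#' rc <- simulate_rnaseq_cohort(cfg)
#' dim(rc$counts)
#' @export
simulate_rnaseq_cohort <- function(config, truth = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  G <- config$n_genes
  if (is.null(truth)) {
    genes <- sprintf("g%05d", seq_len(G))
    signs <- integer(G)
    idx <- sort(sample.int(G, config$n_signal_genes))
    if (length(idx) > 0) signs[idx] <- sample(rep_len(c(1L, -1L), length(idx)))
    truth <- list(signal_genes = genes[idx],
                  signs = stats::setNames(signs, genes),
                  config = config)
  } else {
    genes <- names(truth$signs)
    signs <- as.integer(truth$signs)
    if (length(genes) != G) stop("truth does not match config$n_genes")
  }
  n <- config$rnaseq_n
  covs <- draw_covariates(n, ppbmi = "bmi")
  covs$sample <- sprintf("rs%03d", seq_len(n))
  risk <- count_risk_factors(covs, preset = "perinatal")

  lambda <- stats::rlnorm(G, meanlog = log(150), sdlog = 1.2)
  lib <- 2^stats::runif(n, -0.5, 0.5)
  beta1 <- signs * config$signal_effect
  risk_c <- risk - mean(risk)
  mu <- (lambda * exp(outer(beta1, risk_c))) %*% diag(lib)
  if (config$rnaseq_dispersion > 0) {
    counts <- matrix(stats::rnbinom(G * n, mu = mu,
                                    size = 1 / config$rnaseq_dispersion), G, n)
  } else {
    counts <- matrix(stats::rpois(G * n, lambda = mu), G, n)
  }
  rownames(counts) <- genes
  colnames(counts) <- covs$sample
  list(counts = counts, covariates = covs, risk_count = risk, truth = truth)
}

#' Simulate a birth-cohort outcome table
#'
#' Generates `outcome_n` subjects with two cord-serum protein measurements
#' (one linked to outcomes, one null, correlated r ~ 0.2 on the log scale),
#' perinatal and maternal covariates matching the adjustment models, asthma
#' questionnaire fields (health-professional diagnosis, asthma medication,
#' wheeze) from which the binary outcomes are derived via
#' [define_outcomes()], and continuous FEV1/FVC x 100 and bronchodilator
#' response. Asthma follows a logistic model with log-odds
#' `protein_log_or` per SD of the linked protein; FEV1/FVC shifts by
#' `fevfvc_beta` points per SD.
#'
#' @param config a [sim_config()].
#' @param missing_rate fraction of subjects with missing asthma
#'   questionnaire follow-up (default 0).
#' @return data frame (one row per subject) with raw protein concentrations
#'   (`pglyrp1`, `sil6ra`), covariates, questionnaire fields and outcome
#'   columns `current_asthma_mid`, `ever_asthma`, `fevfvc`, `bdr`. The
#'   generating truth is attached as attribute `"truth"`.
#' @examples
#' coh <- simulate_outcome_cohort(sim_config(outcome_n = 100))
#' mean(coh$current_asthma_mid, na.rm = TRUE)
#' @export
simulate_outcome_cohort <- function(config, missing_rate = 0) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  n <- config$outcome_n
  races <- c("White", "Black", "Hispanic", "Other")
  d <- data.frame(
    subject = sprintf("sub%04d", seq_len(n)),
    ga_weeks = rnorm_trunc(n, 39.4, 1.7, 24, 42),
    bw_ga_sex_z = stats::rnorm(n),
    csection = stats::rbinom(n, 1, 0.22),
    female = stats::rbinom(n, 1, 0.49),
    child_race = sample(races, n, TRUE, prob = c(0.66, 0.14, 0.10, 0.10)),
    maternal_race = sample(races, n, TRUE, prob = c(0.70, 0.12, 0.09, 0.09)),
    ppbmi = rnorm_trunc(n, 24.6, 5.0, 16, 50),
    college_grad = stats::rbinom(n, 1, 0.65),
    atopy = stats::rbinom(n, 1, 0.40),
    antibiotics = stats::rbinom(n, 1, 0.30),
    smoking = sample(c("never", "former", "during"), n, TRUE,
                     prob = c(0.70, 0.19, 0.11)),
    stringsAsFactors = FALSE
  )
  # two proteins, log10-scale latent z's correlated ~0.2
  z1 <- stats::rnorm(n)
  z2 <- 0.2 * z1 + sqrt(1 - 0.2^2) * stats::rnorm(n)
  d$pglyrp1 <- 10^(1.2 + 0.30 * z1)
  d$sil6ra <- 10^(1.5 + 0.25 * z2)

  male <- 1 - d$female
  lp <- stats::qlogis(0.15) + config$protein_log_or * z1 +
    0.35 * d$atopy + 0.25 * male
  asthma <- stats::rbinom(n, 1, stats::plogis(lp))

  # questionnaire fields consistent with the latent outcome: cases always
  # carry a diagnosis plus medication and/or wheeze; a few diagnosed
  # symptom-free children fall outside both the case and comparison
  # definitions and become missing
  diag <- asthma
  med <- integer(n); whz <- integer(n)
  case <- asthma == 1
  med[case] <- stats::rbinom(sum(case), 1, 0.7)
  whz[case] <- ifelse(med[case] == 1, stats::rbinom(sum(case), 1, 0.6), 1L)
  ghost <- which(!case & stats::runif(n) < 0.03)
  diag[ghost] <- 1L
  d$diagnosis_mid <- diag
  d$medication_mid <- med
  d$wheeze_mid <- whz
  d$diagnosis_teen <- as.integer(asthma == 1 | (!case & stats::runif(n) < 0.04))
  if (missing_rate > 0) {
    miss <- which(stats::runif(n) < missing_rate)
    d$diagnosis_mid[miss] <- NA_integer_
    d$medication_mid[miss] <- NA_integer_
    d$wheeze_mid[miss] <- NA_integer_
  }
  d <- cbind(d, define_outcomes(d))

  d$fevfvc <- 85 + config$fevfvc_beta * z1 - 0.8 * male + stats::rnorm(n, 0, 6.5)
  d$bdr <- stats::rnorm(n, 3, 4)

  attr(d, "truth") <- list(
    protein_log_or = config$protein_log_or,
    fevfvc_beta = config$fevfvc_beta,
    protein_z = z1,
    config = config
  )
  d
}
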