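# Covariate sets for the three adjustment models. Model 1 adjusts for the
# child's birth characteristics and demographics, model 2 for the mother's
# demographics, model 3 for both (excluding maternal race/ethnicity).
MODEL_COVARIATES <- list(
  univariate = character(0),
  model1 = c("ga_weeks", "bw_ga_sex_z", "csection", "female", "child_race"),
  model2 = c("ppbmi", "maternal_race", "college_grad", "atopy",
             "antibiotics", "smoking"),
  model3 = c("ga_weeks", "bw_ga_sex_z", "csection", "female", "child_race",
             "ppbmi", "college_grad", "atopy", "antibiotics", "smoking")
)

# Reference levels follow the cohort tables: White for race/ethnicity,
# never-smoker for smoking (vaginal delivery and female = 0 are implicit
# references of the 0/1 codings).
set_reference_levels <- function(d) {
  for (col in intersect(c("child_race", "maternal_race"), names(d))) {
    d[[col]] <- stats::relevel(factor(d[[col]]), ref = "White")
  }
  if ("smoking" %in% names(d)) {
    d$smoking <- stats::relevel(factor(d$smoking), ref = "never")
  }
  d
}

#' Standardize a serum-protein measurement
#'
#' Log10-transforms strictly positive concentrations and converts them to
#' an internal z-score: `z = (log10(x) - mean) / SD` with the sample
#' (n - 1) SD, both computed over non-missing values.
#'
#' @param x positive concentrations; `NA` allowed and propagated.
#' @return numeric z-scores, same length and order as `x`.
#' @examples
#' standardize_protein(c(1, 10, 100))  # -1, 0, 1
#' @export
standardize_protein <- function(x) {
  ok <- !is.na(x)
  if (any(x[ok] <= 0)) stop("concentrations must be positive", call. = FALSE)
  lx <- log10(x)
  s <- stats::sd(lx[ok])
  if (!is.finite(s) || s == 0) stop("zero variance", call. = FALSE)
  (lx - mean(lx[ok])) / s
}

#' Fit a protein-outcome association model
#'
#' Binary outcomes are fit by logistic regression and reported as the odds
#' ratio per 1 SD of the predictor with a Wald 95% CI; continuous outcomes
#' by linear regression with a t-based 95% CI. The adjustment set is chosen
#' by `model`: univariate (none), model 1 (child's birth characteristics
#' and demographics), model 2 (maternal demographics), or model 3 (both,
#' excluding maternal race/ethnicity). Analysis is complete-case over the
#' outcome, predictor and active covariates.
#'
#' @param cohort cohort data frame (see [simulate_outcome_cohort()] for the
#'   expected column names).
#' @param outcome name of the outcome column. Columns holding only
#'   0/1/`NA` are modeled as binary.
#' @param predictor name of the (already standardized) predictor column.
#' @param model one of `"univariate"`, `"model1"`, `"model2"`, `"model3"`.
#' @param covariates optional character vector overriding the model's
#'   adjustment set.
#' @return one-row data frame: `outcome`, `predictor`, `model`, `family`,
#'   `estimate` (OR or slope per 1 SD), `lo`, `hi`, `p`, `n`.
#' @export
fit_outcome_model <- function(cohort, outcome, predictor,
                              model = c("univariate", "model1", "model2", "model3"),
                              covariates = NULL) {
  model <- match.arg(model)
  covs <- covariates %||% MODEL_COVARIATES[[model]]
  used <- c(outcome, predictor, covs)
  missing_cols <- setdiff(used, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- cohort[stats::complete.cases(cohort[, used, drop = FALSE]),
              used, drop = FALSE]
  d <- set_reference_levels(d)
  y <- d[[outcome]]
  binary <- all(y %in% c(0, 1))
  fml <- stats::reformulate(c(predictor, covs), response = outcome)
  if (binary) {
    fit <- stats::glm(fml, data = d, family = stats::binomial())
  } else {
    fit <- stats::lm(fml, data = d)
  }
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("singular design: ", paste(names(cf)[is.na(cf)], collapse = ", "),
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  b <- sm[predictor, "Estimate"]
  se <- sm[predictor, "Std. Error"]
  p <- sm[predictor, 4]
  if (binary) {
    if (se > 10) stop("separation: ", predictor, " (unstable estimate)",
                      call. = FALSE)
    est <- exp(b)
    lo <- exp(b - stats::qnorm(0.975) * se)
    hi <- exp(b + stats::qnorm(0.975) * se)
  } else {
    tcrit <- stats::qt(0.975, df = fit$df.residual)
    est <- b; lo <- b - tcrit * se; hi <- b + tcrit * se
  }
  data.frame(outcome = outcome, predictor = predictor, model = model,
             family = if (binary) "logistic" else "linear",
             estimate = est, lo = lo, hi = hi, p = p, n = nrow(d),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' LMG relative importance for a linear model
#'
#' Decomposes the full-model R-squared over predictors by averaging each
#' predictor's increment to R-squared over all orderings of model entry
#' (the LMG method). Grouped dummies of a factor enter as one block.
#' Shares are non-negative and sum exactly to the full-model R-squared.
#'
#' @param data data frame of complete cases.
#' @param response name of the continuous response column.
#' @param predictors character vector of predictor columns (each column is
#'   one block; factors contribute all their dummies together).
#' @return list with `shares` (named, summing to `r2`), `r2` (full model)
#'   and `n`.
#' @export
relative_importance_linear <- function(data, response, predictors) {
  p <- length(predictors)
  if (p < 2) stop("need at least 2 predictors", call. = FALSE)
  used <- c(response, predictors)
  d <- data[stats::complete.cases(data[, used, drop = FALSE]), used, drop = FALSE]
  d <- set_reference_levels(d)
  if (nrow(d) <= p + 1) stop("too few observations", call. = FALSE)
  if (p > 15) stop("LMG enumeration limited to 15 blocks", call. = FALSE)
  full <- stats::lm(stats::reformulate(predictors, response), data = d)
  if (any(is.na(stats::coef(full)))) stop("collinear design", call. = FALSE)

  # R^2 for every subset of predictor blocks
  nsub <- 2^p
  r2 <- numeric(nsub)
  for (s in seq_len(nsub - 1)) {
    in_s <- which(bitwAnd(s, bitwShiftL(1L, seq_len(p) - 1L)) != 0)
    fit <- stats::lm(stats::reformulate(predictors[in_s], response), data = d)
    r2[s + 1] <- summary(fit)$r.squared
  }
  fact <- factorial(0:p)
  shares <- stats::setNames(numeric(p), predictors)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    others <- setdiff(seq_len(p), j)
    for (s in 0:(2^(p - 1) - 1)) {
      # map subset of "others" to a bitmask over all predictors
      mask <- 0L
      sz <- 0L
      for (i in seq_along(others)) {
        if (bitwAnd(s, bitwShiftL(1L, i - 1L)) != 0) {
          mask <- bitwOr(mask, bitwShiftL(1L, others[i] - 1L))
          sz <- sz + 1L
        }
      }
      wgt <- fact[sz + 1] * fact[p - sz] / fact[p + 1]
      shares[j] <- shares[j] +
        wgt * (r2[bitwOr(mask, bit_j) + 1] - r2[mask + 1])
    }
  }
  list(shares = shares, r2 = summary(full)$r.squared, n = nrow(d))
}

#' McFadden pseudo-R-squared drop-one importance for a logistic model
#'
#' Fits the full logistic model and, for each predictor, the model without
#' it; importance is the drop in McFadden's pseudo-R-squared,
#' `1 - logLik(model) / logLik(intercept-only)`, both on the same
#' complete-case rows.
#'
#' @param data data frame.
#' @param outcome binary outcome column name.
#' @param predictors character vector of predictor columns.
#' @return data frame with `predictor`, `r2_full`, `r2_reduced`, `drop`.
#' @export
relative_importance_logistic <- function(data, outcome, predictors) {
  used <- c(outcome, predictors)
  d <- data[stats::complete.cases(data[, used, drop = FALSE]), used, drop = FALSE]
  d <- set_reference_levels(d)
  full <- stats::glm(stats::reformulate(predictors, outcome), data = d,
                     family = stats::binomial())
  null <- stats::glm(stats::reformulate("1", outcome), data = d,
                     family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(null))
  mcf <- function(fit) 1 - as.numeric(stats::logLik(fit)) / ll0
  r2_full <- mcf(full)
  rows <- lapply(predictors, function(pr) {
    red <- stats::glm(stats::reformulate(setdiff(predictors, pr), outcome),
                      data = d, family = stats::binomial())
    data.frame(predictor = pr, r2_full = r2_full, r2_reduced = mcf(red),
               drop = r2_full - mcf(red), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratified univariate association analysis
#'
#' Splits the cohort by a categorical variable and refits the univariate
#' protein-outcome model within each stratum; strata with fewer than
#' `min_n` subjects with a non-missing outcome are skipped with a warning.
#' Heterogeneity is flagged when any two strata have disjoint 95% CIs.
#'
#' @param cohort cohort data frame.
#' @param outcome,predictor column names (see [fit_outcome_model()]).
#' @param stratifier categorical column to split on.
#' @param min_n minimum per-stratum subjects (default 10).
#' @return data frame of per-stratum results (columns of
#'   [fit_outcome_model()] plus `stratum`), with attribute
#'   `heterogeneity` (logical) and `flagged_pairs`.
#' @export
subset_analysis <- function(cohort, outcome, predictor, stratifier,
                            min_n = 10) {
  s <- cohort[[stratifier]]
  if (is.null(s)) stop("stratifier not found", call. = FALSE)
  if (length(unique(s[!is.na(s)])) < 2) stop("stratifier is constant", call. = FALSE)
  rows <- list()
  for (lev in sort(unique(s[!is.na(s)]))) {
    sub <- cohort[!is.na(s) & s == lev, , drop = FALSE]
    n_ok <- sum(!is.na(sub[[outcome]]))
    if (n_ok < min_n) {
      warning("stratum '", lev, "' skipped (n = ", n_ok, " < ", min_n, ")")
      next
    }
    res <- tryCatch(fit_outcome_model(sub, outcome, predictor, "univariate"),
                    error = function(e) NULL)
    if (is.null(res)) {
      warning("stratum '", lev, "' failed to fit")
      next
    }
    res$stratum <- as.character(lev)
    rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  het <- FALSE; pairs <- character(0)
  if (!is.null(out) && nrow(out) > 1) {
    for (i in seq_len(nrow(out) - 1)) {
      for (j in (i + 1):nrow(out)) {
        if (out$lo[i] > out$hi[j] || out$lo[j] > out$hi[i]) {
          het <- TRUE
          pairs <- c(pairs, paste(out$stratum[i], out$stratum[j], sep = " vs "))
        }
      }
    }
  }
  attr(out, "heterogeneity") <- het
  attr(out, "flagged_pairs") <- pairs
  out
}

yn01 <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    out <- rep(NA_integer_, length(x))
    out[tolower(x) %in% c("yes", "y", "1", "true")] <- 1L
    out[tolower(x) %in% c("no", "n", "0", "false")] <- 0L
    out
  } else {
    as.integer(x)
  }
}

#' Derive asthma outcome columns from questionnaire fields
#'
#' Current asthma = health-professional diagnosis AND (asthma medication in
#' the past 12 months OR wheezing in the past 12 months); the comparison
#' group is no diagnosis, no medication and no wheeze; everyone else is
#' missing. Ever asthma = diagnosis at either follow-up; 0 only when every
#' observed follow-up says no and none is missing.
#'
#' @param fields data frame with columns `diagnosis_mid`, `medication_mid`,
#'   `wheeze_mid` and optionally `diagnosis_teen`, coded 0/1/`NA` or
#'   yes/no/`NA`.
#' @return data frame with `current_asthma_mid` and (when a teen column is
#'   present) `ever_asthma`, coded 0/1/`NA`.
#' @export
define_outcomes <- function(fields) {
  diag <- yn01(fields$diagnosis_mid)
  med <- yn01(fields$medication_mid)
  whz <- yn01(fields$wheeze_mid)
  case <- diag == 1 & (med == 1 | whz == 1)
  comp <- diag == 0 & med == 0 & whz == 0
  cur <- rep(NA_integer_, length(diag))
  cur[which(case)] <- 1L
  cur[which(comp)] <- 0L
  out <- data.frame(current_asthma_mid = cur)
  if ("diagnosis_teen" %in% names(fields)) {
    dt <- yn01(fields$diagnosis_teen)
    ever <- rep(NA_integer_, length(diag))
    ever[which(diag == 1 | dt == 1)] <- 1L
    ever[which(diag == 0 & dt == 0)] <- 0L
    out$ever_asthma <- ever
  }
  out
}
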