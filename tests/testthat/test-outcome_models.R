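test_that("protein standardization is an exact log10 z-score", {
  expect_equal(standardize_protein(c(1, 10, 100)), c(-1, 0, 1))
  set.seed(50)
  x <- rlnorm(40, 2, 0.5)
  z <- standardize_protein(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  xm <- c(x, NA)
  zm <- standardize_protein(xm)
  expect_true(is.na(zm[41]))
  expect_error(standardize_protein(c(1, -2, 3)), "positive")
  expect_error(standardize_protein(rep(7, 5)), "zero variance")
})

test_that("outcome models agree with an independent likelihood maximizer", {
  set.seed(51)
  coh <- simulate_outcome_cohort(sim_config(outcome_n = 200, seed = 51))
  coh$pglyrp1_z <- standardize_protein(coh$pglyrp1)

  # logistic, univariate: compare against direct Newton-free optimization
  fit <- fit_outcome_model(coh, "current_asthma_mid", "pglyrp1_z", "univariate")
  d <- coh[!is.na(coh$current_asthma_mid), ]
  nll <- function(b) {
    eta <- b[1] + b[2] * d$pglyrp1_z
    -sum(d$current_asthma_mid * eta - log1p(exp(eta)))
  }
  ml <- optim(c(0, 0), nll, method = "BFGS", control = list(reltol = 1e-14))$par
  expect_equal(log(fit$estimate), ml[2], tolerance = 1e-6)

  # linear: closed-form least squares
  lf <- fit_outcome_model(coh, "fevfvc", "pglyrp1_z", "univariate")
  bhat <- coef(lm(fevfvc ~ pglyrp1_z, coh))[2]
  expect_equal(lf$estimate, unname(bhat), tolerance = 1e-12)
  expect_true(lf$lo <= lf$estimate && lf$estimate <= lf$hi)

  # duplicating every row keeps the point estimate, shrinks the CI
  dup <- rbind(coh, coh)
  fd <- fit_outcome_model(dup, "fevfvc", "pglyrp1_z", "univariate")
  expect_equal(fd$estimate, lf$estimate, tolerance = 1e-10)
  expect_lt(fd$hi - fd$lo, lf$hi - lf$lo)
})

test_that("model-3 adjustment set excludes maternal race and uses complete cases", {
  coh <- simulate_outcome_cohort(sim_config(outcome_n = 300, seed = 52),
                                 missing_rate = 0.1)
  coh$pglyrp1_z <- standardize_protein(coh$pglyrp1)
  fit <- fit_outcome_model(coh, "current_asthma_mid", "pglyrp1_z", "model3")
  expect_equal(fit$family, "logistic")
  expect_lt(fit$n, 300)                     # missing outcomes excluded
  expect_equal(fit$n, sum(!is.na(coh$current_asthma_mid)))
  expect_error(
    fit_outcome_model(coh, "current_asthma_mid", "pglyrp1_z",
                      covariates = "not_a_column"),
    "lacks column")
  # collinear covariate triggers the singular-design error naming the term
  coh$dup <- coh$ga_weeks
  expect_error(
    fit_outcome_model(coh, "fevfvc", "pglyrp1_z",
                      covariates = c("ga_weeks", "dup")),
    "singular design: dup")
})

test_that("LMG shares: orthogonal case, exact sum, and ordering-average oracle", {
  set.seed(53)
  n <- 120
  # orthogonalized predictors: share equals squared marginal correlation
  x1 <- rnorm(n)
  x2 <- residuals(lm(rnorm(n) ~ x1))
  y <- x1 + 0.5 * x2 + rnorm(n)
  d <- data.frame(y = y, x1 = x1, x2 = x2)
  li <- relative_importance_linear(d, "y", c("x1", "x2"))
  expect_equal(unname(li$shares["x1"]), cor(y, x1)^2, tolerance = 1e-10)
  expect_equal(unname(li$shares["x2"]), cor(y, x2)^2, tolerance = 1e-10)
  expect_equal(sum(li$shares), li$r2, tolerance = 1e-10)

  # correlated predictors incl. a factor block: match the all-orderings oracle
  d2 <- data.frame(x1 = rnorm(n))
  d2$x2 <- 0.6 * d2$x1 + rnorm(n)
  d2$f <- factor(sample(c("u", "v", "w"), n, TRUE))
  d2$y <- d2$x1 - d2$x2 + (d2$f == "v") + rnorm(n)
  preds <- c("x1", "x2", "f")
  li2 <- relative_importance_linear(d2, "y", preds)
  oracle <- lmg_oracle(d2, "y", preds)
  expect_equal(li2$shares, oracle, tolerance = 1e-10)
  expect_true(all(li2$shares >= -1e-12))
  expect_equal(sum(li2$shares), li2$r2, tolerance = 1e-10)

  # exhaustive 4-predictor check
  d3 <- data.frame(matrix(rnorm(n * 4), n))
  names(d3) <- paste0("p", 1:4)
  d3$y <- d3$p1 + 0.5 * d3$p2 + rnorm(n)
  li3 <- relative_importance_linear(d3, "y", paste0("p", 1:4))
  expect_equal(li3$shares, lmg_oracle(d3, "y", paste0("p", 1:4)),
               tolerance = 1e-10)
})

test_that("McFadden drop-one importance respects likelihood nesting", {
  set.seed(54)
  coh <- simulate_outcome_cohort(sim_config(outcome_n = 358, seed = 54))
  coh$pglyrp1_z <- standardize_protein(coh$pglyrp1)
  coh$noise <- rnorm(nrow(coh))
  preds <- c("pglyrp1_z", "atopy", "noise")
  ri <- relative_importance_logistic(coh, "current_asthma_mid", preds)
  expect_true(all(ri$drop >= -1e-12))       # full model never fits worse
  expect_lt(ri$drop[ri$predictor == "noise"], 0.01)
  # the generator's true driver gives the largest drop
  expect_equal(ri$predictor[which.max(ri$drop)], "pglyrp1_z")
})

test_that("subset analysis partitions subjects and flags planted modifiers", {
  set.seed(55)
  coh <- simulate_outcome_cohort(sim_config(outcome_n = 358, seed = 55))
  coh$pglyrp1_z <- standardize_protein(coh$pglyrp1)
  res <- subset_analysis(coh, "fevfvc", "pglyrp1_z", "college_grad")
  expect_equal(sum(res$n), sum(!is.na(coh$fevfvc)))
  # independent stratifier: no disjoint CIs expected
  expect_false(attr(res, "heterogeneity"))
  expect_error(subset_analysis(coh, "fevfvc", "pglyrp1_z",
                               stratifier = "nope"), "not found")
  coh$flat <- 1
  expect_error(subset_analysis(coh, "fevfvc", "pglyrp1_z", "flat"), "constant")
  # planted interaction: opposite slopes by stratum get flagged
  coh2 <- coh
  g <- coh2$atopy == 1
  coh2$fevfvc <- 85 + ifelse(g, 6, -6) * coh2$pglyrp1_z + rnorm(nrow(coh2), 0, 2)
  res2 <- subset_analysis(coh2, "fevfvc", "pglyrp1_z", "atopy")
  expect_true(attr(res2, "heterogeneity"))
  # small strata are skipped with a warning
  coh$rare <- c(rep("big", nrow(coh) - 4), rep("tiny", 4))
  expect_warning(subset_analysis(coh, "fevfvc", "pglyrp1_z", "rare"),
                 "skipped")
})

test_that("asthma outcome definitions follow the questionnaire conjunctions", {
  f <- data.frame(
    diagnosis_mid = c(1, 0, 1, 1, 0, NA, 1),
    medication_mid = c(0, 0, NA, NA, NA, 0, 1),
    wheeze_mid = c(1, 0, NA, 1, 0, 0, 0),
    diagnosis_teen = c(0, 0, NA, 0, 1, 0, NA)
  )
  out <- define_outcomes(f)
  # diagnosis + wheeze -> case; all-no -> comparison; diagnosis with both
  # symptom fields missing -> missing; missing diagnosis -> missing
  expect_equal(out$current_asthma_mid, c(1L, 0L, NA, 1L, NA, NA, 1L))
  # ever: any yes -> 1; no at both -> 0; no + missing -> missing
  expect_equal(out$ever_asthma, c(1L, 0L, 1L, 1L, 1L, NA, 1L))
  # yes/no coding accepted
  f2 <- data.frame(diagnosis_mid = c("yes", "no"),
                   medication_mid = c("no", "no"),
                   wheeze_mid = c("yes", "no"))
  expect_equal(define_outcomes(f2)$current_asthma_mid, c(1L, 0L))
})
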