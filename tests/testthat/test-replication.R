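test_that("risk-factor counting uses strict inequalities at the boundaries", {
  d <- data.frame(ga = c(36, 40, 37.0, 36.9),
                  bw = c(2900, 3500, 3000, 2999),
                  ppbmi = c(31, 22, 30, 30.1),
                  sex = c(1, 0, 0, 1))
  expect_equal(count_risk_factors(d, "perinatal"), c(4L, 0L, 0L, 4L))
  # full boundary grid: boundary values never count
  grid <- expand.grid(ga = c(36.999, 37, 37.001),
                      bw = c(2999, 3000, 3001),
                      ppbmi = c(29.9, 30, 30.1), sex = c(0, 1))
  cnt <- count_risk_factors(grid, "perinatal")
  manual <- with(grid, (ga < 37) + (bw < 3000) + (ppbmi > 30) + (sex == 1))
  expect_equal(cnt, as.integer(manual))

  o <- data.frame(ga = 36, bw = 2900, sex = 1, csection = 1)
  expect_equal(count_risk_factors(o, "cesarean"), 4L)
  expect_error(count_risk_factors(data.frame(ga = 36), "perinatal"),
               "missing covariate")
})

test_that("count filtering and median sum scaling behave as specified", {
  cts <- rbind(low = rep(5L, 4),
               hi1 = c(100L, 200L, 100L, 100L),
               hi2 = c(50L, 100L, 50L, 50L))
  colnames(cts) <- paste0("s", 1:4)
  fn <- filter_and_normalize_counts(cts)
  expect_false("low" %in% fn$kept)
  # sample 2 has double the totals of the others: its size factor is larger
  expect_gt(fn$size_factors[2], fn$size_factors[1])
  # doubling one sample's counts leaves its normalized profile unchanged
  cts2 <- cts; cts2[, 3] <- cts2[, 3] * 2L
  fn2 <- filter_and_normalize_counts(cts2)
  prof <- function(x) x / sum(x)
  expect_equal(prof(fn2$normalized[, 3]), prof(fn$normalized[, 3]))
  # equal totals: normalization is the identity
  eq <- rbind(a = c(60L, 60L), b = c(40L, 40L))
  fneq <- filter_and_normalize_counts(eq)
  expect_equal(fneq$normalized, eq[c("a", "b"), ], ignore_attr = TRUE)
  expect_equal(unname(fneq$size_factors), c(1, 1))

  zz <- rbind(g = c(20L, 0L))
  expect_error(filter_and_normalize_counts(zz), "zero total")
})

test_that("NB risk-count model recovers a known slope and stays null-calibrated", {
  set.seed(40)
  n <- 60
  risk <- sample(0:4, n, TRUE)
  # Poisson-simulated gene with log-slope 0.5
  y <- rpois(n, exp(3 + 0.5 * risk))
  cts <- rbind(sig = y, flat = rpois(n, 50))
  colnames(cts) <- paste0("s", 1:n)
  zt <- rnaseq_z(cts, risk)
  sig <- zt[zt$gene == "sig", ]
  # independent oracle: direct likelihood maximization of the Poisson-limit
  # NB model on the same instance
  nll <- function(b) -sum(dpois(y, exp(b[1] + b[2] * risk), log = TRUE))
  ml <- optim(c(3, 0.4), nll)$par
  expect_lt(abs(sig$beta - ml[2]), 0.02)
  expect_lt(abs(sig$beta - 0.5), 2 * sig$se)
  flat <- zt[zt$gene == "flat", ]
  expect_lt(abs(flat$z), 2)

  # all-null cohort: Wald z's approximately standard normal
  cfg <- sim_config(n_genes = 600, n_signal_genes = 0, signal_effect = 0,
                    rnaseq_n = 40, seed = 41)
  rc <- simulate_rnaseq_cohort(cfg)
  fn <- filter_and_normalize_counts(rc$counts)
  zt2 <- rnaseq_z(rc$counts[fn$kept, ], rc$risk_count, fn$size_factors)
  z <- zt2$z[is.finite(zt2$z)]
  expect_lt(abs(mean(z)), 0.15)
  expect_lt(abs(sd(z) - 1), 0.2)
  expect_error(rnaseq_z(cts[, 1:5], risk[1:5]), "at least 8")
  expect_error(rnaseq_z(cts, rep(1, n)), "must vary")
})

test_that("replication score is the signed product with a strict cutoff", {
  pooled <- data.frame(gene = c("a", "b", "c"), z_pooled = c(2, -2.5, 3))
  rna <- data.frame(gene = c("a", "b", "c", "d"), z = c(2, -1.6, -3, 1))
  rs <- replication_score(pooled, rna, cutoff = 3)
  expect_equal(rs$rs, c(4, 4, -9))
  expect_equal(rs$passes, c(TRUE, TRUE, FALSE))
  # symmetry of the product and nesting of passing sets
  expect_equal(rs$rs, rs$z_rnaseq * rs$z_pooled)
  rs1 <- replication_score(pooled, rna, cutoff = 1)
  expect_true(all(rs$gene[rs$passes] %in% rs1$gene[rs1$passes]))
  expect_error(replication_score(pooled, data.frame(gene = "zz", z = 1), 3),
               "empty")
  # rank variant preserves signs
  rsr <- replication_score(pooled, rna, cutoff = 0, use_ranks = TRUE)
  expect_equal(sign(rsr$rs), sign(rs$rs))
})

test_that("cutoff sweep counts are non-increasing and track source p-values", {
  set.seed(42)
  rec <- data.frame(gene = paste0("g", 1:100),
                    z_pooled = rnorm(100), z_rnaseq = rnorm(100))
  rec$rs <- rec$z_pooled * rec$z_rnaseq
  rec$passes <- rec$rs > 3
  sp <- data.frame(gene = rec$gene, sex = runif(100))
  sw <- rs_cutoff_sweep(rec, c(-Inf, 0, 1, 3), source_p = sp)
  expect_equal(sw$n_genes[1], 100)          # cutoff -Inf: everything passes
  expect_true(all(diff(sw$n_genes) <= 0))
  expect_error(rs_cutoff_sweep(rec, c(3, 1)), "increasing")
})

test_that("signature eigenvalue is oriented, linear and rank-aware", {
  set.seed(43)
  n <- 12
  base <- rnorm(n)
  # perfectly correlated genes: first component explains everything
  expr <- rbind(gA = 2 * base + 1, gB = -3 * base, gC = base + 5)
  zp <- c(gA = -2, gB = 4, gC = -3)       # gA, gC low-risk
  sc <- signature_eigenvalue(expr, zp)
  ve <- attr(sc, "variance_explained")
  expect_equal(ve[1], 1, tolerance = 1e-10)
  expect_equal(sum(ve), 1, tolerance = 1e-12)
  # orientation: low-risk genes (negative pooled z) load positively
  expect_gt(mean(attr(sc, "loadings")[c("gA", "gC")]), 0)
  # scores track base since the low-risk genes rise with base
  expect_gt(cor(sc$score, base), 0.99)
  # flipping every expression value flips every score
  sc2 <- signature_eigenvalue(-expr, zp)
  expect_equal(sc2$score, -sc$score, tolerance = 1e-8)
  expect_warning(signature_eigenvalue(rbind(expr, flat = rep(1, n)), zp),
                 "constant")
  # full reconstruction from all components
  zt <- t(scale(t(expr)))
  pc <- prcomp(t(zt))
  rec <- t(pc$x %*% t(pc$rotation)) + rowMeans(zt)
  expect_equal(as.numeric(rec), as.numeric(zt), tolerance = 1e-8)
})

test_that("risk correlation returns Pearson R, Fisher CI and Bonferroni p", {
  risk <- c(0, 1, 2, 3, 4, 0, 1, 2, 3, 4)
  r1 <- correlate_with_risk(risk, risk)
  expect_equal(r1$r, 1)
  r2 <- correlate_with_risk(-risk, risk)
  expect_equal(r2$r, -1)
  set.seed(44)
  v <- risk + rnorm(10)
  r3 <- correlate_with_risk(v, risk, n_tests = 21)
  expect_equal(r3$p_adjusted, min(1, r3$p * 21))
  expect_true(r3$ci[1] <= r3$r && r3$r <= r3$ci[2])
  r4 <- correlate_with_risk(rep(1, 10), risk)
  expect_true(is.na(r4$r))
})

test_that("CLR transform matches its closed form and sums to zero", {
  expect_equal(clr_transform(c(0.25, 0.25, 0.25, 0.25)), rep(0, 4))
  got <- clr_transform(c(0.5, 0.25, 0.25))
  expect_equal(got, c(0.4621, -0.2310, -0.2310), tolerance = 1e-3)
  set.seed(45)
  comp <- matrix(runif(60, 0.01, 1), 10, 6)
  out <- clr_transform(comp)
  expect_true(all(abs(rowSums(out)) < 1e-12))
  withz <- c(0.5, 0.5, 0)
  expect_error(clr_transform(withz, pseudocount = FALSE), "disabled")
  expect_silent(clr_transform(withz))
})

test_that("end-to-end recovery: passers are planted and the signature tracks risk", {
  res <- run_signature_pipeline(sim_config(seed = 7))
  planted <- res$truth$signal_genes
  pass <- res$replication$gene[res$replication$passes]
  expect_gt(length(pass), 10)
  expect_gte(mean(pass %in% planted), 0.8)
  expect_lte(res$risk_correlation$r, -0.4)
})
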