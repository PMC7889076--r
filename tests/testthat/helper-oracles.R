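# Independent oracles kept deliberately naive: they re-derive the statistics
# from their definitions so the package implementations are checked against
# a second route, not against themselves.

# DerSimonian-Laird combination, scalar formulas straight from the
# definition of the moment estimator.
dl_oracle <- function(e, v) {
  k <- length(e)
  w <- 1 / v
  fe <- sum(w * e) / sum(w)
  Q <- sum(w * (e - fe)^2)
  tau2 <- if (k > 1) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  ws <- 1 / (v + tau2)
  mu <- sum(ws * e) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  list(k = k, mu = mu, se = se, Q = Q, tau2 = tau2, z = mu / se)
}

# Weighted KS enrichment score by exhaustive evaluation of the running sum
# at every position.
es_bruteforce <- function(metric, set, weight_exponent = 1) {
  N <- length(metric)
  hit <- names(metric) %in% set
  m <- sum(hit)
  w <- abs(metric)^weight_exponent
  tot <- sum(w[hit])
  inc <- if (tot == 0) as.numeric(hit) / m else w * hit / tot
  delta <- ifelse(hit, inc, -1 / (N - m))
  run <- vapply(seq_len(N), function(i) sum(delta[seq_len(i)]), numeric(1))
  unname(run[which.max(abs(run))])
}

# LMG by explicit averaging over all orderings of predictor entry.
lmg_oracle <- function(data, response, predictors) {
  p <- length(predictors)
  r2 <- function(v) {
    if (length(v) == 0) return(0)
    summary(lm(reformulate(v, response), data = data))$r.squared
  }
  perms <- gtools_permutations(p)
  shares <- setNames(numeric(p), predictors)
  for (r in seq_len(nrow(perms))) {
    entered <- character(0)
    for (j in perms[r, ]) {
      gain <- r2(c(entered, predictors[j])) - r2(entered)
      shares[j] <- shares[j] + gain
      entered <- c(entered, predictors[j])
    }
  }
  shares / nrow(perms)
}

# all permutations of 1..n (tiny n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# small helper: a quick simulated expression dataset for unit tests
tiny_dataset <- function(n = 20, G = 30, seed = 1, id = "t1") {
  set.seed(seed)
  covs <- data.frame(sample = sprintf("s%02d", 1:n),
                     sex = rbinom(n, 1, 0.5),
                     ga = rnorm(n, 39, 1.5),
                     bw = rnorm(n, 3400, 450),
                     ppbmi = sample(0:3, n, TRUE))
  m <- matrix(rnorm(G * n, 7, 1), G, n,
              dimnames = list(sprintf("g%03d", 1:G), covs$sample))
  expression_dataset(id, m, covs)
}
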