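# Single-marker, burden, SKAT and SKAT-O tests against brute-force oracles.

make_pheno <- function(y, x1, x2) list(y = y, x1 = x1, x2 = x2)

make_gene <- function(G) {
  n <- nrow(G)
  mac <- pmin(colSums(G), 2 * n - colSums(G))
  structure(
    list(
      genotypes = G, macs = mac, mafs = mac / (2 * n),
      site_positions = seq_len(ncol(G))
    ),
    class = "gene_replicate"
  )
}

test_that("smt_fit solves the normal equations on a printed n = 8 fixture", {
  y <- c(1.2, -0.4, 0.8, 2.1, -1.3, 0.5, 1.9, -0.2)
  x1 <- c(1, 0, 1, 1, 0, 0, 1, 0)
  x2 <- c(0.3, -1.1, 0.7, 1.8, -0.6, 0.1, 1.2, -0.9)
  g <- c(0, 0, 1, 2, 0, 0, 1, 0)
  X <- cbind(1, x1, x2, g)
  coef_or <- solve(crossprod(X), crossprod(X, y)) # normal-equations oracle
  resid <- y - X %*% coef_or
  sigma2_or <- sum(resid^2) / 4
  se_or <- sqrt(sigma2_or * solve(crossprod(X))[4, 4])
  fit <- smt_fit(make_pheno(y, x1, x2), g)
  expect_equal(fit$beta_hat, coef_or[4], ignore_attr = TRUE)
  expect_equal(fit$gamma_hat, coef_or[1:3], ignore_attr = TRUE,
    tolerance = 1e-10
  )
  expect_equal(fit$se_hat, se_or)
  expect_identical(fit$df, 4L)
  expect_equal(fit$p_raw, 2 * pt(-abs(fit$beta_hat / se_or), 4))
})

test_that("a noiseless linear trait is recovered exactly", {
  set.seed(11)
  n <- 30
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rnorm(n)
  g <- rbinom(n, 2, 0.3)
  y <- 0.5 * x1 + 0.5 * x2 + 2 * g
  fit <- smt_fit(make_pheno(y, x1, x2), g)
  expect_equal(fit$beta_hat, 2)
  expect_equal(fit$sigma2_hat, 0, tolerance = 1e-20)
})

test_that("collinear genotypes are reported as missing fits", {
  set.seed(12)
  n <- 25
  pheno <- make_pheno(rnorm(n), rbinom(n, 1, 0.5), rnorm(n))
  fit <- smt_fit(pheno, pheno$x1) # duplicate of a covariate
  expect_true(is.na(fit$beta_hat) && is.na(fit$p_raw))
  G <- cbind(pheno$x1, rbinom(n, 2, 0.2))
  tab <- smt_fit_gene(pheno, make_gene(G))
  expect_true(is.na(tab$p_raw[1]) && !is.na(tab$p_raw[2]))
})

test_that("vectorized per-gene fits equal single-SNV fits and lm()", {
  pool <- tiny_pool()
  set.seed(13)
  gene <- rarepower:::sample_gene_replicate(pool, 4000, 80)
  cfg <- scenario_config(0, n = 80, seed = 1)
  pheno <- quick_pheno(gene, cfg, seed = 2)
  tab <- smt_fit_gene(pheno, gene)
  for (j in c(1, 3, ncol(gene$genotypes))) {
    single <- smt_fit(pheno, gene$genotypes[, j])
    expect_equal(tab$beta_hat[j], single$beta_hat)
    expect_equal(tab$se_hat[j], single$se_hat)
    expect_equal(tab$p_raw[j], single$p_raw)
    lmfit <- summary(lm(pheno$y ~ pheno$x1 + pheno$x2 + gene$genotypes[, j]))
    expect_equal(tab$p_raw[j], coef(lmfit)[4, 4])
  }
})

test_that("p-value adjustment reproduces hand step-up computations", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04), "bh"), c(0.03, 0.03, 0.04))
  expect_equal(
    adjust_pvalues(c(0.03, 0.5), "bonferroni"), c(0.06, 1.0)
  )
  expect_equal(adjust_pvalues(0.2, "bh"), 0.2) # k = 1 unchanged
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  p <- c(0.001, 0.5, 0.04, NA, 0.9)
  for (m in c("bh", "bonferroni")) {
    adj <- adjust_pvalues(p, m)
    expect_true(all(adj >= p, na.rm = TRUE)) # adjusted >= raw
    expect_true(is.na(adj[4]))
  }
  expect_error(adjust_pvalues(numeric(0)))
  expect_error(adjust_pvalues(c(0.5, 1.2)))
})

test_that("the minP gene rule rejects iff the smallest adjusted p <= alpha", {
  expect_false(gene_level_smt(c(0.2, 0.6), 0.05))
  expect_true(gene_level_smt(c(0.04, 0.6), 0.05))
  expect_identical(
    gene_level_smt(c(0.6, 0.04), 0.05), gene_level_smt(c(0.04, 0.6), 0.05)
  )
})

test_that("burden test equals SMT for one SNV and is scale invariant", {
  pool <- tiny_pool()
  set.seed(14)
  gene <- rarepower:::sample_gene_replicate(pool, 4000, 80)
  cfg <- scenario_config(0, n = 80, seed = 1)
  pheno <- quick_pheno(gene, cfg, seed = 3)
  g1 <- make_gene(gene$genotypes[, 2, drop = FALSE])
  expect_equal(burden_test(pheno, g1)$p, smt_fit(pheno, g1$genotypes[, 1])$p_raw)
  # duplicating all columns doubles the score but leaves the t-test alone
  gdup <- make_gene(cbind(gene$genotypes, gene$genotypes))
  expect_equal(burden_test(pheno, gdup)$p, burden_test(pheno, gene)$p)
  # normal-equations oracle
  s <- rowSums(gene$genotypes)
  lmfit <- summary(lm(pheno$y ~ pheno$x1 + pheno$x2 + s))
  expect_equal(burden_test(pheno, gene)$p, coef(lmfit)[4, 4])
})

test_that("skat weights follow the Beta(1, 25) density", {
  expect_equal(skat_weights(c(0.1, 0.4, 0.5), a1 = 1, a2 = 1), rep(1, 3))
  expect_equal(skat_weights(0.01), 25 * 0.99^24) # ~19.6557
  w <- skat_weights(c(0.001, 0.01, 0.05, 0.2, 0.5))
  expect_true(all(diff(w) < 0))
  expect_error(skat_weights(0))
})

test_that("SKAT matches a dense explicit-matrix construction", {
  set.seed(42)
  n <- 50
  k <- 3
  G <- matrix(rbinom(n * k, 2, 0.1), n, k)
  pheno <- make_pheno(rnorm(n), rbinom(n, 1, 0.5), rnorm(n))
  gene <- make_gene(G)
  w <- skat_weights(gene$mafs)
  X <- cbind(1, pheno$x1, pheno$x2)
  P <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
  r <- drop(P %*% pheno$y)
  sig2 <- sum(r^2) / n
  Z <- G %*% diag(w)
  Q_or <- drop(t(r) %*% Z %*% t(Z) %*% r) / sig2
  lam_or <- eigen(t(Z) %*% P %*% Z, symmetric = TRUE)$values
  lam_or <- lam_or[lam_or > 1e-10 * max(lam_or)]
  st <- skat_test(pheno, gene)
  expect_equal(st$Q, Q_or)
  expect_equal(sort(st$lambda, decreasing = TRUE), lam_or)
  expect_equal(st$p, quadform_pvalue(Q_or, lam_or)$p, tolerance = 1e-6)
})

test_that("SKAT reduces to the chi-square score test for a single SNV", {
  set.seed(43)
  n <- 120
  g <- rbinom(n, 2, 0.15)
  pheno <- make_pheno(rnorm(n) + 0.3 * g, rbinom(n, 1, 0.5), rnorm(n))
  gene <- make_gene(matrix(g, ncol = 1))
  X <- cbind(1, pheno$x1, pheno$x2)
  P <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
  r <- drop(P %*% pheno$y)
  sig2 <- sum(r^2) / n
  p_or <- pchisq(sum(g * r)^2 / sig2 / drop(t(g) %*% P %*% g), 1,
    lower.tail = FALSE
  )
  expect_equal(skat_test(pheno, gene, weights = 1)$p, p_or, tolerance = 1e-9)
})

test_that("SKAT is invariant to column order and allele relabelling", {
  pool <- tiny_pool()
  set.seed(44)
  gene <- rarepower:::sample_gene_replicate(pool, 4000, 60)
  cfg <- scenario_config(0, n = 60, seed = 1)
  pheno <- quick_pheno(gene, cfg, seed = 4)
  p0 <- skat_test(pheno, gene)$p
  perm <- sample(ncol(gene$genotypes))
  gperm <- make_gene(gene$genotypes[, perm])
  expect_equal(skat_test(pheno, gperm)$p, p0, tolerance = 1e-8)
  # relabel major/minor on one column; make_gene re-orients and MAF-based
  # weights are recomputed, so the test is unchanged
  Gflip <- gene$genotypes
  Gflip[, 1] <- 2L - Gflip[, 1]
  expect_equal(skat_test(pheno, make_gene(Gflip))$p, p0, tolerance = 1e-8)
})

test_that("degenerate SKAT inputs follow the stated conventions", {
  set.seed(45)
  n <- 40
  pheno <- make_pheno(rnorm(n), rbinom(n, 1, 0.5), rnorm(n))
  gene <- make_gene(matrix(rbinom(n * 2, 2, 0.2), n, 2))
  expect_equal(skat_test(pheno, gene, weights = c(0, 0))$Q, 0)
  expect_equal(skat_test(pheno, gene, weights = c(0, 0))$p, 1)
})

test_that("SKAT-O degenerates to SKAT at rho 0 and the burden score at rho 1", {
  pool <- tiny_pool()
  set.seed(46)
  gene <- rarepower:::sample_gene_replicate(pool, 4000, 70)
  cfg <- scenario_config(0, n = 70, seed = 1)
  pheno <- quick_pheno(gene, cfg, seed = 5)
  expect_equal(
    skato_test(pheno, gene, rho_grid = 0)$p, skat_test(pheno, gene)$p,
    tolerance = 1e-8
  )
  # rho = 1: weighted burden score, a scaled chi-square_1
  n <- 70
  X <- cbind(1, pheno$x1, pheno$x2)
  P <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
  r <- drop(P %*% pheno$y)
  sig2 <- sum(r^2) / n
  w <- skat_weights(gene$mafs)
  b <- drop(gene$genotypes %*% w)
  p_or <- pchisq(sum(b * r)^2 / sig2 / drop(t(b) %*% P %*% b), 1,
    lower.tail = FALSE
  )
  expect_equal(skato_test(pheno, gene, rho_grid = 1)$p, p_or, tolerance = 1e-9)
})

# independent R mirror of the SKAT-O construction (same published method,
# separate code path: R eigen + quadform_pvalue + stats::integrate)
skato_mirror <- function(pheno, gene, rho_grid = default_rho_grid()) {
  n <- length(pheno$y)
  X <- cbind(1, pheno$x1, pheno$x2)
  P <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
  r <- drop(P %*% pheno$y)
  sig2 <- sum(r^2) / n
  w <- skat_weights(gene$mafs)
  Z <- gene$genotypes %*% diag(w, ncol(gene$genotypes))
  A <- t(Z) %*% P %*% Z
  u <- drop(t(Z) %*% r)
  k <- ncol(A)
  s <- sum(A)
  bvec <- rowSums(A)
  lt1 <- rho_grid < 1 - 1e-12
  rho <- rho_grid[lt1]
  lams <- list()
  pr <- numeric(length(rho))
  for (ii in seq_along(rho)) {
    a <- sqrt(1 - rho[ii])
    bco <- (sqrt(1 - rho[ii] + k * rho[ii]) - a) / k
    R12 <- a * diag(k) + bco * matrix(1, k, k)
    lam <- eigen(R12 %*% A %*% R12, symmetric = TRUE)$values
    lams[[ii]] <- lam[lam > 1e-10 * max(lam)]
    Qr <- ((1 - rho[ii]) * sum(u^2) + rho[ii] * sum(u)^2) / sig2
    pr[ii] <- quadform_pvalue(Qr, lams[[ii]])$p
  }
  p1 <- if (any(!lt1)) {
    pchisq(sum(u)^2 / sig2 / s, 1, lower.tail = FALSE)
  }
  T <- min(c(pr, p1))
  qmin <- vapply(lams, function(lam) {
    c2 <- sum(lam^2)
    df <- 12 / (12 * sum(lam^4) / c2^2)
    sum(lam) + (qchisq(T, df, lower.tail = FALSE) - df) / sqrt(2 * df) *
      sqrt(2 * c2)
  }, numeric(1))
  tau <- rho * s + (1 - rho) * sum(bvec^2) / s
  lamk <- eigen(A - outer(bvec, bvec) / s, symmetric = TRUE)$values
  lamk <- lamk[lamk > max(1e-10 * max(lamk), 1e-14)]
  xmax <- min(c(69, qmin / tau, if (!is.null(p1)) qchisq(T, 1, lower.tail = FALSE)))
  # substitute x = u^2 to remove the chisq_1 density singularity at 0
  fint <- Vectorize(function(u) {
    cmin <- min((qmin - tau * u^2) / (1 - rho))
    F <- if (cmin <= 0) 0 else 1 - quadform_pvalue(cmin, lamk)$p
    F * sqrt(2 / pi) * exp(-u^2 / 2)
  })
  keep <- stats::integrate(fint, 0, sqrt(xmax),
    rel.tol = 1e-7, subdivisions = 400
  )$value
  max(min(1 - keep, length(rho_grid) * T), T)
}

test_that("SKAT-O matches an independent R mirror of the construction", {
  pool <- tiny_pool()
  cfg <- scenario_config(0, n = 90, seed = 1)
  for (seed in 1:6) {
    set.seed(seed * 31)
    gene <- rarepower:::sample_gene_replicate(pool, 3000, 90)
    pheno <- quick_pheno(gene, cfg, seed = seed)
    res <- skato_test(pheno, gene, acc = 1e-8)
    expect_equal(res$p, skato_mirror(pheno, gene), tolerance = 1e-4)
    # uncorrected minimum is a lower bound; grid multiplicity an upper bound
    expect_gte(res$p, min(res$rho$p) - 1e-10)
    expect_lte(res$p, min(1, 8 * min(res$rho$p)) + 1e-10)
  }
})

test_that("gene_test_all agrees with the individual test functions", {
  pool <- tiny_pool()
  set.seed(47)
  gene <- rarepower:::sample_gene_replicate(pool, 4000, 80)
  cfg <- scenario_config(0, n = 80, seed = 1)
  pheno <- quick_pheno(gene, cfg, seed = 6)
  all_res <- gene_test_all(pheno, gene)
  expect_equal(all_res$burden_p, burden_test(pheno, gene)$p)
  expect_equal(all_res$skat_p, skat_test(pheno, gene, acc = 1e-7)$p,
    tolerance = 1e-6
  )
  expect_equal(
    all_res$smt_min_adj_p[["bh"]],
    min(adjust_pvalues(smt_fit_gene(pheno, gene)$p_raw, "bh"), na.rm = TRUE)
  )
  # rare-only inclusion drops common SNVs from every test identically
  rare_res <- gene_test_all(pheno, gene, inclusion = "rare")
  expect_identical(nrow(rare_res$smt), sum(gene$mafs <= 0.03))
  expect_equal(
    rare_res$burden_p, burden_test(pheno, gene, inclusion = "rare")$p
  )
})
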