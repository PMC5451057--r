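#' Tail probability of a weighted chi-square mixture
#'
#' Computes `P(sum_j lambda_j chisq_1 > q_obs)`, the null tail of
#' variance-component score statistics.  The default `"davies"` route
#' inverts the characteristic function numerically (Imhof's integral,
#' integrated over oscillation periods with adaptive Gauss-Kronrod rules and
#' an alternating-series truncation) for four or more eigenvalues, and uses
#' exact chi-square convolution for one to three; requested absolute
#' accuracy is `acc`.  `"liu"` is the Liu-Tang-Zhang moment-matching
#' surrogate (also the automatic fallback if inversion leaves `[0, 1]`),
#' and `"saddlepoint"` the Kuonen saddlepoint approximation.  Eigenvalues
#' below `1e-10 * max(lambdas)` are truncated for numerical stability.
#'
#' @param q_obs observed statistic, `>= 0`.
#' @param lambdas eigenvalue weights of the mixture (at least one positive).
#' @param method `"davies"`, `"liu"` or `"saddlepoint"`.
#' @param acc absolute accuracy target for the davies route.
#' @return List with `p` (upper-tail probability) and `method_used`
#'   (`"liu"` if the davies route fell back).
#' @examples
#' quadform_pvalue(qchisq(0.95, 2), c(1, 1))$p # 0.05
#' @export
quadform_pvalue <- function(q_obs, lambdas,
                            method = c("davies", "liu", "saddlepoint"),
                            acc = 1e-9) {
  method <- match.arg(method)
  stopifnot(q_obs >= 0, length(lambdas) >= 1, all(is.finite(lambdas)))
  if (!any(lambdas > 0)) stop("at least one positive eigenvalue required")
  .qf_tail_cpp(q_obs, as.numeric(lambdas), method, acc)
}

#' Beta-density MAF weights for SKAT-type kernels
#'
#' The linear weighted kernel weights each SNV by the Beta(`a1`, `a2`)
#' density evaluated at its MAF; the default (1, 25) up-weights rare
#' variants steeply and is the conventional default of the SKAT family.
#'
#' @param mafs minor allele frequencies in `(0, 0.5]`.
#' @param a1,a2 Beta shape parameters.
#' @return Numeric weight vector.
#' @examples
#' skat_weights(c(0.0005, 0.01, 0.3))
#' @export
skat_weights <- function(mafs, a1 = 1, a2 = 25) {
  stopifnot(all(mafs > 0), all(mafs <= 0.5))
  dbeta(mafs, a1, a2)
}

#' Default mixing grid for SKAT-O
#'
#' Eight values `rho = (0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1)`
#' interpolating between SKAT (`rho = 0`) and the weighted burden score
#' test (`rho = 1`).
#'
#' @return Numeric vector of length 8.
#' @export
default_rho_grid <- function() c(0, 0.1^2, 0.2^2, 0.3^2, 0.4^2, 0.5^2, 0.5, 1)

# design matrix of the covariate-only null model
null_design <- function(pheno) {
  cbind(1, pheno$x1, pheno$x2)
}

# restrict a gene to an inclusion mode ("all" SNVs or "rare" only)
filter_inclusion <- function(gene, inclusion = c("all", "rare"),
                             rare_threshold = 0.03) {
  inclusion <- match.arg(inclusion)
  if (inclusion == "all") {
    return(gene)
  }
  keep <- which(gene$mafs <= rare_threshold)
  if (!length(keep)) {
    return(NULL)
  }
  structure(
    list(
      genotypes = gene$genotypes[, keep, drop = FALSE],
      macs = gene$macs[keep], mafs = gene$mafs[keep],
      site_positions = gene$site_positions[keep]
    ),
    class = "gene_replicate"
  )
}

#' Single-marker Wald t-test for one SNV
#'
#' Fits `Y = gamma0 + gamma1 x1 + gamma2 x2 + beta g + eps` by ordinary
#' least squares and tests `beta = 0` with the Wald-type t statistic
#' `beta_hat / SE(beta_hat) ~ t_{n-4}`, using the unbiased residual-variance
#' estimate (divisor n - 4).
#'
#' @param pheno a `phenotype_set`.
#' @param g one genotype column (minor allele counts).
#' @return A `single_marker_fit` list: `beta_hat`, `se_hat`, `t_stat`,
#'   `df`, `p_raw`, `gamma_hat` (intercept and covariate coefficients) and
#'   `sigma2_hat`.  Collinear genotype columns yield `NA` estimates.
#' @export
smt_fit <- function(pheno, g) {
  n <- length(pheno$y)
  stopifnot(n > 4, length(g) == n)
  X <- cbind(`(Intercept)` = 1, x1 = pheno$x1, x2 = pheno$x2, g = g)
  fit <- lm.fit(X, pheno$y)
  df <- n - 4L
  if (fit$rank < 4L) {
    out <- list(
      beta_hat = NA_real_, se_hat = NA_real_, t_stat = NA_real_,
      df = df, p_raw = NA_real_, gamma_hat = fit$coefficients[1:3],
      sigma2_hat = NA_real_
    )
    return(structure(out, class = "single_marker_fit"))
  }
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtXinv[4, 4])
  beta <- fit$coefficients[["g"]]
  t_stat <- beta / se
  structure(
    list(
      beta_hat = beta, se_hat = se, t_stat = t_stat, df = df,
      p_raw = 2 * pt(-abs(t_stat), df),
      gamma_hat = fit$coefficients[1:3], sigma2_hat = sigma2
    ),
    class = "single_marker_fit"
  )
}

#' Single-marker tests for every SNV in a gene
#'
#' Vectorized version of [smt_fit()] over all (included) genotype columns,
#' plus multiplicity-adjusted p-values.
#'
#' @param pheno a `phenotype_set`.
#' @param gene a `gene_replicate`.
#' @param inclusion `"all"` SNVs or `"rare"` only (MAF <= `rare_threshold`).
#' @param rare_threshold MAF cutoff for the rare-only mode.
#' @param adjust correction methods to attach (`"bh"`, `"bonferroni"`).
#' @return Data frame with one row per tested SNV: `site`, `maf`,
#'   `beta_hat`, `se_hat`, `t_stat`, `p_raw`, and a `p_<method>` column per
#'   requested correction.
#' @export
smt_fit_gene <- function(pheno, gene, inclusion = "all", rare_threshold = 0.03,
                         adjust = c("bh", "bonferroni")) {
  gene <- filter_inclusion(gene, inclusion, rare_threshold)
  if (is.null(gene)) stop("no SNV left after inclusion filtering")
  res <- .gene_tests_cpp(
    pheno$y, null_design(pheno), gene$genotypes * 1.0,
    rep(1, ncol(gene$genotypes)), default_rho_grid(),
    TRUE, FALSE, FALSE, FALSE, 1e-9
  )
  out <- cbind(
    data.frame(site = gene$site_positions, maf = gene$mafs),
    res$smt
  )
  for (m in adjust) {
    out[[paste0("p_", m)]] <- adjust_pvalues(out$p_raw, m)
  }
  out
}

#' Multiplicity adjustment of per-SNV p-values
#'
#' Bonferroni (`min(1, k p)`) or Benjamini-Hochberg step-up adjusted
#' values, order-preserving and capped at 1.  `NA` entries (degenerate
#' fits) are ignored for the effective number of tests and propagated.
#'
#' @param p_raw raw p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values in input order.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.04), "bh")
#' @export
adjust_pvalues <- function(p_raw, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (!length(p_raw)) stop("empty p-value vector")
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p_raw))
  ok <- !is.na(p_raw)
  out[ok] <- p.adjust(p_raw[ok], method = if (method == "bh") "BH" else "bonferroni")
  out
}

#' Gene-level minP decision for single-marker tests
#'
#' A gene is declared significant when its smallest multiplicity-adjusted
#' per-SNV p-value is at most `alpha`.
#'
#' @param p_adj adjusted p-values of all tested SNVs in the gene.
#' @param alpha nominal level.
#' @return Logical rejection indicator.
#' @export
gene_level_smt <- function(p_adj, alpha) {
  stopifnot(any(!is.na(p_adj)))
  min(p_adj, na.rm = TRUE) <= alpha
}

#' Unweighted burden test
#'
#' Regresses the trait on the per-individual sum of minor alleles across
#' the gene's (included) SNVs, adjusting for the covariates, and reports
#' the Wald t-test (df n - 4) of the score coefficient.
#'
#' @inheritParams smt_fit_gene
#' @return List with `beta_hat`, `se_hat`, `t_stat`, `p`; `NA`s if the
#'   gene score is constant.
#' @export
burden_test <- function(pheno, gene, inclusion = "all", rare_threshold = 0.03) {
  gene <- filter_inclusion(gene, inclusion, rare_threshold)
  if (is.null(gene)) stop("no SNV left after inclusion filtering")
  res <- .gene_tests_cpp(
    pheno$y, null_design(pheno), gene$genotypes * 1.0,
    rep(1, ncol(gene$genotypes)), default_rho_grid(),
    FALSE, TRUE, FALSE, FALSE, 1e-9
  )
  res$burden
}

#' SKAT: variance-component score test with the linear weighted kernel
#'
#' Computes `Q = ||W G' r||^2 / sigma2_hat` with `r` the covariate-only
#' residuals, `W = diag(weights)` and `sigma2_hat` the maximum-likelihood
#' residual variance of the null model; the null distribution is the
#' chi-square mixture with eigenvalue weights from `W G' P G W` (`P` the
#' residual projection of the null design), evaluated with
#' [quadform_pvalue()].
#'
#' @inheritParams smt_fit_gene
#' @param weights per-SNV kernel weights; default [skat_weights()] on the
#'   included SNVs' MAFs.
#' @param method tail method passed to the mixture kernel.
#' @param acc absolute accuracy of the davies route.
#' @return List with `p`, the statistic `Q`, and the mixture `lambda`s.
#' @export
skat_test <- function(pheno, gene, weights = NULL, inclusion = "all",
                      rare_threshold = 0.03, method = "davies", acc = 1e-9) {
  gene <- filter_inclusion(gene, inclusion, rare_threshold)
  if (is.null(gene)) stop("no SNV left after inclusion filtering")
  if (is.null(weights)) weights <- skat_weights(gene$mafs)
  stopifnot(length(weights) == ncol(gene$genotypes), all(weights >= 0))
  res <- .gene_tests_cpp(
    pheno$y, null_design(pheno), gene$genotypes * 1.0,
    as.numeric(weights), default_rho_grid(),
    FALSE, FALSE, TRUE, FALSE, acc
  )
  if (method != "davies" && length(res$skat$lambda)) {
    res$skat$p <- quadform_pvalue(res$skat$Q, res$skat$lambda, method, acc)$p
  }
  res$skat
}

#' SKAT-O: optimal combination of SKAT and a weighted burden score test
#'
#' For every mixing value `rho` in the grid the statistic
#' `Q_rho = (1 - rho) Q_SKAT + rho Q_burden-type` is referred to its exact
#' chi-square-mixture null; the minimum p-value over the grid is then
#' corrected for the grid search through the one-dimensional integral over
#' the shared burden-direction chi-square_1 component (exact in the
#' Gaussian linear model, where the orthogonal "kappa" part is independent
#' of the burden direction).
#'
#' @inheritParams skat_test
#' @param rho_grid mixing grid, defaults to [default_rho_grid()].
#' @return List with the combined `p` and a per-`rho` data frame
#'   (`rho`, `Q`, `p`).
#' @export
skato_test <- function(pheno, gene, weights = NULL,
                       rho_grid = default_rho_grid(), inclusion = "all",
                       rare_threshold = 0.03, acc = 1e-9) {
  gene <- filter_inclusion(gene, inclusion, rare_threshold)
  if (is.null(gene)) stop("no SNV left after inclusion filtering")
  if (is.null(weights)) weights <- skat_weights(gene$mafs)
  stopifnot(
    length(weights) == ncol(gene$genotypes), all(weights >= 0),
    all(rho_grid >= 0), all(rho_grid <= 1)
  )
  res <- .gene_tests_cpp(
    pheno$y, null_design(pheno), gene$genotypes * 1.0,
    as.numeric(weights), as.numeric(rho_grid),
    FALSE, FALSE, FALSE, TRUE, acc
  )
  out <- res$skato
  out$rho <- res$skato_rho
  out
}

#' All four tests on one gene replicate
#'
#' Convenience wrapper running the single-marker tests (with BH and
#' Bonferroni minP summaries), the burden test, SKAT and SKAT-O in one
#' pass.
#'
#' @inheritParams skat_test
#' @param rho_grid SKAT-O mixing grid.
#' @return A `gene_test_result` list: per-SNV table `smt`, gene-level
#'   `smt_min_adj_p` (named by correction), `burden_p`, `skat_p`,
#'   `skato_p`, and the `inclusion` mode.
#' @export
gene_test_all <- function(pheno, gene, weights = NULL,
                          rho_grid = default_rho_grid(), inclusion = "all",
                          rare_threshold = 0.03, acc = 1e-7) {
  genef <- filter_inclusion(gene, inclusion, rare_threshold)
  if (is.null(genef)) stop("no SNV left after inclusion filtering")
  if (is.null(weights)) weights <- skat_weights(genef$mafs)
  res <- .gene_tests_cpp(
    pheno$y, null_design(pheno), genef$genotypes * 1.0,
    as.numeric(weights), as.numeric(rho_grid),
    TRUE, TRUE, TRUE, TRUE, acc
  )
  smt <- cbind(
    data.frame(site = genef$site_positions, maf = genef$mafs), res$smt
  )
  smt$p_bh <- adjust_pvalues(smt$p_raw, "bh")
  smt$p_bonferroni <- adjust_pvalues(smt$p_raw, "bonferroni")
  structure(
    list(
      smt = smt,
      smt_min_adj_p = c(
        bh = suppressWarnings(min(smt$p_bh, na.rm = TRUE)),
        bonferroni = suppressWarnings(min(smt$p_bonferroni, na.rm = TRUE))
      ),
      burden_p = res$burden$p,
      skat_p = res$skat$p,
      skato_p = res$skato$p,
      inclusion = inclusion
    ),
    class = "gene_test_result"
  )
}
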