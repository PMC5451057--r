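#' The simulation-study scenario grid
#'
#' Thirty-six alternative-hypothesis scenarios plus the null (scenario 0),
#' crossing the percentage of causal rare variants (5/10/20/50% of the
#' SNVs with MAF <= 0.03 in a gene), the effect-size constant `c` in
#' `beta_i = c * |log10(MAF_i)|` (0.6/0.3/0.2), and the percentage of causal
#' effects with positive sign (100/80/50).  The grid ships as a YAML file
#' under `inst/extdata` and is returned as a data frame.
#'
#' @return Data frame with columns `scenario`, `causal_percent`, `c`,
#'   `positive_percent`.
#' @examples
#' head(scenario_grid())
#' @export
scenario_grid <- function() {
  path <- system.file("extdata", "scenario_grid.yaml", package = "rarepower")
  rows <- yaml::read_yaml(path)$scenarios
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Resolve one scenario into a full configuration
#'
#' @param scenario scenario id, 0 (null) to 36.
#' @param n diploid sample size (default 1,000).
#' @param m number of Monte-Carlo replicates.
#' @param rare_threshold MAF cutoff defining "rare" (default 0.03).
#' @param error_dist phenotype error distribution: `"normal"` (the study
#'   model), or `"t4"`, `"t8"`, `"lognormal"` for the misspecification arm.
#' @param trait `"quantitative"` or `"binary"`.
#' @param gene_length gene window size in bp.
#' @param seed experiment root seed.
#' @return A `scenario_config` list with fields `scenario`,
#'   `causal_fraction`, `c`, `positive_fraction`, `rare_threshold`,
#'   `error_dist`, `trait`, `n`, `m`, `gene_length`, `seed`.
#' @export
scenario_config <- function(scenario, n = 1000, m = 10000,
                            rare_threshold = 0.03,
                            error_dist = c("normal", "t4", "t8", "lognormal"),
                            trait = c("quantitative", "binary"),
                            gene_length = 3000, seed = 1L) {
  grid <- scenario_grid()
  row <- grid[grid$scenario == scenario, ]
  if (nrow(row) != 1L) stop("unknown scenario id: ", scenario)
  cfg <- list(
    scenario = scenario,
    causal_fraction = row$causal_percent / 100,
    c = row$c,
    positive_fraction = row$positive_percent / 100,
    rare_threshold = rare_threshold,
    error_dist = match.arg(error_dist),
    trait = match.arg(trait),
    n = as.integer(n), m = as.integer(m),
    gene_length = gene_length, seed = as.integer(seed)
  )
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<scenario_config> scenario %d: %.0f%% causal, c = %.2g, ",
      "%.0f%% positive, %s errors, %s trait, n = %d, m = %d, seed = %d\n"
    ),
    x$scenario, 100 * x$causal_fraction, x$c, 100 * x$positive_fraction,
    x$error_dist, x$trait, x$n, x$m, x$seed
  ))
  invisible(x)
}

# round-half-up, the documented rounding rule for causal counts and sign
# splits (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

#' Select causal variants in a gene
#'
#' Causal variants are chosen uniformly at random among the rare sites
#' (MAF <= `rare_threshold`); the count is
#' `max(1, round_half_up(causal_fraction * #rare))`, i.e. at least one rare
#' variant per gene is causal under any alternative scenario.  A
#' `causal_fraction` of 0 returns the empty set (null scenario).
#'
#' @param gene a `gene_replicate`.
#' @param cfg a `scenario_config` (only `causal_fraction` and
#'   `rare_threshold` are used).
#' @param seed optional seed; default continues the current RNG stream.
#' @return Integer vector of causal site indices (columns of
#'   `gene$genotypes`).
#' @export
select_causal_variants <- function(gene, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$causal_fraction == 0) {
    return(integer(0))
  }
  rare <- which(gene$mafs <= cfg$rare_threshold)
  if (length(rare) == 0L) {
    stop(structure(
      class = c("rarepower_no_eligible_sites", "error", "condition"),
      list(message = "no rare site eligible as causal", call = NULL)
    ))
  }
  n_causal <- max(1L, round_half_up(cfg$causal_fraction * length(rare)))
  n_causal <- min(n_causal, length(rare))
  sort(rare[sample.int(length(rare), n_causal)])
}

#' Assign signed effect sizes to causal variants
#'
#' Effect magnitudes follow `|beta_i| = c * |log10(MAF_i)|`, so rarer
#' variants get larger effects.  A uniformly random subset of
#' `round_half_up(positive_fraction * #causal)` sites receives a positive
#' sign; the remainder are negative.
#'
#' @param mafs MAFs of the causal sites, all in `(0, rare_threshold]`.
#' @param cfg a `scenario_config` (uses `c` and `positive_fraction`).
#' @param causal_indices site indices the MAFs belong to (carried through).
#' @param seed optional seed.
#' @return An `effect_assignment`: list with `causal_indices` and signed
#'   `betas`.
#' @export
assign_effect_sizes <- function(mafs, cfg, causal_indices = seq_along(mafs),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(mafs <= 0)) stop("MAF = 0 gives an undefined effect magnitude")
  betas <- cfg$c * abs(log10(mafs))
  n_pos <- round_half_up(cfg$positive_fraction * length(mafs))
  sign <- rep(-1, length(mafs))
  if (n_pos > 0L) sign[sample.int(length(mafs), min(n_pos, length(mafs)))] <- 1
  structure(
    list(causal_indices = causal_indices, betas = betas * sign),
    class = "effect_assignment"
  )
}

# error draws for the phenotype model; lognormal is mean-centred so the
# null intercept stays 0
rtrait_error <- function(n, dist) {
  switch(dist,
    normal = rnorm(n),
    t4 = rt(n, df = 4),
    t8 = rt(n, df = 8),
    lognormal = exp(rnorm(n)) - exp(0.5),
    stop("unknown error distribution: ", dist)
  )
}

#' Generate a quantitative trait given a gene replicate
#'
#' The phenotype model is
#' `Y = 0.5 x1 + 0.5 x2 + sum_i beta_i g_i + eps` with `x1 ~ Bin(0.5)`,
#' `x2 ~ N(0,1)` and `eps` standard normal (or t4 / t8 / centred standard
#' log-normal in the error-misspecification arm).
#'
#' @param gene a `gene_replicate`.
#' @param eff an `effect_assignment` (empty under the null).
#' @param cfg a `scenario_config` (uses `error_dist`).
#' @param seed optional seed.
#' @return A `phenotype_set`: list with `y`, `x1`, `x2`, `error_dist`.
#' @export
generate_quantitative_trait <- function(gene, eff, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gene$genotypes)
  x1 <- rbinom(n, 1L, 0.5)
  x2 <- rnorm(n)
  y <- 0.5 * x1 + 0.5 * x2 + rtrait_error(n, cfg$error_dist)
  if (length(eff$causal_indices)) {
    y <- y + drop(gene$genotypes[, eff$causal_indices, drop = FALSE] %*% eff$betas)
  }
  structure(
    list(y = y, x1 = x1, x2 = x2, error_dist = cfg$error_dist),
    class = "phenotype_set"
  )
}

#' Proportion of trait variance explained by the causal variants
#'
#' Computes `sum_i 2 MAF_i (1 - MAF_i) beta_i^2 / var_y` over the causal
#' sites (non-causal sites contribute 0), the additive heritability the
#' gene contributes to the trait.
#'
#' @param gene a `gene_replicate`.
#' @param eff an `effect_assignment`.
#' @param var_y trait variance (empirical variance of `y` per replicate in
#'   the study summaries).
#' @return Proportion in `[0, 1)`.
#' @export
explained_variance <- function(gene, eff, var_y) {
  stopifnot(var_y > 0)
  if (!length(eff$causal_indices)) {
    return(0)
  }
  maf <- gene$mafs[eff$causal_indices]
  sum(2 * maf * (1 - maf) * eff$betas^2) / var_y
}

#' Generate a balanced case-control trait from a logistic model
#'
#' Disease status follows
#' `logit P(case) = gamma0 + 0.5 x1 + 0.5 x2 + sum_i beta_i g_i`, with the
#' intercept `gamma0` solved numerically so that the population prevalence
#' matches `prevalence`.  A balanced sample of `n/2` cases and `n/2`
#' controls is then drawn by rejection sampling; population individuals are
#' generated by resampling genotype rows of the gene replicate with
#' replacement, with fresh covariates each time.  The logistic design and
#' its defaults are a reconstruction and deliberately configurable.
#'
#' @param gene a `gene_replicate` (its genotype rows define the
#'   population's genotype distribution).
#' @param eff an `effect_assignment` on the columns of `gene$genotypes`.
#' @param cfg a `scenario_config` with `trait = "binary"`.
#' @param prevalence population disease prevalence in (0, 1).
#' @param seed optional seed.
#' @return A `phenotype_set` with binary `y` (1 = case), `x1`, `x2`, and
#'   the case-control `genotypes` matrix (row-resampled).
#' @export
generate_binary_trait <- function(gene, eff, cfg, prevalence = 0.1,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be strictly inside (0, 1)")
  }
  n <- cfg$n
  npop <- nrow(gene$genotypes)
  draw_batch <- function(size) {
    g <- gene$genotypes[sample.int(npop, size, replace = TRUE), , drop = FALSE]
    x1 <- rbinom(size, 1L, 0.5)
    x2 <- rnorm(size)
    eta <- 0.5 * x1 + 0.5 * x2
    if (length(eff$causal_indices)) {
      eta <- eta + drop(g[, eff$causal_indices, drop = FALSE] %*% eff$betas)
    }
    list(g = g, x1 = x1, x2 = x2, eta = eta)
  }
  # solve the intercept on a fixed reference population (common random
  # numbers keep the root-finding deterministic)
  ref <- draw_batch(50000L)
  g0 <- uniroot(
    function(g0) mean(stats::plogis(g0 + ref$eta)) - prevalence,
    lower = -50, upper = 50, tol = 1e-8
  )$root
  need_case <- ceiling(n / 2)
  need_ctrl <- n - need_case
  ys <- integer(0)
  x1s <- integer(0)
  x2s <- numeric(0)
  gs <- NULL
  while (need_case > 0L || need_ctrl > 0L) {
    b <- draw_batch(max(2000L, 4L * (need_case + need_ctrl)))
    case <- rbinom(length(b$eta), 1L, stats::plogis(g0 + b$eta))
    keep_case <- which(case == 1L)[seq_len(min(need_case, sum(case == 1L)))]
    keep_ctrl <- which(case == 0L)[seq_len(min(need_ctrl, sum(case == 0L)))]
    keep <- c(keep_case, keep_ctrl)
    ys <- c(ys, case[keep])
    x1s <- c(x1s, b$x1[keep])
    x2s <- c(x2s, b$x2[keep])
    gs <- rbind(gs, b$g[keep, , drop = FALSE])
    need_case <- need_case - length(keep_case)
    need_ctrl <- need_ctrl - length(keep_ctrl)
  }
  structure(
    list(
      y = ys, x1 = x1s, x2 = x2s, genotypes = gs,
      intercept = g0, prevalence = prevalence, error_dist = "logistic"
    ),
    class = "phenotype_set"
  )
}
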