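# Scenario grid, causal-variant selection, effect sizes, phenotype models.

test_that("scenario grid reproduces the 37-row study design", {
  grid <- scenario_grid()
  expect_identical(nrow(grid), 37L)
  expect_identical(grid$scenario, 0:36)
  expect_equal(grid[grid$scenario == 0, ]$c, 0)
  expect_equal(grid[grid$scenario == 1, ][, -1], # 5% causal, c = 0.6, all +
    data.frame(causal_percent = 5, c = 0.6, positive_percent = 100),
    ignore_attr = TRUE
  )
  expect_equal(grid[grid$scenario == 12, ][, -1],
    data.frame(causal_percent = 50, c = 0.2, positive_percent = 100),
    ignore_attr = TRUE
  )
  # blocks 13-24 and 25-36 repeat 1-12 with different sign splits
  expect_equal(grid$causal_percent[grid$scenario %in% 13:24],
    grid$causal_percent[grid$scenario %in% 1:12])
  expect_equal(grid$c[grid$scenario %in% 25:36], grid$c[grid$scenario %in% 1:12])
  expect_true(all(grid$positive_percent[grid$scenario %in% 13:24] == 80))
  expect_true(all(grid$positive_percent[grid$scenario %in% 25:36] == 50))
})

test_that("causal-variant counts follow the round-half-up rule with floor 1", {
  pool <- tiny_pool()
  set.seed(31)
  gene <- rarepower:::sample_gene_replicate(pool, 5000, 100)
  # synthetic replicate with exactly 20 and 33 rare sites via maf override
  fake_gene <- function(n_rare, n_common = 3) {
    k <- n_rare + n_common
    structure(
      list(
        genotypes = matrix(1L, 4, k),
        mafs = c(rep(0.01, n_rare), rep(0.2, n_common)),
        macs = rep(1L, k), site_positions = seq_len(k)
      ),
      class = "gene_replicate"
    )
  }
  cfg05 <- scenario_config(1, seed = 1) # causal fraction 0.05
  cfg50 <- scenario_config(10, seed = 1) # causal fraction 0.5
  expect_length(select_causal_variants(fake_gene(20), cfg05, seed = 2), 1L)
  expect_length(select_causal_variants(fake_gene(33), cfg50, seed = 2), 17L)
  # round_half_up(16.5) = 17, checked against the exhaustive rule table
  rule <- function(frac, k) max(1, floor(frac * k + 0.5))
  scen_for_frac <- c("0.05" = 1, "0.1" = 4, "0.2" = 7, "0.5" = 10)
  for (k in c(1, 5, 20, 33, 50)) {
    for (frac in c(0.05, 0.1, 0.2, 0.5)) {
      cfg <- scenario_config(scen_for_frac[[as.character(frac)]], seed = 1)
      expect_length(
        select_causal_variants(fake_gene(k), cfg, seed = 3),
        rule(frac, k)
      )
    }
  }
  # null scenario selects nothing; all-common gene under alternative errors
  expect_length(
    select_causal_variants(gene, scenario_config(0, seed = 1), seed = 1), 0L
  )
  expect_error(
    select_causal_variants(fake_gene(0), cfg05, seed = 1),
    class = "rarepower_no_eligible_sites"
  )
  # only rare sites are eligible
  sel <- select_causal_variants(fake_gene(10), cfg50, seed = 5)
  expect_true(all(fake_gene(10)$mafs[sel] <= 0.03))
})

test_that("effect magnitudes follow c|log10 MAF| and the exact sign split", {
  cfg <- scenario_config(13, seed = 1) # c = 0.6, 80% positive
  eff <- assign_effect_sizes(rep(0.0005, 10), cfg, seed = 4)
  expect_equal(abs(eff$betas), rep(0.6 * log10(2000), 10)) # ~1.98058
  expect_identical(sum(eff$betas > 0), 8L)
  expect_identical(sum(eff$betas < 0), 2L)
  # magnitude strictly decreasing in MAF
  mafs <- c(0.0005, 0.002, 0.01, 0.03)
  eff2 <- assign_effect_sizes(mafs, scenario_config(1, seed = 1), seed = 4)
  expect_true(all(diff(abs(eff2$betas)) < 0))
  # c = 0 gives null effects; maf 0 is rejected
  eff0 <- assign_effect_sizes(mafs, scenario_config(0, seed = 1), seed = 4)
  expect_true(all(eff0$betas == 0))
  expect_error(assign_effect_sizes(c(0, 0.01), cfg, seed = 1), "MAF")
})

test_that("quantitative trait equals covariate signal plus genetic term", {
  pool <- tiny_pool()
  set.seed(55)
  gene <- rarepower:::sample_gene_replicate(pool, 5000, 200)
  cfg <- scenario_config(1, n = 200, seed = 1)
  rare <- which(gene$mafs <= 0.03)
  eff <- list(causal_indices = rare[1:2], betas = c(1.5, -2))
  # same seed: y(eff) - y(null) is exactly G beta (x1, x2, eps shared)
  y1 <- generate_quantitative_trait(gene, eff, cfg, seed = 9)
  y0 <- generate_quantitative_trait(gene, null_effect(), cfg, seed = 9)
  expect_equal(
    y1$y - y0$y,
    drop(gene$genotypes[, eff$causal_indices] %*% eff$betas)
  )
  # covariate coefficients are 0.5/0.5: regression on large null sample
  cfg_big <- scenario_config(0, n = 200, seed = 1)
  set.seed(2)
  big <- do.call(rbind, lapply(1:50, function(i) {
    ph <- generate_quantitative_trait(gene, null_effect(), cfg_big)
    data.frame(y = ph$y, x1 = ph$x1, x2 = ph$x2)
  }))
  co <- summary(lm(y ~ x1 + x2, data = big))$coefficients
  expect_lt(abs(co[2, 1] - 0.5), 4 * co[2, 2])
  expect_lt(abs(co[3, 1] - 0.5), 4 * co[3, 2])
  # null variance: Var(Y) = 0.25*0.25 + 0.25*1 + 1 = 1.3125
  expect_equal(var(big$y), 1.3125, tolerance = 0.05)
})

test_that("misspecified error distributions have the stated shapes", {
  pool <- tiny_pool()
  set.seed(65)
  gene <- rarepower:::sample_gene_replicate(pool, 5000, 100)
  draw_eps <- function(dist) {
    cfg <- scenario_config(0, n = 100, error_dist = dist, seed = 1)
    unlist(lapply(1:400, function(i) {
      ph <- generate_quantitative_trait(gene, null_effect(), cfg)
      ph$y - 0.5 * ph$x1 - 0.5 * ph$x2
    }))
  }
  set.seed(3)
  eps_t4 <- draw_eps("t4")
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2 - 3
  expect_gt(kurt(eps_t4), 1) # t4 has heavy tails (infinite kurtosis)
  set.seed(3)
  eps_ln <- draw_eps("lognormal")
  expect_equal(mean(eps_ln), 0, tolerance = 0.05) # mean-centred
  expect_gt(min(eps_ln), -exp(0.5) - 1e-9) # support bounded below
  expect_gt(mean((eps_ln - mean(eps_ln))^3), 0) # right skew
})

test_that("explained variance matches the hand-computed formula", {
  gene <- structure(
    list(
      genotypes = matrix(0L, 2, 3), mafs = c(0.01, 0.02, 0.3),
      macs = c(1L, 2L, 30L), site_positions = 1:3
    ),
    class = "gene_replicate"
  )
  eff1 <- list(causal_indices = 1L, betas = 1.2)
  expect_equal(
    explained_variance(gene, eff1, 1.5),
    2 * 0.01 * 0.99 * 1.44 / 1.5 # = 0.019008
  )
  expect_equal(explained_variance(gene, null_effect(), 1.5), 0)
  # additive over disjoint causal sets
  eff2 <- list(causal_indices = 2L, betas = -0.7)
  eff12 <- list(causal_indices = c(1L, 2L), betas = c(1.2, -0.7))
  expect_equal(
    explained_variance(gene, eff12, 2),
    explained_variance(gene, eff1, 2) + explained_variance(gene, eff2, 2)
  )
  expect_error(explained_variance(gene, eff1, 0))
})

test_that("under the null the trait is independent of every genotype column", {
  pool <- tiny_pool()
  cfg <- scenario_config(0, n = 150, seed = 1)
  set.seed(8)
  cors <- unlist(lapply(1:40, function(i) {
    gene <- rarepower:::sample_gene_replicate(pool, 5000, 150)
    ph <- generate_quantitative_trait(gene, null_effect(), cfg)
    apply(gene$genotypes, 2, function(g) cor(g, ph$y))
  }))
  expect_lt(abs(mean(cors)), 0.01)
})

test_that("binary traits are balanced and hit the target prevalence", {
  pool <- tiny_pool()
  set.seed(91)
  gene <- rarepower:::sample_gene_replicate(pool, 5000, 200)
  cfg <- scenario_config(0, n = 200, trait = "binary", seed = 1)
  ph <- generate_binary_trait(gene, null_effect(), cfg, prevalence = 0.1,
    seed = 12
  )
  expect_identical(sum(ph$y == 1L), 100L)
  expect_identical(sum(ph$y == 0L), 100L)
  expect_identical(nrow(ph$genotypes), 200L)
  # the solved intercept reproduces the population prevalence (null model:
  # prevalence = E[plogis(g0 + 0.5 x1 + 0.5 x2)])
  set.seed(5)
  x1 <- rbinom(2e5, 1, 0.5)
  x2 <- rnorm(2e5)
  expect_equal(mean(plogis(ph$intercept + 0.5 * x1 + 0.5 * x2)), 0.1,
    tolerance = 0.005
  )
  expect_error(
    generate_binary_trait(gene, null_effect(), cfg, prevalence = 0),
    "prevalence"
  )
})
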