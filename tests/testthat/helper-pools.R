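# Shared simulation fixtures, built once per test session.
#
# `tiny_pool()`  - small fast pool for unit tests (400 haplotypes, 30kb).
# `study_pool()` - the full study-scale pool (10,000 haplotypes, 200kb,
#                  default European-growth demography); only built when a
#                  test first asks for it.

.pool_cache <- new.env(parent = emptyenv())

tiny_pool <- function() {
  if (is.null(.pool_cache$tiny)) {
    .pool_cache$tiny <- simulate_haplotype_pool(
      n_haplotypes = 400, region_length = 3e4, seed = 101
    )
  }
  .pool_cache$tiny
}

study_pool <- function() {
  if (is.null(.pool_cache$study)) {
    .pool_cache$study <- simulate_haplotype_pool(seed = 11)
  }
  .pool_cache$study
}

# hand-built 6-haplotype pool for brute-force pairing checks
toy_pool <- function() {
  haps <- rbind(
    c(1L, 0L, 0L, 1L),
    c(0L, 1L, 0L, 1L),
    c(0L, 0L, 0L, 1L),
    c(1L, 0L, 0L, 1L),
    c(0L, 0L, 1L, 0L),
    c(0L, 1L, 0L, 0L)
  )
  rarepower:::new_haplotype_pool(haps, c(100, 2900, 3100, 8000), 1e4, "loaded")
}

null_effect <- function() list(causal_indices = integer(0), betas = numeric(0))

quick_pheno <- function(gene, cfg, seed = 1) {
  generate_quantitative_trait(gene, null_effect(), cfg, seed = seed)
}
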