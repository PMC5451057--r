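#' Demographic model presets for the haplotype-pool simulator
#'
#' `european_growth_demography()` is the package default: a single
#' population with a Tennessen-style recent-growth history (explosive
#' growth over the last ~205 generations on top of an out-of-Africa
#' bottleneck), calibrated so that 3kb gene regions sampled from a
#' 10,000-haplotype / 200kb pool carry on average about 33 non-monomorphic
#' SNVs in diploid samples of n = 1,000, with roughly 40% singletons and
#' around 80% of sites at MAF <= 0.03 -- a rare-variant-heavy site-frequency
#' spectrum typical of European-ancestry sequence data.
#' `constant_size_demography()` gives a neutral constant-size model, mainly
#' useful for analytic cross-checks (Watterson's formula).
#'
#' @param mutation_rate per-bp per-generation mutation rate.
#' @param recombination_rate per-bp per-generation recombination rate.
#' @param Ne effective population size for the constant-size model.
#' @return A list with `mutation_rate`, `recombination_rate` and an
#'   `epochs` data frame (`time` in generations before present, `size`,
#'   `growth_rate`), accepted by [simulate_haplotype_pool()].
#' @export
european_growth_demography <- function(mutation_rate = 4.3e-8,
                                       recombination_rate = 1e-8) {
  list(
    mutation_rate = mutation_rate,
    recombination_rate = recombination_rate,
    epochs = data.frame(
      time = c(0, 205, 920, 2040),
      size = c(50000, 4604, 930, 12000),
      growth_rate = c(0.0116, 0.00224, 0, 0)
    )
  )
}

#' @rdname european_growth_demography
#' @export
constant_size_demography <- function(Ne, mutation_rate,
                                     recombination_rate = 0) {
  list(
    mutation_rate = mutation_rate,
    recombination_rate = recombination_rate,
    epochs = data.frame(time = 0, size = Ne, growth_rate = 0)
  )
}

python_binary <- function() {
  py <- getOption("rarepower.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no python interpreter found; set options(rarepower.python = ...)")
  }
  py
}

new_haplotype_pool <- function(haplotypes, positions, region_length,
                               provenance) {
  storage.mode(haplotypes) <- "integer"
  stopifnot(
    all(haplotypes %in% c(0L, 1L)),
    length(positions) == ncol(haplotypes),
    !is.unsorted(positions, strictly = TRUE) || ncol(haplotypes) <= 1L,
    all(positions >= 0), all(positions < region_length)
  )
  cs <- colSums(haplotypes)
  if (any(cs == 0L | cs == nrow(haplotypes))) {
    stop("pool contains non-segregating sites")
  }
  structure(
    list(
      haplotypes = haplotypes, positions = as.numeric(positions),
      region_length = as.numeric(region_length), provenance = provenance
    ),
    class = "haplotype_pool"
  )
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(
    sprintf(
      "<haplotype_pool> %d haplotypes x %d segregating sites over %.0f bp (%s)\n",
      nrow(x$haplotypes), ncol(x$haplotypes), x$region_length, x$provenance
    )
  )
  invisible(x)
}

#' Simulate a haplotype pool from a coalescent model
#'
#' Runs a neutral coalescent with recombination (msprime, invoked through
#' the helper script shipped with the package) under a piecewise demographic
#' model and returns the segregating binary haplotypes over the region.
#' Derived alleles are coded 1.  Deterministic given `seed`.
#'
#' @param n_haplotypes number of haploid samples (default 10,000).
#' @param region_length region size in bp (default 200kb).
#' @param demographic_params list as returned by
#'   [european_growth_demography()] (the default) or
#'   [constant_size_demography()].
#' @param seed integer random seed.
#' @param num_replicates simulate this many independent pools in one
#'   backend call; if greater than 1 a list of pools is returned.
#' @return A `haplotype_pool` (or list of them): binary matrix `haplotypes`
#'   (rows = haplotypes), `positions` in bp, `region_length`, `provenance`.
#' @examples
#' \dontrun{
#' pool <- simulate_haplotype_pool(200, 5e4, seed = 1)
#' }
#' @export
simulate_haplotype_pool <- function(n_haplotypes = 10000,
                                    region_length = 2e5,
                                    demographic_params = european_growth_demography(),
                                    seed = 1L,
                                    num_replicates = 1L) {
  stopifnot(
    n_haplotypes >= 2, n_haplotypes %% 2 == 0, region_length > 0,
    num_replicates >= 1
  )
  dp <- demographic_params
  if (dp$mutation_rate < 0 || dp$recombination_rate < 0 ||
    any(dp$epochs$size <= 0)) {
    stop("invalid demographic parameters: rates must be >= 0, sizes > 0")
  }
  script <- system.file("python", "simulate_pool.py", package = "rarepower")
  stopifnot(nzchar(script))
  tmp <- tempfile("pool")
  cfg <- tempfile("poolcfg", fileext = ".json")
  on.exit(unlink(c(cfg, tmp, paste0(tmp, ".", seq_len(num_replicates)))),
    add = TRUE
  )
  epochs <- lapply(seq_len(nrow(dp$epochs)), function(i) {
    list(
      time = dp$epochs$time[i], size = dp$epochs$size[i],
      growth_rate = dp$epochs$growth_rate[i]
    )
  })
  jsonlite::write_json(
    list(
      n_haplotypes = n_haplotypes, region_length = region_length,
      mutation_rate = dp$mutation_rate,
      recombination_rate = dp$recombination_rate,
      epochs = epochs, seed = seed, num_replicates = num_replicates,
      out = tmp
    ),
    cfg,
    auto_unbox = TRUE, digits = NA
  )
  status <- system2(python_binary(), c(shQuote(script), shQuote(cfg)),
    stdout = FALSE, stderr = ""
  )
  if (status != 0L) stop("coalescent backend failed (exit ", status, ")")
  paths <- if (num_replicates == 1L) tmp else paste0(tmp, ".", seq_len(num_replicates))
  pools <- lapply(paths, function(p) {
    pool <- load_haplotype_pool(p)
    pool$provenance <- "simulated"
    pool
  })
  if (num_replicates == 1L) pools[[1L]] else pools
}

#' Read and write haplotype-pool files
#'
#' The pool file is plain text: a header line `H S region_length`, a line of
#' `S` strictly increasing site positions in bp, then `H` lines each holding
#' one haplotype as a string of `S` characters 0/1.  `load_haplotype_pool()`
#' validates the matrix (binary entries, segregating columns, increasing
#' positions) and tags the pool `provenance = "loaded"`, which permits
#' byte-identical reuse of an externally exported pool.
#'
#' @param path file path.
#' @param pool a `haplotype_pool`.
#' @return `load_haplotype_pool()` returns a `haplotype_pool`;
#'   `write_haplotype_pool()` returns `path` invisibly.
#' @export
load_haplotype_pool <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed pool file: missing header")
  hdr <- scan(text = lines[1L], quiet = TRUE)
  if (length(hdr) != 3L) stop("malformed pool file header")
  H <- as.integer(hdr[1L])
  S <- as.integer(hdr[2L])
  region_length <- hdr[3L]
  positions <- scan(text = lines[2L], quiet = TRUE)
  if (length(positions) != S) stop("positions row does not match header")
  if (S > 1L && any(diff(positions) <= 0)) {
    stop("site positions must be strictly increasing")
  }
  if (length(lines) != H + 2L) stop("haplotype row count does not match header")
  if (S == 0L) {
    return(new_haplotype_pool(
      matrix(integer(0), nrow = H, ncol = 0L),
      numeric(0), region_length, "loaded"
    ))
  }
  raw <- vapply(lines[-(1:2)], charToRaw, raw(S), USE.NAMES = FALSE)
  bad <- !(raw == charToRaw("0") | raw == charToRaw("1"))
  if (any(bad)) stop("haplotype entries must be 0 or 1")
  haps <- t(matrix(as.integer(raw == charToRaw("1")), nrow = S, ncol = H))
  new_haplotype_pool(haps, positions, region_length, "loaded")
}

#' @rdname load_haplotype_pool
#' @export
write_haplotype_pool <- function(pool, path) {
  stopifnot(inherits(pool, "haplotype_pool"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "%d %d %.10g", nrow(pool$haplotypes), ncol(pool$haplotypes),
    pool$region_length
  ), con)
  writeLines(paste(sprintf("%.10g", pool$positions), collapse = " "), con)
  apply(pool$haplotypes, 1L, function(row) {
    writeLines(paste(row, collapse = ""), con)
  })
  invisible(path)
}

#' Sample a gene window from the pool
#'
#' Draws a uniformly random window start `s` in
#' `[0, region_length - gene_length]` and returns the indices of all pool
#' sites with position in the half-open interval `[s, s + gene_length)`.
#' An empty window is allowed here; emptiness is handled after diploid
#' pairing (see [pair_haplotypes()]).
#'
#' @param pool a `haplotype_pool`.
#' @param gene_length window size in bp (default 3kb).
#' @param seed optional seed; by default the current RNG stream is used.
#' @param start force the window start (used in tests).
#' @return Integer vector of site indices (possibly empty), with the window
#'   start attached as attribute `"start"`.
#' @export
sample_gene_region <- function(pool, gene_length = 3000, seed = NULL,
                               start = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), gene_length <= pool$region_length)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start)) start <- runif(1L, 0, pool$region_length - gene_length)
  idx <- which(pool$positions >= start & pool$positions < start + gene_length)
  attr(idx, "start") <- start
  idx
}

new_gene_replicate <- function(genotypes, positions) {
  n <- nrow(genotypes)
  mac <- colSums(genotypes)
  flip <- mac > n # counted allele must be the sample minor allele
  if (any(flip)) {
    genotypes[, flip] <- 2L - genotypes[, flip]
    mac[flip] <- 2L * n - mac[flip]
  }
  poly <- mac > 0L & mac < 2L * n
  if (!any(poly)) {
    return(NULL)
  }
  genotypes <- genotypes[, poly, drop = FALSE]
  mac <- mac[poly]
  structure(
    list(
      genotypes = genotypes, macs = as.integer(mac),
      mafs = mac / (2 * n), site_positions = positions[poly]
    ),
    class = "gene_replicate"
  )
}

#' @export
print.gene_replicate <- function(x, ...) {
  cat(sprintf(
    "<gene_replicate> %d individuals x %d SNVs (MAF %.4g..%.4g)\n",
    nrow(x$genotypes), ncol(x$genotypes), min(x$mafs), max(x$mafs)
  ))
  invisible(x)
}

#' Pair haplotypes into a diploid gene replicate
#'
#' Draws `2 * n_individuals` haplotypes from the pool without replacement
#' (each haplotype used at most once per replicate), restricts them to the
#' gene window, sums consecutive pairs into additive genotype codes 0/1/2,
#' re-orients every column so the counted allele is the minor allele in the
#' sample, and drops monomorphic columns.  A replicate with no polymorphic
#' site left signals the classed condition `rarepower_empty_gene`, on which
#' callers are expected to resample the gene.
#'
#' @param pool a `haplotype_pool`.
#' @param window site-index vector from [sample_gene_region()].
#' @param n_individuals diploid sample size n.
#' @param seed optional seed; default uses the current RNG stream.
#' @return A `gene_replicate`: integer matrix `genotypes` (n x k, minor
#'   allele counts), `macs`, `mafs = macs / 2n`, `site_positions`.
#' @export
pair_haplotypes <- function(pool, window, n_individuals, seed = NULL) {
  stopifnot(2 * n_individuals <= nrow(pool$haplotypes))
  if (!is.null(seed)) set.seed(seed)
  rows <- sample.int(nrow(pool$haplotypes), 2L * n_individuals)
  hap <- pool$haplotypes[rows, window, drop = FALSE]
  odd <- seq(1L, 2L * n_individuals, by = 2L)
  gt <- hap[odd, , drop = FALSE] + hap[odd + 1L, , drop = FALSE]
  gene <- new_gene_replicate(gt, pool$positions[window])
  if (is.null(gene)) {
    stop(structure(
      class = c("rarepower_empty_gene", "error", "condition"),
      list(message = "gene replicate has no polymorphic site", call = NULL)
    ))
  }
  gene
}

# Hot-path sampler: window + pairing, resampling empty genes; optionally
# requires >= 1 rare site (alternative scenarios need a causal candidate).
# Counts resamples in the "resampled" attribute.
sample_gene_replicate <- function(pool, gene_length, n_individuals,
                                  require_rare = FALSE, rare_threshold = 0.03,
                                  max_tries = 1000L) {
  H <- nrow(pool$haplotypes)
  for (try in seq_len(max_tries)) {
    start <- runif(1L, 0, pool$region_length - gene_length)
    idx <- which(pool$positions >= start & pool$positions < start + gene_length)
    if (length(idx) == 0L) next
    rows <- sample.int(H, 2L * n_individuals)
    odd <- seq(1L, 2L * n_individuals, by = 2L)
    hap <- pool$haplotypes[rows, idx, drop = FALSE]
    gt <- hap[odd, , drop = FALSE] + hap[odd + 1L, , drop = FALSE]
    gene <- new_gene_replicate(gt, pool$positions[idx])
    if (is.null(gene)) next
    if (require_rare && !any(gene$mafs <= rare_threshold)) next
    attr(gene, "resampled") <- try - 1L
    return(gene)
  }
  stop("failed to sample a usable gene replicate after ", max_tries, " tries")
}

#' Export a gene replicate as a minimal VCF
#'
#' Writes CHROM/POS/REF/ALT/GT records (REF = major, ALT = minor allele;
#' genotypes are unphased allele counts), enough for interoperability tests
#' with standard VCF tooling.
#'
#' @param gene a `gene_replicate`.
#' @param path output path.
#' @param chrom chromosome label.
#' @return `path`, invisibly.
#' @export
export_gene_vcf <- function(gene, path, chrom = "1") {
  n <- nrow(gene$genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", sprintf("S%04d", seq_len(n))
    ), collapse = "\t")
  ), con)
  gtcode <- c("0/0", "0/1", "1/1")
  for (j in seq_along(gene$site_positions)) {
    fields <- c(
      chrom, sprintf("%d", as.integer(ceiling(gene$site_positions[j])) + 1L),
      sprintf("snv%d", j), "A", "T", ".", "PASS", ".", "GT",
      gtcode[gene$genotypes[, j] + 1L]
    )
    writeLines(paste(fields, collapse = "\t"), con)
  }
  invisible(path)
}
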