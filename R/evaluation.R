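#' Run the Monte-Carlo experiment for one scenario
#'
#' For each of the `cfg$m` replicates: sample a fresh 3kb gene from the
#' haplotype pool (resampling degenerate windows so denominators stay at
#' exactly `m`), pick causal variants and effect sizes when `c > 0`,
#' generate the phenotype, and run the requested tests.  Each replicate
#' runs on its own RNG sub-stream derived from `cfg$seed` via
#' [child_seed()], so results are reproducible replicate-by-replicate and
#' invariant to execution order.
#'
#' @param cfg a `scenario_config`.
#' @param pool a `haplotype_pool` (needs `2 * cfg$n` haplotypes).
#' @param methods subset of `c("smt", "burden", "skat", "skato")`.
#' @param inclusion `"all"` SNVs or `"rare"` only.
#' @param rho_grid SKAT-O mixing grid.
#' @param acc absolute accuracy of the chi-square-mixture tail evaluations.
#' @param collect_tstats additionally collect every per-SNV t statistic
#'   together with its minor allele count (memory-heavy for large `m`).
#' @param collect_snv additionally collect per-SNV p-values and MAFs of the
#'   causal SNVs (for SNV-level power).
#' @param progress print a progress line every `progress` replicates
#'   (0 = silent).
#' @return A `scenario_result`: data frame `replicates` with one row per
#'   replicate (`k` SNVs tested, gene-level p-values `smt_min_p_bh`,
#'   `smt_min_p_bonferroni`, `burden_p`, `skat_p`, `skato_p`, and
#'   `explained_var`), the resolved `cfg`, the inclusion mode, the count of
#'   resampled degenerate draws, and optional `tstats` / `snv` tables.
#' @export
run_scenario <- function(cfg, pool,
                         methods = c("smt", "burden", "skat", "skato"),
                         inclusion = c("all", "rare"), rho_grid = default_rho_grid(),
                         acc = 1e-6, collect_tstats = FALSE, collect_snv = FALSE,
                         progress = 0L) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(pool, "haplotype_pool"))
  if (cfg$trait != "quantitative") {
    stop(
      "run_scenario() drives the quantitative-trait study; the binary arm ",
      "is exposed through generate_binary_trait()"
    )
  }
  inclusion <- match.arg(inclusion)
  methods <- match.arg(methods, several.ok = TRUE)
  do_smt <- "smt" %in% methods
  do_burden <- "burden" %in% methods
  do_skat <- "skat" %in% methods
  do_skato <- "skato" %in% methods
  m <- cfg$m
  n <- cfg$n
  alt <- cfg$causal_fraction > 0
  res <- matrix(NA_real_, nrow = m, ncol = 7L)
  colnames(res) <- c(
    "k", "smt_min_p_bh", "smt_min_p_bonferroni", "burden_p", "skat_p",
    "skato_p", "explained_var"
  )
  resampled <- 0L
  tstat_list <- if (collect_tstats) vector("list", m)
  snv_list <- if (collect_snv) vector("list", m)
  for (i in seq_len(m)) {
    set.seed(child_seed(cfg$seed, i))
    gene <- sample_gene_replicate(pool, cfg$gene_length, n,
      require_rare = alt, rare_threshold = cfg$rare_threshold
    )
    resampled <- resampled + attr(gene, "resampled")
    if (alt) {
      causal <- select_causal_variants(gene, cfg)
      eff <- assign_effect_sizes(gene$mafs[causal], cfg, causal)
    } else {
      eff <- list(causal_indices = integer(0), betas = numeric(0))
    }
    pheno <- generate_quantitative_trait(gene, eff, cfg)
    genef <- filter_inclusion(gene, inclusion, cfg$rare_threshold)
    if (is.null(genef)) next # no SNV in inclusion mode; row stays NA
    w <- skat_weights(genef$mafs)
    s <- .replicate_summary_cpp(
      pheno$y, cbind(1, pheno$x1, pheno$x2), genef$genotypes * 1.0, w,
      rho_grid, do_smt || collect_tstats || collect_snv, do_burden,
      do_skat, do_skato, acc
    )
    res[i, 1L] <- s[6L]
    res[i, 2L] <- s[1L]
    res[i, 3L] <- s[2L]
    res[i, 4L] <- s[3L]
    res[i, 5L] <- s[4L]
    res[i, 6L] <- s[5L]
    res[i, 7L] <- explained_variance(gene, eff, var(pheno$y))
    if (collect_tstats || collect_snv) {
      full <- .gene_tests_cpp(
        pheno$y, cbind(1, pheno$x1, pheno$x2), genef$genotypes * 1.0, w,
        rho_grid, TRUE, FALSE, FALSE, FALSE, acc
      )
      if (collect_tstats) {
        tstat_list[[i]] <- data.frame(
          replicate = i, mac = genef$macs, t_stat = full$smt$t_stat,
          beta_hat = full$smt$beta_hat, se_hat = full$smt$se_hat
        )
      }
      if (collect_snv) {
        causal_in_f <- match(
          gene$site_positions[eff$causal_indices], genef$site_positions
        )
        keep <- !is.na(causal_in_f)
        if (any(keep)) {
          idx <- causal_in_f[keep]
          snv_list[[i]] <- data.frame(
            replicate = i, maf = genef$mafs[idx],
            p_raw = full$smt$p_raw[idx],
            p_bh = adjust_pvalues(full$smt$p_raw, "bh")[idx]
          )
        }
      }
    }
    if (progress > 0L && i %% progress == 0L) {
      message("replicate ", i, "/", m)
    }
  }
  structure(
    list(
      replicates = as.data.frame(res), cfg = cfg, inclusion = inclusion,
      methods = methods, resampled = resampled,
      tstats = if (collect_tstats) do.call(rbind, tstat_list),
      snv = if (collect_snv) do.call(rbind, snv_list)
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "<scenario_result> scenario %d, m = %d replicates, inclusion = %s\n",
    x$cfg$scenario, nrow(x$replicates), x$inclusion
  ))
  invisible(x)
}

method_pvalues <- function(result, method) {
  r <- result$replicates
  switch(method,
    smt_bh = r$smt_min_p_bh,
    smt_bonferroni = r$smt_min_p_bonferroni,
    burden = r$burden_p,
    skat = r$skat_p,
    skato = r$skato_p,
    stop("unknown method: ", method)
  )
}

#' Gene-level power / type-I-error estimate
#'
#' The rejection proportion among the `m` replicates at nominal level
#' `alpha` (for the single-marker tests: the minP rule on the adjusted
#' p-values), with its binomial Monte-Carlo standard error
#' `sqrt(p_hat (1 - p_hat) / m)`.
#'
#' @param result a `scenario_result`.
#' @param method one of `"smt_bh"`, `"smt_bonferroni"`, `"burden"`,
#'   `"skat"`, `"skato"`.
#' @param alpha nominal level(s).
#' @return Data frame with `level`, `method`, `inclusion`, `alpha`,
#'   `estimate`, `mc_se`, `m_or_l`.
#' @export
estimate_gene_power <- function(result, method, alpha = 0.05) {
  p <- method_pvalues(result, method)
  stopifnot(length(p) >= 1)
  do.call(rbind, lapply(alpha, function(a) {
    est <- mean(p <= a, na.rm = TRUE)
    m <- sum(!is.na(p))
    data.frame(
      level = "gene", method = method, inclusion = result$inclusion,
      alpha = a, estimate = est, mc_se = sqrt(est * (1 - est) / m),
      m_or_l = m
    )
  }))
}

#' SNV-level power estimate for causal rare variants
#'
#' The proportion of causal-SNV p-values at or below `alpha`, pooled over
#' all replicates, within a MAF stratum.
#'
#' @param snv the `snv` table of a `scenario_result` run with
#'   `collect_snv = TRUE` (columns `maf` and a p-value column).
#' @param alpha nominal level.
#' @param maf_range inclusive lower / exclusive upper MAF bound of the
#'   stratum (upper bound inclusive at 0.5); `NULL` pools all causal SNVs.
#' @param p_column which p-value to threshold (`"p_raw"` or `"p_bh"`).
#' @return Data frame as in [estimate_gene_power()] with `level = "snv"`
#'   and `maf_class`.
#' @export
estimate_snv_power <- function(snv, alpha = 0.05, maf_range = NULL,
                               p_column = "p_raw") {
  stopifnot(is.data.frame(snv), p_column %in% names(snv))
  if (!is.null(maf_range)) {
    snv <- snv[snv$maf >= maf_range[1] & snv$maf < maf_range[2], , drop = FALSE]
  }
  l <- sum(!is.na(snv[[p_column]]))
  if (l == 0L) {
    return(data.frame(
      level = "snv", method = p_column, alpha = alpha, estimate = NA_real_,
      mc_se = NA_real_, m_or_l = 0L,
      maf_class = if (is.null(maf_range)) "all" else paste(maf_range, collapse = "-")
    ))
  }
  est <- mean(snv[[p_column]] <= alpha, na.rm = TRUE)
  data.frame(
    level = "snv", method = p_column, alpha = alpha, estimate = est,
    mc_se = sqrt(est * (1 - est) / l), m_or_l = l,
    maf_class = if (is.null(maf_range)) "all" else paste(maf_range, collapse = "-")
  )
}

#' Summarise an experiment across scenarios, methods and levels
#'
#' Builds the wide rejection-rate table (one row per scenario x inclusion,
#' one column per method x alpha) plus the median (MAD) explained variance
#' per scenario, the shape used by the study's scenario-overview and
#' null-calibration tables.
#'
#' @param results list of `scenario_result` objects.
#' @param methods methods to tabulate.
#' @param alphas nominal levels to tabulate.
#' @return List with `power` (wide data frame) and `explained_variance`
#'   (per-scenario median and MAD, in percent).
#' @export
summarize_experiment <- function(results,
                                 methods = c(
                                   "smt_bh", "smt_bonferroni", "burden",
                                   "skat", "skato"
                                 ),
                                 alphas = 0.05) {
  if (inherits(results, "scenario_result")) results <- list(results)
  rows <- lapply(results, function(res) {
    avail <- methods[vapply(methods, function(mm) {
      !all(is.na(method_pvalues(res, mm)))
    }, logical(1))]
    row <- data.frame(
      scenario = res$cfg$scenario, inclusion = res$inclusion,
      m = nrow(res$replicates)
    )
    for (mm in avail) {
      for (a in alphas) {
        est <- estimate_gene_power(res, mm, a)
        row[[sprintf("%s_a%g", mm, a)]] <- est$estimate
      }
    }
    row
  })
  power <- do.call(rbind, lapply(rows, function(r) {
    missing <- setdiff(unique(unlist(lapply(rows, names))), names(r))
    for (mc in missing) r[[mc]] <- NA_real_
    r
  }))
  ev <- do.call(rbind, lapply(results, function(res) {
    v <- res$replicates$explained_var
    data.frame(
      scenario = res$cfg$scenario,
      median_explained_pct = 100 * median(v, na.rm = TRUE),
      mad_explained_pct = 100 * mad(v, na.rm = TRUE)
    )
  }))
  list(power = power, explained_variance = ev)
}

#' Write tidy per-replicate results
#'
#' Long-format TSV with one row per replicate x method: replicate id,
#' method, inclusion mode, p-value, and the decision at each requested
#' alpha.
#'
#' @param result a `scenario_result`.
#' @param path output TSV path.
#' @param alphas decision levels to include.
#' @return `path`, invisibly.
#' @export
write_replicate_tsv <- function(result, path, alphas = c(0.05, 2.5e-6)) {
  methods <- c("smt_bh", "smt_bonferroni", "burden", "skat", "skato")
  long <- do.call(rbind, lapply(methods, function(mm) {
    p <- method_pvalues(result, mm)
    if (all(is.na(p))) {
      return(NULL)
    }
    df <- data.frame(
      replicate = seq_along(p), method = mm, inclusion = result$inclusion,
      p = p
    )
    for (a in alphas) df[[sprintf("reject_a%g", a)]] <- !is.na(p) & p <= a
    df
  }))
  utils::write.table(long, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Power-by-scenario figure
#'
#' Dot-and-line plot of gene-level power per scenario for each method, one
#' panel per nominal level (log scale for genome-wide levels), mirroring
#' the study's power figure.  Requires ggplot2.
#'
#' @param summary the `power` element of [summarize_experiment()].
#' @return A ggplot object.
#' @export
plot_power <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_power() needs the ggplot2 package")
  }
  cols <- setdiff(names(summary), c("scenario", "inclusion", "m"))
  long <- do.call(rbind, lapply(cols, function(cl) {
    parts <- strsplit(cl, "_a", fixed = TRUE)[[1]]
    data.frame(
      scenario = summary$scenario, inclusion = summary$inclusion,
      method = parts[1], alpha = as.numeric(parts[2]), power = summary[[cl]]
    )
  }))
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = factor(.data$scenario), y = .data$power,
      colour = .data$method, group = .data$method
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::facet_grid(alpha ~ inclusion, scales = "free_y") +
    ggplot2::labs(x = "scenario", y = "gene-level rejection rate")
}
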