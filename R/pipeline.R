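#' Pipeline configuration
#'
#' Collects the inputs and thresholds of the end-to-end analysis. In
#' synthetic mode the study is generated by [simulate_study()]; otherwise
#' coverage files, pileups and a SNP mask are read from the given paths.
#'
#' @param synthetic Generate the inputs with the bundled simulator.
#' @param sim A [sim_config()] (synthetic mode).
#' @param coverage_files Named vector of Bismark coverage paths (by sample
#'   id); real-data mode.
#' @param meta Sample metadata data.frame (real-data mode).
#' @param pileups Named vector (\code{marine}, \code{fw}) of pileup paths.
#' @param snp_mask Path to the SNP mask, or NULL.
#' @param dm_threshold Methylation-difference threshold, percentage points
#'   (default 15).
#' @param alpha FDR cutoff (default 0.05).
#' @param rrbs_min_cov Minimum RRBS coverage in every sample (default 5).
#' @param min_qual Minimum pileup base quality (default 20).
#' @param pool_min_cov,min_count,max_cov Pool-seq filters (defaults 3, 2,
#'   1000).
#' @param match_window Non-DMC matching window, bp (default 2000).
#' @param n_ranks Ranks for the profile analyses (default 50).
#' @param covered_fraction_floor Coverage floor for rank/label exclusion
#'   (default 0.60).
#' @param excluded_chroms Chromosomes excluded from the site matrix.
#' @param pool_size Haploid pool sizes (used for real-data mode; synthetic
#'   mode takes them from \code{sim}).
#' @param seed Master seed.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(synthetic = TRUE, sim = sim_config(),
                            coverage_files = NULL, meta = NULL,
                            pileups = NULL, snp_mask = NULL,
                            dm_threshold = 15, alpha = 0.05,
                            rrbs_min_cov = 5L, min_qual = 20L,
                            pool_min_cov = 3L, min_count = 2L, max_cov = 1000L,
                            match_window = 2000L, n_ranks = 50L,
                            covered_fraction_floor = 0.60,
                            excluded_chroms = c("chrM", "chrXIX", "chrY"),
                            pool_size = c(marine = 24L, fw = 20L),
                            seed = 1L) {
  if (!(dm_threshold > 0 && dm_threshold <= 100)) {
    stop_config("dm_threshold must be in (0, 100]")
  }
  if (!(alpha > 0 && alpha <= 1)) stop_config("alpha must be in (0, 1]")
  stopifnot(rrbs_min_cov >= 1, min_qual >= 0, pool_min_cov >= min_count,
            min_count >= 1, max_cov >= pool_min_cov, match_window > 0,
            n_ranks >= 2, covered_fraction_floor >= 0, covered_fraction_floor <= 1)
  if (!synthetic) {
    if (is.null(coverage_files) || is.null(meta) || is.null(pileups)) {
      stop_config("real-data mode needs coverage_files, meta and pileups")
    }
  }
  structure(as.list(environment()), class = "pipeline_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", sep = "", file = con, append = TRUE)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Stages: site filtering; differential-methylation and inducibility
#' classification; distance-matched non-DMC subsampling; per-category and
#' per-rank diversity, Fst and SNP typing from the pool pileups; paired
#' per-chromosome statistics and rank trend fits; a markdown report. Every
#' stage's output is written as TSV under \code{out_dir} and the run is
#' reproducible given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Object of class \code{methdiv_run}: a named list of result tables
#'   plus \code{out_dir} and (synthetic mode) the \code{truth} table.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  cat(sprintf("methdiv %s | seed %d | %s\n", as.character(utils::packageVersion("methdiv")),
              config$seed, format(Sys.time(), "%Y-%m-%d")), file = logf)

  ## stage: inputs
  truth <- NULL
  if (config$synthetic) {
    sim <- config$sim
    sim$seed <- substream_seed(config$seed, "simulate")
    study <- simulate_study(sim, file.path(out_dir, "sim"))
    truth <- study$truth
    coverage_files <- study$coverage_files
    meta <- study$meta
    pileups <- study$pileups
    mask <- read_snp_mask(study$snp_mask)
    pool_size <- sim$pool_size
    log_line(logf, "stage simulate: %d sites, %d samples", nrow(truth), nrow(meta))
  } else {
    coverage_files <- config$coverage_files
    meta <- config$meta
    pileups <- config$pileups
    mask <- if (is.null(config$snp_mask)) NULL else read_snp_mask(config$snp_mask)
    pool_size <- config$pool_size
  }

  ## stage: filter
  calls <- lapply(coverage_files, read_bismark_coverage)
  main_ids <- meta$sample_id[meta$treatment == "native"]
  mat <- build_site_matrix(calls, meta, snp_mask = mask,
                           min_cov = config$rrbs_min_cov,
                           excluded_chroms = config$excluded_chroms,
                           drop_invariant_over = main_ids)
  log_line(logf, "stage filter: %d sites retained from %d samples",
           nrow(mat$sites), nrow(meta))

  grp <- function(popn, trt) meta$sample_id[meta$population == popn & meta$treatment == trt]

  ## stage: DM + inducibility
  dm_pop <- classify_sites(test_dm(mat, grp("marine", "native"), grp("freshwater", "native")),
                           config$dm_threshold, config$alpha)
  dm_mar <- classify_sites(test_dm(mat, grp("marine", "native"), grp("marine", "transplanted")),
                           config$dm_threshold, config$alpha)
  dm_fw <- classify_sites(test_dm(mat, grp("freshwater", "native"), grp("freshwater", "transplanted")),
                          config$dm_threshold, config$alpha)
  induc <- classify_inducibility(dm_pop, dm_mar, dm_fw)
  fwrite(dm_pop, file.path(out_dir, "dm_population.tsv"), sep = "\t")
  fwrite(induc, file.path(out_dir, "inducibility.tsv"), sep = "\t")
  n_cls <- table(dm_pop$site_class)
  log_line(logf, "stage dm: %d non-DMC, %d hypo, %d hyper",
           n_cls[["non_DMC"]], n_cls[["hypo"]], n_cls[["hyper"]])

  ## stage: matched subsampling of non-DMCs
  dmcs <- dm_pop[site_class != "non_DMC", .(chrom, pos)]
  nondmcs <- dm_pop[site_class == "non_DMC", .(chrom, pos)]
  sub <- subsample_non_dmcs(dmcs, nondmcs, window = config$match_window,
                            seed = substream_seed(config$seed, "match"))
  fwrite(sub$provenance, file.path(out_dir, "matched_subsample.tsv"), sep = "\t")
  log_line(logf, "stage match: %d matched non-DMCs from %d DMCs",
           nrow(sub$selected), nrow(dmcs))

  ## labels: chromosome x category over DMCs + matched non-DMCs
  lab_sites <- rbind(
    dm_pop[site_class != "non_DMC", .(chrom, pos, class = as.character(site_class))],
    sub$selected[, .(chrom, pos, class = "non_DMC")])
  chr_labels <- lab_sites[, .(chrom, pos, label = paste(chrom, class, sep = "|"))]
  cat_labels <- lab_sites[, .(chrom, pos, label = class)]

  ## stage: pool-seq diversity
  params <- list(marine = pool_params(pool_size[["marine"]], config$min_count,
                                      config$pool_min_cov, config$max_cov),
                 fw = pool_params(pool_size[["fw"]], config$min_count,
                                  config$pool_min_cov, config$max_cov))
  recs <- lapply(pileups, parse_pileup, min_qual = config$min_qual)

  div_chr <- rbindlist(lapply(c("marine", "fw"), function(p) {
    d <- aggregate_diversity(recs[[p]], chr_labels, params[[p]],
                             config$covered_fraction_floor)
    d[, population := p]
    d
  }))
  div_cat <- rbindlist(lapply(c("marine", "fw"), function(p) {
    d <- aggregate_diversity(recs[[p]], cat_labels, params[[p]],
                             config$covered_fraction_floor)
    d[, population := p]
    d
  }))
  fwrite(div_chr, file.path(out_dir, "diversity_by_chrom_category.tsv"), sep = "\t")
  fwrite(div_cat, file.path(out_dir, "diversity_by_category.tsv"), sep = "\t")
  log_line(logf, "stage diversity: %d chromosome x category labels", nrow(div_chr))

  ## stage: Fst
  fst_chr <- pairwise_fst(recs$marine, recs$fw, chr_labels,
                          params$marine, params$fw)
  fst_cat <- pairwise_fst(recs$marine, recs$fw, cat_labels,
                          params$marine, params$fw)
  fwrite(fst_chr, file.path(out_dir, "fst_by_chrom_category.tsv"), sep = "\t")
  fwrite(fst_cat, file.path(out_dir, "fst_by_category.tsv"), sep = "\t")

  ## stage: SNP typing
  snp_pct <- rbindlist(lapply(c("marine", "fw"), function(p) {
    snps <- call_biallelic_snps(recs[[p]], lab_sites[, .(chrom, pos)],
                                min_count = config$min_count)
    d <- snp_type_percentages(snps, chr_labels)
    d[, population := p]
    d
  }))
  snp_share <- rbindlist(lapply(c("marine", "fw"), function(p) {
    snps <- call_biallelic_snps(recs[[p]], lab_sites[, .(chrom, pos)],
                                min_count = config$min_count)
    data.table(population = p, n_snps = nrow(snps),
               pct_ctga_of_snps = 100 * mean(snps$snp_type == "CT_GA"))
  }))
  fwrite(snp_pct, file.path(out_dir, "snp_percentages.tsv"), sep = "\t")
  fwrite(snp_share, file.path(out_dir, "snp_type_share.tsv"), sep = "\t")
  log_line(logf, "stage snps: CT/GA share marine %.1f%%, fw %.1f%%",
           snp_share$pct_ctga_of_snps[1], snp_share$pct_ctga_of_snps[2])

  ## stage: rank profiles (mean PM per class x population; inducibility)
  rank_tabs <- list()
  for (p in c("marine", "fw")) {
    popn <- if (p == "marine") "marine" else "freshwater"
    summ <- methylation_summary(mat, grp(popn, "native"))
    for (cl in c("non_DMC", "hypo", "hyper")) {
      sites_cl <- lab_sites[class == cl, .(chrom, pos)]
      vals <- merge(summ, sites_cl, by = c("chrom", "pos"))
      if (nrow(vals) < config$n_ranks * 2) next
      asg <- assign_ranks(vals[, .(chrom, pos, value = mean_pm)], config$n_ranks)
      rp <- rank_diversity(asg, recs[[p]], params[[p]], config$covered_fraction_floor)
      rp[, `:=`(population = p, variable = "mean_pm", category = cl)]
      rank_tabs[[paste(p, cl)]] <- rp
    }
  }
  trend_fits <- list()
  for (p in c("marine", "fw")) {
    col <- if (p == "marine") "abs_induced_change_marine" else "abs_induced_change_fw"
    ind_sites <- induc[site_class != "non_DMC" & !is.na(get(col)),
                       .(chrom, pos, value = get(col))]
    if (nrow(ind_sites) >= config$n_ranks * 2) {
      asg <- assign_ranks(ind_sites, config$n_ranks)
      rp <- rank_diversity(asg, recs[[p]], params[[p]], config$covered_fraction_floor)
      rp[, `:=`(population = p, variable = "abs_induced_change", category = "DMC")]
      rank_tabs[[paste(p, "induced")]] <- rp
      use <- rp[excluded == FALSE]
      tf <- fit_linear_trend(use$mean_value, use$pi,
                             response = paste0("pi_", p),
                             predictor = "abs_induced_change")
      trend_fits[[p]] <- data.table(population = p, response = "pi",
                                    predictor = "abs_induced_change",
                                    slope = tf$slope, r2 = tf$r2,
                                    adj_r2 = tf$adj_r2, p_value = tf$p_value,
                                    n_ranks = tf$n)
    }
  }
  ranks <- rbindlist(rank_tabs, use.names = TRUE, fill = TRUE)
  trends <- rbindlist(trend_fits)
  if (nrow(ranks)) fwrite(ranks, file.path(out_dir, "rank_profiles.tsv"), sep = "\t")
  if (nrow(trends)) fwrite(trends, file.path(out_dir, "trend_fits.tsv"), sep = "\t")

  ## stage: paired statistics
  paired <- run_paired_stats(div_chr, fst_chr, snp_pct, induc, chr_labels)
  fwrite(paired, file.path(out_dir, "paired_comparisons.tsv"), sep = "\t")
  log_line(logf, "stage stats: %d paired comparisons, %d trend fits",
           nrow(paired), nrow(trends))

  write_report(out_dir, mat, dm_pop, induc, sub, div_cat, fst_cat, snp_share,
               paired, trends)

  structure(list(out_dir = out_dir, truth = truth, matrix = mat,
                 dm_population = dm_pop, inducibility = induc,
                 matched_subsample = sub,
                 diversity_by_chrom = div_chr, diversity_by_category = div_cat,
                 fst_by_chrom = fst_chr, fst_by_category = fst_cat,
                 snp_percentages = snp_pct, snp_type_share = snp_share,
                 rank_profiles = ranks, trend_fits = trends,
                 paired_comparisons = paired),
            class = "methdiv_run")
}

# per-chromosome paired tests over categories and populations
run_paired_stats <- function(div_chr, fst_chr, snp_pct, induc, chr_labels) {
  split_lab <- function(dt) {
    dt <- copy_dt(dt)
    dt[, c("chromv", "category") := tstrsplit(label, "|", fixed = TRUE)]
    dt
  }
  dv <- split_lab(div_chr)
  fs <- split_lab(fst_chr)
  sp <- split_lab(snp_pct)

  res <- list()
  add <- function(metric, cat, gA, gB, vA, vB) {
    if (length(intersect(names(vA), names(vB))) < 3) return()
    pc <- paired_compare(vA, vB, metric = metric, groupA = gA, groupB = gB)
    res[[length(res) + 1]] <<- data.table(
      metric = metric, category = cat, groupA = gA, groupB = gB,
      n_pairs = pc$n_pairs, shapiro_p = pc$shapiro_p, test_used = pc$test_used,
      p_value = pc$p_value, mean_diff = pc$mean_diff, degenerate = pc$degenerate)
  }
  vec <- function(dt, valcol, popn, cat) {
    sub <- dt[population == popn & category == cat & !is.na(get(valcol))]
    setNames(sub[[valcol]], sub$chromv)
  }
  for (cat in c("non_DMC", "hypo", "hyper")) {
    for (mcol in c("pi", "theta_w", "tajimas_d")) {
      add(mcol, cat, "marine", "fw",
          vec(dv, mcol, "marine", cat), vec(dv, mcol, "fw", cat))
    }
    add("pct_ctga", cat, "marine", "fw",
        vec(sp, "pct_ctga", "marine", cat), vec(sp, "pct_ctga", "fw", cat))
  }
  # category contrasts within population (DMC vs non-DMC baseline)
  for (p in c("marine", "fw")) {
    for (cat in c("hypo", "hyper")) {
      add("pi", paste0(cat, "_vs_non_DMC_", p), "non_DMC", cat,
          vec(dv, "pi", p, "non_DMC"), vec(dv, "pi", p, cat))
    }
  }
  fvec <- function(cat) {
    sub <- fs[category == cat & !is.na(fst)]
    setNames(sub$fst, sub$chromv)
  }
  add("fst", "hypo_vs_non_DMC", "non_DMC", "hypo", fvec("non_DMC"), fvec("hypo"))
  add("fst", "hyper_vs_non_DMC", "non_DMC", "hyper", fvec("non_DMC"), fvec("hyper"))

  # % induced per chromosome and class, marine vs fw
  icls <- merge(induc, chr_labels[, .(chrom, pos)], by = c("chrom", "pos"))
  for (cat in c("non_DMC", "hypo", "hyper")) {
    sub <- icls[site_class == cat]
    if (!nrow(sub)) next
    pm <- sub[, .(v = 100 * mean(induced_marine)), by = chrom]
    pf <- sub[, .(v = 100 * mean(induced_fw)), by = chrom]
    add("pct_induced", cat, "marine", "fw",
        setNames(pm$v, pm$chrom), setNames(pf$v, pf$chrom))
  }
  rbindlist(res)
}

copy_dt <- function(dt) data.table::copy(as.data.table(dt))

write_report <- function(out_dir, mat, dm_pop, induc, sub, div_cat, fst_cat,
                         snp_share, paired, trends) {
  n_cls <- table(dm_pop$site_class)
  lines <- c(
    "# Differential methylation x nucleotide diversity: run report", "",
    sprintf("- retained CpG sites: %d across %d samples", nrow(mat$sites), nrow(mat$meta)),
    sprintf("- site classes: %d non-DMC, %d FW-hypo, %d FW-hyper",
            n_cls[["non_DMC"]], n_cls[["hypo"]], n_cls[["hyper"]]),
    sprintf("- matched non-DMC subsample: %d sites (window %d bp)",
            nrow(sub$selected), sub$window),
    "", "## Per-category diversity", "",
    "| population | category | pi | theta_w | Tajima's D | covered fraction |",
    "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(div_cat))) {
    r <- div_cat[i]
    lines <- c(lines, sprintf("| %s | %s | %.5f | %.5f | %s | %.3f |",
                              r$population, r$label, r$pi, r$theta_w,
                              ifelse(is.na(r$tajimas_d), "NA", sprintf("%.3f", r$tajimas_d)),
                              r$covered_fraction))
  }
  lines <- c(lines, "", "## Pairwise Fst by category", "")
  for (i in seq_len(nrow(fst_cat))) {
    lines <- c(lines, sprintf("- %s: Fst = %.5f (%d sites)",
                              fst_cat$label[i], fst_cat$fst[i], fst_cat$n_sites[i]))
  }
  lines <- c(lines, "",
             sprintf("C-T/G-A share of biallelic SNPs: marine %.1f%%, freshwater %.1f%%",
                     snp_share$pct_ctga_of_snps[1], snp_share$pct_ctga_of_snps[2]),
             "", "## Paired per-chromosome comparisons", "",
             "| metric | category | A | B | test | p |", "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(paired))) {
    r <- paired[i]
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %.4g |",
                              r$metric, r$category, r$groupA, r$groupB,
                              r$test_used, r$p_value))
  }
  if (nrow(trends)) {
    lines <- c(lines, "", "## Rank trend fits", "")
    for (i in seq_len(nrow(trends))) {
      r <- trends[i]
      lines <- c(lines, sprintf("- %s: pi ~ %s slope %.4g, adj R2 %.2f, p %.3g",
                                r$population, r$predictor, r$slope, r$adj_r2, r$p_value))
    }
  }
  writeLines(lines, file.path(out_dir, "report.md"))
}

#' @export
print.methdiv_run <- function(x, ...) {
  n_cls <- table(x$dm_population$site_class)
  cat("methdiv pipeline run\n")
  cat(sprintf("  sites: %d (%d non-DMC, %d hypo, %d hyper)\n",
              nrow(x$dm_population), n_cls[["non_DMC"]], n_cls[["hypo"]], n_cls[["hyper"]]))
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}
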