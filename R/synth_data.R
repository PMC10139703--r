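#' Synthetic-study configuration
#'
#' Defines the generating model for a synthetic marine/freshwater RRBS +
#' pool-seq study with exact ground truth. Defaults emulate the study design
#' the analysis assumes: 11 RRBS samples (3 marine native, 3 freshwater
#' native, 3 marine transplanted, 2 freshwater transplanted), pools of 12 and
#' 10 diploid individuals (24 and 20 haploids) at mean depths 10.4x and 8x, a
#' bimodal percent-methylation distribution at non-DMCs, directional shifts
#' of at least 25 percentage points at DMCs, class-dependent polymorphism
#' enrichment with a C-T/G-A share of 0.90 (marine) / 0.94 (freshwater), and
#' a bottleneck-reduced derived (freshwater) population.
#'
#' @param n_sites Named integer vector of site counts per class
#'   (\code{non_DMC}, \code{hypo}, \code{hyper}).
#' @param n_chroms Number of synthetic chromosomes (2..12).
#' @param spacing Range (bp) of inter-site gaps drawn uniformly.
#' @param chrom_length Optional fixed chromosome length; an error is raised
#'   if the placed sites exceed it.
#' @param pool_size Haploid pool sizes, named \code{marine}, \code{fw}.
#' @param pool_depth Mean pool-seq depths per population.
#' @param rrbs_depth Mean RRBS coverage per sample.
#' @param rrbs_floor Minimum emitted RRBS coverage (set 0 to disable).
#' @param nondmc_high_weight Weight of the highly methylated mode of the
#'   non-DMC beta mixture.
#' @param nondmc_beta_low,nondmc_beta_high Beta shape pairs of the two modes.
#' @param hypo_marine_beta,hyper_marine_beta Beta shapes of the marine
#'   (ancestral) percent-methylation distribution for the two DMC classes.
#' @param dmc_shift Range of the between-population methylation shift at
#'   DMCs (proportion scale).
#' @param precision Between-individual beta precision per class and
#'   population (larger = less inter-individual variability).
#' @param p_poly Marine polymorphism probability per class (hyper > hypo >
#'   non-DMC gives the heterozygosity ordering the study reports).
#' @param bottleneck Factor (< 1) scaling freshwater polymorphism
#'   probability.
#' @param maf_beta Beta shapes of the population alternate-allele frequency
#'   at polymorphic sites.
#' @param ctga_share Probability that a polymorphic site is a C-T/G-A
#'   transition, per population.
#' @param induced_frac Target fraction of sites per class induced in either
#'   population (converted internally to a per-population rate).
#' @param induced_shift Range of the absolute induced methylation change at
#'   induced sites (proportion scale).
#' @param mask_frac Fraction of sites carrying a simulated C-T SNP in RRBS
#'   individuals; these go into the emitted SNP mask.
#' @param flank Number of monomorphic flanking pileup positions emitted on
#'   each side of every site.
#' @param seed Master seed; each emitter draws from a named substream.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(n_sites = c(non_DMC = 5000L, hypo = 4500L, hyper = 750L),
                       n_chroms = 6L,
                       spacing = c(100L, 900L),
                       chrom_length = NULL,
                       pool_size = c(marine = 24L, fw = 20L),
                       pool_depth = c(marine = 10.4, fw = 8.0),
                       rrbs_depth = 20,
                       rrbs_floor = 5L,
                       nondmc_high_weight = 0.55,
                       nondmc_beta_low = c(0.6, 12),
                       nondmc_beta_high = c(12, 0.6),
                       hypo_marine_beta = c(9, 1.8),
                       hyper_marine_beta = c(2.2, 6),
                       dmc_shift = c(0.25, 0.60),
                       precision = list(non_DMC = c(marine = 60, fw = 60),
                                        hypo = c(marine = 40, fw = 10),
                                        hyper = c(marine = 12, fw = 40)),
                       p_poly = c(non_DMC = 0.05, hypo = 0.10, hyper = 0.16),
                       bottleneck = 0.7,
                       maf_beta = c(0.5, 1.5),
                       ctga_share = c(marine = 0.90, fw = 0.94),
                       induced_frac = c(non_DMC = 0.038, hypo = 0.113, hyper = 0.392),
                       induced_shift = c(0.25, 0.50),
                       mask_frac = 0.02,
                       flank = 1L,
                       seed = 1L) {
  stopifnot(all(n_sites >= 0), all(names(n_sites) == c("non_DMC", "hypo", "hyper")),
            n_chroms >= 2, n_chroms <= 12,
            all(pool_size >= 2), all(pool_depth > 0),
            all(p_poly >= 0 & p_poly <= 1), bottleneck > 0, bottleneck <= 1,
            all(induced_frac >= 0 & induced_frac <= 1),
            all(ctga_share >= 0 & ctga_share <= 1), mask_frac >= 0, mask_frac <= 1)
  cfg <- as.list(environment())
  cfg$design <- data.frame(
    sample_id = c("M1", "M2", "M3", "F1", "F2", "F3", "MT1", "MT2", "MT3", "FT1", "FT2"),
    population = c(rep("marine", 3), rep("freshwater", 3),
                   rep("marine", 3), rep("freshwater", 2)),
    treatment = c(rep("native", 6), rep("transplanted", 5)),
    stringsAsFactors = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

rbeta_clamped <- function(n, mean, phi) {
  m <- pmin(pmax(mean, 0), 1)
  out <- numeric(n)
  edge <- m <= 0 | m >= 1
  out[edge] <- m[edge]
  if (any(!edge)) {
    out[!edge] <- rbeta(sum(!edge), m[!edge] * phi[!edge], (1 - m[!edge]) * phi[!edge])
  }
  out
}

#' Simulate the ground truth of a synthetic study
#'
#' Sites are placed along the configured chromosomes with uniformly drawn
#' gaps, class labels permuted at random, per-population methylation means
#' drawn from the class mixture model, induced flags and shifts drawn per
#' population, and polymorphism indicators, alternate-allele frequencies and
#' SNP types drawn per population (freshwater scaled by the bottleneck
#' factor). Reproducible given the config seed.
#'
#' @param config A [sim_config()].
#' @return data.table (the truth table), one row per site.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "truth"), {
    N <- sum(config$n_sites)
    chroms <- paste0("chr", as.character(utils::as.roman(seq_len(config$n_chroms))))
    chrom <- sort(sample(chroms, N, replace = TRUE))
    pos <- integer(N)
    for (ch in chroms) {
      idx <- which(chrom == ch)
      gaps <- round(runif(length(idx), config$spacing[1], config$spacing[2]))
      pos[idx] <- cumsum(gaps) + 1000L
    }
    if (!is.null(config$chrom_length) && N > 0 && max(pos) > config$chrom_length) {
      stop_config("class counts exceed chromosome capacity (max position %d > length %d)",
                  max(pos), config$chrom_length)
    }
    cls <- sample(rep(names(config$n_sites), times = config$n_sites))
    dt <- data.table(chrom = chrom, pos = as.integer(pos),
                     class = factor(cls, levels = c("non_DMC", "hypo", "hyper")))

    # population methylation means
    n_nd <- sum(cls == "non_DMC")
    pm_m <- numeric(N)
    hi <- runif(n_nd) < config$nondmc_high_weight
    pm_nd <- numeric(n_nd)
    pm_nd[hi] <- rbeta(sum(hi), config$nondmc_beta_high[1], config$nondmc_beta_high[2])
    pm_nd[!hi] <- rbeta(sum(!hi), config$nondmc_beta_low[1], config$nondmc_beta_low[2])
    pm_m[cls == "non_DMC"] <- pm_nd
    pm_m[cls == "hypo"] <- rbeta(sum(cls == "hypo"),
                                 config$hypo_marine_beta[1], config$hypo_marine_beta[2])
    pm_m[cls == "hyper"] <- rbeta(sum(cls == "hyper"),
                                  config$hyper_marine_beta[1], config$hyper_marine_beta[2])
    shift <- runif(N, config$dmc_shift[1], config$dmc_shift[2])
    pm_f <- pm_m
    pm_f[cls == "hypo"] <- pmax(pm_m[cls == "hypo"] - shift[cls == "hypo"], 0.02)
    pm_f[cls == "hyper"] <- pmin(pm_m[cls == "hyper"] + shift[cls == "hyper"], 0.98)
    # keep the DMC contrast at >= 25 points even after clamping
    pm_m[cls == "hypo"] <- pmax(pm_m[cls == "hypo"], pm_f[cls == "hypo"] + 0.25)
    pm_m[cls == "hyper"] <- pmin(pm_m[cls == "hyper"], pm_f[cls == "hyper"] - 0.25)
    dt[, pm_marine := pm_m]
    dt[, pm_fw := pm_f]
    dt[, phi_marine := vapply(as.character(class), function(k) config$precision[[k]]["marine"], 0)]
    dt[, phi_fw := vapply(as.character(class), function(k) config$precision[[k]]["fw"], 0)]

    # inducibility: per-population rate q with P(either) = induced_frac
    q <- 1 - sqrt(1 - config$induced_frac[as.character(cls)])
    dt[, induced_marine := runif(N) < q]
    dt[, induced_fw := runif(N) < q]
    dt[, induced_shift_marine := ifelse(induced_marine,
                                        runif(N, config$induced_shift[1], config$induced_shift[2]),
                                        NA_real_)]
    dt[, induced_shift_fw := ifelse(induced_fw,
                                    runif(N, config$induced_shift[1], config$induced_shift[2]),
                                    NA_real_)]

    # polymorphism per population
    pp_m <- config$p_poly[as.character(cls)]
    dt[, poly_marine := runif(N) < pp_m]
    dt[, poly_fw := runif(N) < pp_m * config$bottleneck]
    dt[, p_alt_marine := ifelse(poly_marine,
                                0.02 + 0.96 * rbeta(N, config$maf_beta[1], config$maf_beta[2]), 0)]
    dt[, p_alt_fw := ifelse(poly_fw,
                            0.02 + 0.96 * rbeta(N, config$maf_beta[1], config$maf_beta[2]), 0)]

    # site alleles: CpG reference strand C or G; SNP type per site
    dt[, ref := sample(c("C", "G"), N, replace = TRUE)]
    share <- ifelse(dt$poly_marine, config$ctga_share["marine"], config$ctga_share["fw"])
    snp_type <- ifelse(dt$poly_marine | dt$poly_fw,
                       ifelse(runif(N) < share, "CT_GA", "other"), NA_character_)
    other_pick <- sample(c(1L, 2L), N, replace = TRUE)
    alt <- rep(NA_character_, N)
    is_ct <- !is.na(snp_type) & snp_type == "CT_GA"
    is_ot <- !is.na(snp_type) & snp_type == "other"
    alt[is_ct] <- ifelse(dt$ref[is_ct] == "C", "T", "A")
    alt[is_ot] <- ifelse(dt$ref[is_ot] == "C",
                         c("A", "G")[other_pick[is_ot]],
                         c("T", "C")[other_pick[is_ot]])
    dt[, snp_type := snp_type]
    dt[, alt := alt]

    # sites with a C-T SNP segregating among the RRBS individuals -> mask
    dt[, rrbs_snp := runif(N) < config$mask_frac]
    dt[]
  })
}

#' Emit Bismark-style coverage files from the truth
#'
#' Per site and sample: an individual methylation level is drawn from a beta
#' distribution centred on the population mean (class/population precision),
#' coverage from a floored Poisson, and the methylated count binomially.
#' Transplanted samples use the induced-shifted mean at induced sites (the
#' shift moves the level towards the opposite extreme; the analysis ignores
#' its direction).
#'
#' @param truth [simulate_truth()] output.
#' @param config The [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths (one per sample).
#' @export
emit_rrbs <- function(truth, config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(substream_seed(config$seed, "rrbs"), {
    N <- nrow(truth)
    paths <- character(0)
    for (i in seq_len(nrow(config$design))) {
      s <- config$design[i, ]
      pop <- if (s$population == "marine") "marine" else "fw"
      m <- if (pop == "marine") truth$pm_marine else truth$pm_fw
      phi <- if (pop == "marine") truth$phi_marine else truth$phi_fw
      if (s$treatment == "transplanted") {
        ind <- if (pop == "marine") truth$induced_marine else truth$induced_fw
        sh <- if (pop == "marine") truth$induced_shift_marine else truth$induced_shift_fw
        dirn <- ifelse(m > 0.5, -1, 1)
        m <- ifelse(ind, pmin(pmax(m + dirn * sh, 0.02), 0.98), m)
      }
      ind_pm <- rbeta_clamped(N, m, phi)
      cov <- rpois(N, config$rrbs_depth)
      if (config$rrbs_floor > 0) cov <- pmax(cov, config$rrbs_floor)
      meth <- rbinom(N, cov, ind_pm)
      out <- data.table(chrom = truth$chrom, start = truth$pos, end = truth$pos,
                        pct = round(100 * meth / pmax(cov, 1), 2),
                        count_meth = meth, count_unmeth = cov - meth)
      path <- file.path(dir, paste0(s$sample_id, ".cov"))
      fwrite(out, path, sep = "\t", col.names = FALSE)
      paths[s$sample_id] <- path
    }
    paths
  })
}

#' Emit pool-seq pileup files from the truth
#'
#' Two-stage sampling per site and population: the realised pool alternate
#' count among the n haploids is binomial in the population frequency, then
#' reads are drawn binomially from the pool frequency at Poisson depth.
#' All emitted base qualities are phred 40 (above the default filter);
#' monomorphic flanking positions are emitted around every site so windowed
#' statistics see a local background. Zero-depth positions are omitted, as
#' in real pileups.
#'
#' @param truth [simulate_truth()] output.
#' @param config The [sim_config()].
#' @param dir Output directory.
#' @return Named character vector of pileup paths
#'   (\code{marine}, \code{fw}).
#' @export
emit_poolseq <- function(truth, config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(substream_seed(config$seed, "pool"), {
    paths <- character(0)
    for (pop in c("marine", "fw")) {
      n <- config$pool_size[[pop]]
      depth_mean <- config$pool_depth[[pop]]
      p_alt <- if (pop == "marine") truth$p_alt_marine else truth$p_alt_fw
      N <- nrow(truth)

      depth <- rpois(N, depth_mean)
      k <- rbinom(N, n, p_alt)
      n_alt <- rbinom(N, depth, k / n)
      alt <- ifelse(is.na(truth$alt), "N", truth$alt)

      rows <- list(data.table(
        chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
        depth = depth,
        bases = paste0(strrep(".", depth - n_alt), strrep(alt, n_alt))))
      if (config$flank > 0) {
        for (f in seq_len(config$flank)) {
          for (sgn in c(-1L, 1L)) {
            fd <- rpois(N, depth_mean)
            rows[[length(rows) + 1]] <- data.table(
              chrom = truth$chrom, pos = truth$pos + sgn * 10L * f,
              ref = truth$ref, depth = fd, bases = strrep(".", fd))
          }
        }
      }
      all <- rbindlist(rows)
      all <- all[depth > 0]
      setorder(all, chrom, pos)
      all[, qual := strrep("I", depth)]
      path <- file.path(dir, paste0(pop, ".pileup"))
      fwrite(all[, .(chrom, pos, ref, depth, bases, qual)], path,
             sep = "\t", col.names = FALSE, quote = FALSE)
      paths[pop] <- path
    }
    paths
  })
}

#' Generate a complete synthetic study on disk
#'
#' Runs [simulate_truth()], [emit_rrbs()] and [emit_poolseq()], and writes
#' the truth table, the SNP mask (sites simulated as C-T polymorphic among
#' the RRBS individuals) and the sample metadata.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return List: \code{truth}, \code{meta}, \code{coverage_files},
#'   \code{pileups}, \code{snp_mask}, \code{truth_file}.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_truth(config)
  cov_files <- emit_rrbs(truth, config, file.path(dir, "rrbs"))
  pileups <- emit_poolseq(truth, config, file.path(dir, "pool"))
  mask_file <- file.path(dir, "snp_mask.tsv")
  fwrite(truth[rrbs_snp == TRUE, .(chrom, pos)], mask_file,
         sep = "\t", col.names = FALSE)
  truth_file <- file.path(dir, "truth.tsv")
  fwrite(truth, truth_file, sep = "\t")
  list(truth = truth, meta = config$design, coverage_files = cov_files,
       pileups = pileups, snp_mask = mask_file, truth_file = truth_file)
}
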