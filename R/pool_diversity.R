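#' Estimator parameters for pooled-sequencing diversity
#'
#' @param pool_size Number of haploid genomes in the pool (2x diploid
#'   individuals), >= 2.
#' @param min_count Minimum reads supporting an allele for it to be treated
#'   as real rather than sequencing error (default 2).
#' @param min_cov,max_cov Coverage bounds applied after the min-count filter
#'   (defaults 3 and 1000).
#' @param correction_mode \code{"pool_corrected"} (default) divides the naive
#'   per-site statistics by their expected value for a site segregating in a
#'   pool of \code{pool_size} haploids under binomial read sampling and the
#'   min-count filter; \code{"naive"} reports the uncorrected statistics.
#' @return An object of class \code{pool_params}.
#' @export
pool_params <- function(pool_size, min_count = 2L, min_cov = 3L,
                        max_cov = 1000L,
                        correction_mode = c("pool_corrected", "naive")) {
  correction_mode <- match.arg(correction_mode)
  stopifnot(pool_size >= 2, min_count >= 1, min_cov >= min_count,
            max_cov >= min_cov)
  structure(list(pool_size = as.integer(pool_size),
                 min_count = as.integer(min_count),
                 min_cov = as.integer(min_cov),
                 max_cov = as.integer(max_cov),
                 correction_mode = correction_mode),
            class = "pool_params")
}

## ---------------------------------------------------------------------------
## pileup parsing

BASES <- c("A", "C", "G", "T")

#' Parse a SAMtools pileup into quality-filtered allele counts
#'
#' Decodes the 6-column pileup format (chrom, pos, ref, depth, read bases,
#' base qualities; phred+33). \code{.}/\code{,} count as the reference base;
#' \code{ACGTacgt} count as stated; \code{^} (with its mapping-quality
#' character), \code{$} and indel runs (\code{+}/\code{-} with digit length)
#' are consumed without counting; \code{*}, \code{N} and reference skips are
#' dropped; bases with quality below \code{min_qual} are dropped. Lines whose
#' reference base is not one of ACGT are skipped with a warning.
#'
#' @param path Pileup file path.
#' @param min_qual Minimum base quality (default 20).
#' @return data.table with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{A}, \code{C}, \code{G}, \code{T} and \code{M} (post-filter
#'   coverage, the sum of the four counts).
#' @export
parse_pileup <- function(path, min_qual = 20L) {
  if (!file.exists(path)) stop_config("pileup file does not exist: %s", path)
  raw <- readLines(path)
  if (!length(raw)) {
    return(data.table(chrom = character(), pos = integer(), ref = character(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer(), M = integer()))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop_config("malformed pileup line %d in %s: expected 6 fields", which(nf < 6)[1], path)
  }
  chrom <- vapply(fields, `[`, "", 1L)
  pos <- as.integer(vapply(fields, `[`, "", 2L))
  ref <- toupper(vapply(fields, `[`, "", 3L))
  bases <- vapply(fields, `[`, "", 5L)
  quals <- vapply(fields, `[`, "", 6L)

  bad_ref <- !(ref %in% BASES)
  if (any(bad_ref)) {
    warning(sprintf("%d pileup records with unknown reference base skipped", sum(bad_ref)))
  }

  counts <- matrix(0L, length(raw), 4, dimnames = list(NULL, BASES))

  simple <- !grepl("[^.,ACGTacgtNn*]", bases)
  low <- if (min_qual > 0) {
    grepl(sprintf("[\\x21-\\x%x]", 0x20 + as.integer(min_qual)), quals, perl = TRUE)
  } else rep(FALSE, length(raw))
  fast <- simple & !low & !bad_ref

  if (any(fast)) {
    b <- bases[fast]
    if (any(nchar(b) != nchar(quals[fast]))) {
      i <- which(fast)[which(nchar(b) != nchar(quals[fast]))[1]]
      stop_config("base/quality length mismatch at pileup line %d (%s:%d)",
                  i, chrom[i], pos[i])
    }
    cnt1 <- function(ch) nchar(b) - nchar(gsub(ch, "", b, fixed = TRUE))
    refcnt <- cnt1(".") + cnt1(",")
    for (nt in BASES) {
      counts[fast, nt] <- cnt1(nt) + cnt1(tolower(nt))
    }
    idx <- cbind(which(fast), match(ref[fast], BASES))
    counts[idx] <- counts[idx] + refcnt
  }

  slow <- which(!fast & !bad_ref)
  for (i in slow) {
    counts[i, ] <- decode_pileup_column(bases[i], quals[i], ref[i], min_qual,
                                        line = i, chrom = chrom[i], pos = pos[i])
  }

  out <- data.table(chrom = chrom, pos = pos, ref = ref,
                    A = counts[, "A"], C = counts[, "C"],
                    G = counts[, "G"], T = counts[, "T"])
  out <- out[!bad_ref]
  out[, M := A + C + G + T]
  out[]
}

# scalar decoder for pileup base columns containing indels, read start/end
# markers or sub-threshold qualities
decode_pileup_column <- function(bases, quals, ref, min_qual, line = NA,
                                 chrom = "", pos = NA) {
  ch <- strsplit(bases, "")[[1]]
  qv <- utf8ToInt(quals) - 33L
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  i <- 1L
  q <- 1L
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L            # caret plus encoded mapping quality
    } else if (c0 == "$") {
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {
      j <- i + 1L
      while (j <= n && ch[j] %in% as.character(0:9)) j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len           # skip the inserted/deleted sequence
    } else {
      if (q > length(qv)) {
        stop_config("base/quality length mismatch at pileup line %s (%s:%s)",
                    line, chrom, pos)
      }
      ok <- qv[q] >= min_qual
      q <- q + 1L
      b <- if (c0 %in% c(".", ",")) ref else toupper(c0)
      if (ok && b %in% BASES) counts[b] <- counts[b] + 1L
      i <- i + 1L
    }
  }
  if (q - 1L != length(qv)) {
    stop_config("base/quality length mismatch at pileup line %s (%s:%s)",
                line, chrom, pos)
  }
  counts
}

## ---------------------------------------------------------------------------
## per-site estimators and pool correction

.correction_cache <- new.env(parent = emptyenv())

# Expected naive pi for a site segregating in a pool of n haploids, reads
# binomial at coverage M, minor alleles below b discarded; pool allele counts
# weighted by the neutral 1/k spectrum (normalised so the expected true
# heterozygosity is 1). Reduces to (n-1)/n when b = 0 and all read
# configurations are observable.
pool_correction_pi <- function(M, n, b) {
  key <- sprintf("pi_%d_%d_%d", M, n, b)
  if (!is.null(.correction_cache[[key]])) return(.correction_cache[[key]])
  val <- 0
  if (M >= max(2, 2 * b)) {
    r <- b:(M - b)
    pi_cfg <- (M / (M - 1)) * 2 * (r / M) * ((M - r) / M)
    for (k in seq_len(n - 1)) {
      val <- val + (1 / k) * sum(dbinom(r, M, k / n) * pi_cfg)
    }
  }
  .correction_cache[[key]] <- val
  val
}

# Expected probability (neutral 1/k weights, normalised) that a segregating
# pool site is detected as segregating at coverage M under the min-count
# filter; corrected theta per segregating site is 1 / (a1(n) * this).
pool_correction_theta <- function(M, n, b) {
  key <- sprintf("th_%d_%d_%d", M, n, b)
  if (!is.null(.correction_cache[[key]])) return(.correction_cache[[key]])
  val <- 0
  if (M >= max(2, 2 * b)) {
    r <- b:(M - b)
    a1n <- harmonic1(n)
    for (k in seq_len(n - 1)) {
      val <- val + (1 / k) * sum(dbinom(r, M, k / n))
    }
    val <- val / a1n
  }
  .correction_cache[[key]] <- val
  val
}

#' Per-site diversity estimators from allele counts
#'
#' Applies the min-count and coverage filters and computes per-site pi (the
#' small-sample-corrected expected heterozygosity among reads, equal to the
#' number of pairwise differences divided by choose(M, 2)), the segregation
#' indicator S, and Watterson's theta. In \code{pool_corrected} mode pi and
#' theta are rescaled by the expected value of the naive statistic for a
#' segregating pool site (see [pool_params()]).
#'
#' @param records data.table from [parse_pileup()] (columns A, C, G, T).
#' @param params A [pool_params()] object.
#' @return \code{records} with added columns \code{excluded} (coverage out of
#'   bounds after filtering), \code{M_filt} (post-min-count coverage),
#'   \code{pi_site}, \code{theta_site}, \code{S_site} (NA for excluded
#'   sites).
#' @export
site_estimators <- function(records, params) {
  stopifnot(inherits(params, "pool_params"))
  dt <- as.data.table(records)
  cnt <- as.matrix(dt[, .(A, C, G, T)])
  cnt[cnt < params$min_count] <- 0L
  M <- rowSums(cnt)
  excluded <- M < params$min_cov | M > params$max_cov
  n_alleles <- rowSums(cnt > 0)
  S <- as.integer(n_alleles >= 2)

  sumf2 <- ifelse(M > 0, rowSums((cnt / pmax(M, 1))^2), 1)
  pi_naive <- ifelse(M >= 2, (M / (M - 1)) * (1 - sumf2), 0)
  uMall <- sort(unique(M))
  a1M <- vapply(uMall, harmonic1, 0)[match(M, uMall)]
  theta_naive <- ifelse(M >= 2, S / pmax(a1M, .Machine$double.eps), 0)

  if (params$correction_mode == "pool_corrected") {
    n <- params$pool_size
    b <- params$min_count
    uM <- sort(unique(M[!excluded & M >= 2]))
    cpi <- vapply(uM, pool_correction_pi, 0, n = n, b = b)
    cth <- vapply(uM, pool_correction_theta, 0, n = n, b = b)
    ipi <- cpi[match(M, uM)]
    ith <- cth[match(M, uM)]
    pi_out <- ifelse(pi_naive > 0 & !is.na(ipi) & ipi > 0, pi_naive / ipi, 0)
    theta_out <- ifelse(S > 0 & !is.na(ith) & ith > 0,
                        S / (harmonic1(n) * ith), 0)
  } else {
    pi_out <- pi_naive
    theta_out <- theta_naive
  }

  dt[, M_filt := M]
  dt[, excluded := excluded]
  dt[, pi_site := ifelse(excluded, NA_real_, pi_out)]
  dt[, theta_site := ifelse(excluded, NA_real_, theta_out)]
  dt[, S_site := ifelse(excluded, NA_integer_, S)]
  dt[]
}

## ---------------------------------------------------------------------------
## Tajima's D

#' Classical Tajima constants
#'
#' @param n Sample size (>= 2).
#' @return Named list with \code{a1}, \code{a2}, \code{b1}, \code{b2},
#'   \code{c1}, \code{c2}, \code{e1}, \code{e2}.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  a1 <- harmonic1(n)
  a2 <- harmonic2(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D from aggregated sums
#'
#' @param pi_sum Sum of per-site pairwise diversity over the site set.
#' @param S_total Number of segregating sites (>= 0).
#' @param n_eff Effective sample size used for the constants (>= 2).
#' @param n_sites Number of sites (unused by the statistic itself; kept for
#'   the record).
#' @return The normalised difference \eqn{(\pi - S/a_1)/\sqrt{Var}}, or
#'   \code{NA} when \code{S_total} is 0.
#' @export
tajimas_d <- function(pi_sum, S_total, n_eff, n_sites = NA) {
  if (S_total < 0) stop_config("S_total must be non-negative")
  if (S_total == 0) return(NA_real_)
  k <- tajima_constants(n_eff)
  (pi_sum - S_total / k$a1) /
    sqrt(k$e1 * S_total + k$e2 * S_total * (S_total - 1))
}

## ---------------------------------------------------------------------------
## label-level aggregation

#' Aggregate per-site diversity over labelled site sets
#'
#' Per label: pi and theta are per-site averages over covered (non-excluded)
#' labelled sites; covered_fraction is covered / labelled; Tajima's D is
#' computed from the naive per-site sums with effective sample size
#' min(pool haploids, median covered-site coverage). Labels whose covered
#' fraction falls below \code{min_covered_fraction} are flagged.
#'
#' @param records [parse_pileup()] output.
#' @param site_labels data.table with \code{chrom}, \code{pos}, \code{label};
#'   a site carries exactly one label per analysis.
#' @param params A [pool_params()] object.
#' @param min_covered_fraction Coverage floor for flagging (default 0.60).
#' @return data.table with one row per label: \code{label}, \code{pi},
#'   \code{theta_w}, \code{tajimas_d}, \code{n_sites} (covered),
#'   \code{n_labeled}, \code{covered_fraction}, \code{flagged}.
#' @export
aggregate_diversity <- function(records, site_labels, params,
                                min_covered_fraction = 0.60) {
  labels <- as.data.table(site_labels)
  if (anyDuplicated(labels[, .(chrom, pos)])) {
    stop_config("a site carries more than one label")
  }
  est <- site_estimators(records, params)
  # naive sums for Tajima's D regardless of correction mode
  naive <- if (params$correction_mode == "naive") est else {
    site_estimators(records, pool_params(params$pool_size, params$min_count,
                                         params$min_cov, params$max_cov,
                                         correction_mode = "naive"))
  }
  est[, pi_naive := naive$pi_site]
  m <- merge(labels, est, by = c("chrom", "pos"), all.x = TRUE)
  m[, covered := !is.na(excluded) & !excluded]
  res <- m[, {
    cov <- covered
    ns <- sum(cov)
    if (ns == 0) {
      list(pi = NA_real_, theta_w = NA_real_, tajimas_d = NA_real_,
           n_sites = 0L, n_labeled = .N, covered_fraction = 0)
    } else {
      S_tot <- sum(S_site[cov])
      n_eff <- min(params$pool_size, stats::median(M_filt[cov]))
      D <- if (n_eff >= 2) tajimas_d(sum(pi_naive[cov]), S_tot, n_eff, ns) else NA_real_
      list(pi = sum(pi_site[cov]) / ns,
           theta_w = sum(theta_site[cov]) / ns,
           tajimas_d = D,
           n_sites = as.integer(ns), n_labeled = .N,
           covered_fraction = ns / .N)
    }
  }, by = label]
  res[, flagged := covered_fraction < min_covered_fraction]
  res[]
}

## ---------------------------------------------------------------------------
## Fst

#' Pairwise Fst between two pools over labelled sites
#'
#' Classical heterozygosity-ratio form: per site, within-pool heterozygosities
#' \eqn{h_k = (M_k/(M_k-1)) (1 - \sum f_{a,k}^2)}; total heterozygosity from
#' the mean allele frequencies with the analogous small-sample factor using
#' the combined coverage; \eqn{F_{st} = (h_T - \bar h)/h_T}, defined when
#' \eqn{h_T > 0}. The label value is the mean of defined per-site values;
#' negative values are retained unless \code{clamp}. The min-count filter is
#' applied to counts summed across pools by default.
#'
#' @param recs1,recs2 [parse_pileup()] outputs for the two pools.
#' @param site_labels data.table (chrom, pos, label), or \code{NULL} with
#'   \code{window_size} set for windowed labels.
#' @param params1,params2 [pool_params()] per pool (min_count must agree).
#' @param min_count_mode \code{"summed"} (default) or \code{"per_pool"}.
#' @param clamp Clamp negative label means at zero for display (default
#'   FALSE).
#' @param window_size,step_size Optional non-overlapping windowed mode
#'   (requires \code{step_size == window_size}); labels become
#'   \code{chrom:window_start}.
#' @return data.table: \code{label}, \code{fst}, \code{n_sites} (sites with
#'   defined per-site Fst).
#' @export
pairwise_fst <- function(recs1, recs2, site_labels, params1, params2,
                         min_count_mode = c("summed", "per_pool"),
                         clamp = FALSE, window_size = NULL, step_size = NULL) {
  min_count_mode <- match.arg(min_count_mode)
  if (params1$min_count != params2$min_count) {
    stop_config("min_count must agree between pools")
  }
  b <- params1$min_count
  m <- merge(as.data.table(recs1)[, .(chrom, pos, A1 = A, C1 = C, G1 = G, T1 = T)],
             as.data.table(recs2)[, .(chrom, pos, A2 = A, C2 = C, G2 = G, T2 = T)],
             by = c("chrom", "pos"))
  if (!is.null(window_size)) {
    step_size <- step_size %||% window_size
    if (step_size != window_size) {
      stop_config("windowed Fst supports non-overlapping windows only (step == window)")
    }
    m[, label := sprintf("%s:%d", chrom, (pos - 1L) %/% as.integer(window_size) *
                           as.integer(window_size) + 1L)]
  } else {
    m <- merge(m, as.data.table(site_labels), by = c("chrom", "pos"))
  }
  if (!nrow(m)) return(data.table(label = character(), fst = numeric(), n_sites = integer()))

  c1 <- as.matrix(m[, .(A1, C1, G1, T1)])
  c2 <- as.matrix(m[, .(A2, C2, G2, T2)])
  if (min_count_mode == "summed") {
    drop <- (c1 + c2) < b
  } else {
    drop <- c1 < b | c2 < b
  }
  c1[drop] <- 0L
  c2[drop] <- 0L
  M1 <- rowSums(c1); M2 <- rowSums(c2)
  ok <- M1 >= params1$min_cov & M1 <= params1$max_cov &
        M2 >= params2$min_cov & M2 <= params2$max_cov & M1 >= 2 & M2 >= 2

  f1 <- c1 / pmax(M1, 1); f2 <- c2 / pmax(M2, 1)
  h1 <- (M1 / pmax(M1 - 1, 1)) * (1 - rowSums(f1^2))
  h2 <- (M2 / pmax(M2 - 1, 1)) * (1 - rowSums(f2^2))
  fbar <- (f1 + f2) / 2
  Mt <- M1 + M2
  hT <- (Mt / pmax(Mt - 1, 1)) * (1 - rowSums(fbar^2))
  fst <- ifelse(ok & hT > 0, (hT - (h1 + h2) / 2) / hT, NA_real_)

  m[, fst_site := fst]
  res <- m[, .(fst = mean(fst_site, na.rm = TRUE),
               n_sites = sum(!is.na(fst_site))), by = label]
  res[n_sites == 0, fst := NA_real_]
  if (clamp) res[, fst := pmax(fst, 0)]
  res[]
}

## ---------------------------------------------------------------------------
## SNP typing at CpG sites

#' Detect and type biallelic SNPs at listed sites
#'
#' Alleles with count >= \code{min_count} are retained; a site with exactly
#' two retained alleles yields a record typed \code{CT_GA} iff the unordered
#' allele pair is \{C,T\} or \{G,A\}, else \code{other}. Monomorphic and
#' tri-/tetra-allelic sites yield no record.
#'
#' @param records [parse_pileup()] output.
#' @param sites data.table (chrom, pos) restricting the scan, or \code{NULL}
#'   for all records.
#' @param min_count Allele detection threshold (default 2).
#' @return data.table: \code{chrom}, \code{pos}, \code{major_allele},
#'   \code{minor_allele}, \code{snp_type} (\code{CT_GA}/\code{other}).
#' @export
call_biallelic_snps <- function(records, sites = NULL, min_count = 2L) {
  dt <- as.data.table(records)
  if (!is.null(sites)) {
    dt <- merge(dt, as.data.table(sites)[, .(chrom, pos)], by = c("chrom", "pos"))
  }
  cnt <- as.matrix(dt[, .(A, C, G, T)])
  cnt[cnt < min_count] <- 0L
  nal <- rowSums(cnt > 0)
  bi <- nal == 2
  if (!any(bi)) {
    return(data.table(chrom = character(), pos = integer(),
                      major_allele = character(), minor_allele = character(),
                      snp_type = character()))
  }
  sub <- cnt[bi, , drop = FALSE]
  ord <- apply(sub, 1, function(x) order(x, decreasing = TRUE)[1:2])
  major <- BASES[ord[1, ]]
  minor <- BASES[ord[2, ]]
  pair <- paste(pmin(major, minor), pmax(major, minor))
  snp_type <- ifelse(pair %in% c("C T", "A G"), "CT_GA", "other")
  data.table(chrom = dt$chrom[bi], pos = dt$pos[bi],
             major_allele = major, minor_allele = minor, snp_type = snp_type)
}

#' Percentage of labelled sites harbouring SNPs of each type
#'
#' Denominators are all labelled sites (polymorphic or not).
#'
#' @param snps [call_biallelic_snps()] output.
#' @param site_labels data.table (chrom, pos, label).
#' @param all_sites Optional data.table (label, n_sites) overriding the
#'   denominators derived from \code{site_labels}.
#' @return data.table: \code{label}, \code{n_sites}, \code{pct_ctga},
#'   \code{pct_other}.
#' @export
snp_type_percentages <- function(snps, site_labels, all_sites = NULL) {
  labels <- as.data.table(site_labels)
  denom <- if (is.null(all_sites)) {
    labels[, .(n_sites = .N), by = label]
  } else as.data.table(all_sites)
  s <- merge(as.data.table(snps), labels, by = c("chrom", "pos"))
  num <- s[, .(n_ctga = sum(snp_type == "CT_GA"),
               n_other = sum(snp_type == "other")), by = label]
  out <- merge(denom, num, by = "label", all.x = TRUE)
  out[is.na(n_ctga), n_ctga := 0L]
  out[is.na(n_other), n_other := 0L]
  out[, pct_ctga := 100 * n_ctga / n_sites]
  out[, pct_other := 100 * n_other / n_sites]
  out[n_sites == 0, c("pct_ctga", "pct_other") := NA_real_]
  out[, c("n_ctga", "n_other") := NULL]
  out[]
}
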