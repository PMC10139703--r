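test_that("pileup columns decode reference matches, qualities and indels", {
  # all reference matches
  p1 <- write_lines_tmp("chrI\t100\tC\t4\t.,.,\tIIII")
  r1 <- parse_pileup(p1)
  expect_equal(r1$C, 4L)
  expect_equal(r1$M, 4L)

  # phred 40,2,40,40: the T at quality 2 fails the filter
  p2 <- write_lines_tmp("chrI\t100\tC\t4\t.T..\tI#II")
  r2 <- parse_pileup(p2, min_qual = 20)
  expect_equal(r2$C, 3L)
  expect_equal(r2$T, 0L)

  # insertion consumed without counting
  p3 <- write_lines_tmp("chrI\t100\tC\t2\t.+2AT.\tII")
  r3 <- parse_pileup(p3)
  expect_equal(r3$C, 2L)
  expect_equal(r3$M, 2L)

  # read start (^ + mapq), read end, deletion placeholder, N, lower case
  p4 <- write_lines_tmp("chrI\t7\tG\t6\t^I.,$t*Na\tIIIIII")
  r4 <- parse_pileup(p4)
  expect_equal(r4$G, 2L)
  expect_equal(r4$T, 1L)
  expect_equal(r4$A, 1L)
  expect_equal(r4$M, 4L)
})

test_that("pileup errors and unknown references are reported", {
  bad <- write_lines_tmp("chrI\t100\tC\t3\t...\tII")  # 3 bases, 2 quals
  expect_error(parse_pileup(bad), "mismatch")
  unk <- write_lines_tmp(c("chrI\t1\tN\t2\t..\tII", "chrI\t5\tC\t2\t..\tII"))
  expect_warning(res <- parse_pileup(unk), "unknown reference")
  expect_equal(nrow(res), 1L)
  expect_equal(res$pos, 5L)
})

test_that("per-site naive estimators match the worked examples", {
  params <- pool_params(20, min_count = 2, min_cov = 3, correction_mode = "naive")
  # {C:2, T:2}: 4 pairwise differences among C(4,2)=6 read pairs -> 2/3
  e1 <- site_estimators(make_records(C = 2L, T = 2L), params)
  expect_equal(e1$pi_site, 2 / 3)
  expect_equal(e1$S_site, 1L)
  # {C:9, T:1}, b=2: the singleton T is removed, site monomorphic
  e2 <- site_estimators(make_records(C = 9L, T = 1L), params)
  expect_equal(e2$pi_site, 0)
  expect_equal(e2$S_site, 0L)
  # {C:2} fails min_cov = 3
  e3 <- site_estimators(make_records(C = 2L), params)
  expect_true(e3$excluded)
  expect_true(is.na(e3$pi_site))
})

test_that("Tajima's D handles the boundary cases", {
  expect_equal(tajima_constants(4)$a1, 11 / 6)
  a1 <- tajima_constants(10)$a1
  expect_equal(tajimas_d(pi_sum = 5 / a1, S_total = 5, n_eff = 10), 0)
  expect_true(is.na(tajimas_d(0, 0, 10)))
  expect_error(tajimas_d(1, -1, 10), "non-negative")
})

test_that("aggregation is additive over any partition of a site set", {
  set.seed(12)
  n <- 300
  recs <- make_records(C = rpois(n, 6) + 2L, T = rbinom(n, 4, 0.3), pos = seq_len(n) * 10L)
  params <- pool_params(20, 2, 3)
  whole <- aggregate_diversity(recs, data.table(chrom = "chrI", pos = recs$pos, label = "all"), params)
  half <- sample(c("u", "v"), n, replace = TRUE)
  parts <- aggregate_diversity(recs, data.table(chrom = "chrI", pos = recs$pos, label = half), params)
  # coverage-weighted recombination of the parts equals the whole
  expect_equal(sum(parts$pi * parts$n_sites), whole$pi * whole$n_sites, tolerance = 1e-12)
  expect_equal(sum(parts$theta_w * parts$n_sites), whole$theta_w * whole$n_sites, tolerance = 1e-12)
  expect_equal(sum(parts$n_sites), whole$n_sites)
})

test_that("labels with insufficient coverage are flagged and empty ones absent", {
  recs <- make_records(C = c(5L, 5L, 1L), pos = c(10L, 20L, 30L))
  labels <- data.table(chrom = "chrI", pos = c(10L, 20L, 30L, 40L, 50L),
                       label = c("a", "a", "a", "a", "b"))
  params <- pool_params(20, 2, 3)
  agg <- aggregate_diversity(recs, labels, params, min_covered_fraction = 0.6)
  a <- agg[label == "a"]
  expect_equal(a$n_sites, 2L)           # 30 fails min_cov, 40 has no record
  expect_equal(a$covered_fraction, 0.5)
  expect_true(a$flagged)
  b <- agg[label == "b"]
  expect_true(is.na(b$pi))
  expect_equal(b$n_sites, 0L)
})

test_that("Fst honours the identity, fixation and symmetry contracts", {
  params <- pool_params(22, 2, 3)
  lab <- function(n) data.table(chrom = "chrI", pos = seq_len(n) * 10L, label = "x")
  # identical pools: no differentiation; the finite-coverage small-sample
  # factors leave a slightly negative value that vanishes as coverage grows
  # and is 0 under the clamp display option
  r <- make_records(C = c(10L, 8L), T = c(5L, 4L))
  f_id <- pairwise_fst(r, r, lab(2), params, params)$fst
  expect_lte(f_id, 0)
  expect_lt(abs(f_id), 0.06)
  big <- make_records(C = c(1000L, 800L), T = c(500L, 400L))
  params_hi <- pool_params(22, 2, 3, max_cov = 10000)
  expect_lt(abs(pairwise_fst(big, big, lab(2), params_hi, params_hi)$fst), 1e-3)
  expect_equal(pairwise_fst(r, r, lab(2), params, params, clamp = TRUE)$fst, 0)
  # fixed difference: approaches 1 with coverage
  prev <- 0
  for (N in c(10L, 50L, 500L)) {
    f <- pairwise_fst(make_records(C = N), make_records(T = N), lab(1),
                      params, params)$fst
    expect_gte(f, prev)
    prev <- f
  }
  expect_gt(prev, 0.99)
  # symmetry under pool relabelling and allele-name permutation
  r1 <- make_records(C = c(12L, 3L), T = c(2L, 9L))
  r2 <- make_records(C = c(5L, 8L), T = c(9L, 2L))
  f12 <- pairwise_fst(r1, r2, lab(2), params, params)$fst
  f21 <- pairwise_fst(r2, r1, lab(2), params, params)$fst
  expect_equal(f12, f21)
  swap <- function(x) { y <- copy(x); y[, c("A", "C", "G", "T") := .(T, G, C, A)]; y }
  fsw <- pairwise_fst(swap(r1), swap(r2), lab(2), params, params)$fst
  expect_equal(f12, fsw)
})

test_that("the summed min-count convention differs from per-pool as documented", {
  params <- pool_params(22, 2, 3)
  lab <- data.table(chrom = "chrI", pos = 10L, label = "x")
  # alt supported by 1 read in each pool: kept under summed (1+1 >= 2),
  # dropped per pool
  r1 <- make_records(C = 9L, T = 1L)
  r2 <- make_records(C = 9L, T = 1L)
  f_sum <- pairwise_fst(r1, r2, lab, params, params, min_count_mode = "summed")
  f_pp <- pairwise_fst(r1, r2, lab, params, params, min_count_mode = "per_pool")
  expect_equal(f_sum$n_sites, 1L)
  expect_equal(f_pp$n_sites, 0L)   # monomorphic after the filter: h_T = 0
})

test_that("biallelic SNP typing follows the unordered-pair rule", {
  recs <- make_records(A = c(0L, 3L, 2L, 0L, 1L),
                       C = c(8L, 0L, 8L, 9L, 9L),
                       G = c(0L, 7L, 0L, 0L, 0L),
                       T = c(4L, 0L, 2L, 0L, 0L),
                       pos = c(10L, 20L, 30L, 40L, 50L))
  snps <- call_biallelic_snps(recs, min_count = 2)
  expect_equal(snps$pos, c(10L, 20L))       # 30 triallelic, 40 monomorphic,
  expect_equal(snps$snp_type, c("CT_GA", "CT_GA"))  # 50 singleton alt
  expect_equal(snps$major_allele, c("C", "G"))
  expect_equal(snps$minor_allele, c("T", "A"))

  other <- call_biallelic_snps(make_records(C = 7L, G = 3L), min_count = 2)
  expect_equal(other$snp_type, "other")
})

test_that("SNP-type percentages use all labelled sites as denominator", {
  labels <- data.table(chrom = "chrI", pos = seq_len(10) * 10L, label = "cat")
  snps <- data.table(chrom = "chrI", pos = c(10L, 20L, 30L),
                     major_allele = "C", minor_allele = c("T", "T", "G"),
                     snp_type = c("CT_GA", "CT_GA", "other"))
  pct <- snp_type_percentages(snps, labels)
  expect_equal(pct$pct_ctga, 20)
  expect_equal(pct$pct_other, 10)

  none <- snp_type_percentages(snps[0], labels)
  expect_equal(none$pct_ctga, 0)
  expect_equal(none$pct_other, 0)
})
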