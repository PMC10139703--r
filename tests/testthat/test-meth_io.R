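test_that("coverage parsing recomputes pm from counts and preserves file order", {
  path <- write_lines_tmp(c("chrI\t100\t100\t75.0\t3\t1",
                            "chrII\t50\t50\t10\t1\t9"))
  calls <- read_bismark_coverage(path)
  expect_equal(calls$chrom, c("chrI", "chrII"))
  expect_equal(calls$pos, c(100L, 50L))
  expect_equal(calls$pm, c(100 * 3 / 4, 10))
  expect_equal(calls$count_meth, c(3L, 1L))
})

test_that("empty and malformed coverage files are handled", {
  empty <- write_lines_tmp(character())
  expect_equal(nrow(read_bismark_coverage(empty)), 0L)

  bad <- write_lines_tmp("chrI\t100\t100\tNA\tx\t1")
  expect_error(read_bismark_coverage(bad), "line 1")

  short <- write_lines_tmp(c("chrI\t1\t1\t0\t0\t1", "chrI\t2\t2\t5"))
  expect_error(read_bismark_coverage(short), "line 2")

  neg <- write_lines_tmp("chrI\t1\t1\t0\t-3\t1")
  expect_error(read_bismark_coverage(neg), "egative")
})

test_that("SNP mask accepts both the 2-column and the BED dialect", {
  two <- read_snp_mask(write_lines_tmp(c("chrI\t100", "chrI\t200")))
  expect_equal(two$pos, c(100L, 200L))
  # BED 0-based half-open [99, 101) -> 1-based 100, 101
  bed <- read_snp_mask(write_lines_tmp("chrI\t99\t101\tsnp"))
  expect_equal(bed$pos, c(100L, 101L))
})

sample_calls <- function(tab) {
  # tab: data.table chrom, pos, meth, unmeth
  data.table(chrom = tab$chrom, pos = tab$pos,
             count_meth = tab$meth, count_unmeth = tab$unmeth,
             pm = 100 * tab$meth / (tab$meth + tab$unmeth))
}

test_that("site matrix applies the four retention filters", {
  meta <- data.frame(sample_id = c("a", "b"), population = c("marine", "freshwater"),
                     treatment = "native")
  base <- data.table(chrom = c("chrI", "chrI", "chrXIX", "chrI", "chrI"),
                     pos = c(10L, 20L, 30L, 40L, 50L),
                     meth = c(5L, 5L, 5L, 5L, 0L), unmeth = c(5L, 5L, 5L, 5L, 8L))
  low <- copy(base)
  low[pos == 20L, c("meth", "unmeth") := .(2L, 2L)] # 4x coverage in sample b
  calls <- list(a = sample_calls(base), b = sample_calls(low))
  mask <- data.table(chrom = "chrI", pos = 40L)

  mat <- build_site_matrix(calls, meta, snp_mask = mask, min_cov = 5)
  # pos 20 fails coverage in b, pos 30 on an excluded chromosome, 40 masked
  expect_equal(mat$sites$pos, c(10L, 50L))

  # invariance filter: pos 50 is 0% in both samples
  mat2 <- build_site_matrix(calls, meta, snp_mask = mask, min_cov = 5,
                            drop_invariant_over = c("a", "b"))
  expect_equal(mat2$sites$pos, 10L)
})

test_that("invariance filter is evaluated over the given subset only", {
  meta <- data.frame(sample_id = c("a", "b", "t"),
                     population = c("marine", "freshwater", "marine"),
                     treatment = c("native", "native", "transplanted"))
  mk <- function(m1, m2) sample_calls(data.table(chrom = "chrI", pos = c(10L, 20L),
                                                 meth = c(m1, m2),
                                                 unmeth = c(10L - m1, 10L - m2)))
  calls <- list(a = mk(0L, 5L), b = mk(0L, 5L), t = mk(5L, 5L))
  # site 10 is 0% in the comparison samples a,b but 50% in treatment sample t
  mat <- build_site_matrix(calls, meta, min_cov = 5, drop_invariant_over = c("a", "b"))
  expect_equal(mat$sites$pos, 20L)
  mat_all <- build_site_matrix(calls, meta, min_cov = 5,
                               drop_invariant_over = c("a", "b", "t"))
  expect_equal(mat_all$sites$pos, c(10L, 20L))
})

test_that("configuration and validation errors are raised", {
  meta <- data.frame(sample_id = c("a", "b"), population = "marine", treatment = "native")
  one <- sample_calls(data.table(chrom = "chrI", pos = 10L, meth = 5L, unmeth = 5L))
  expect_error(build_site_matrix(list(a = one), meta), "no call stream")
  dup <- sample_calls(data.table(chrom = "chrI", pos = c(10L, 10L),
                                 meth = c(5L, 5L), unmeth = c(5L, 5L)))
  expect_error(build_site_matrix(list(a = dup, b = one), meta), "duplicate")
})

test_that("filtering is idempotent and monotone in min_cov and mask size", {
  set.seed(77)
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     population = c("marine", "marine", "freshwater"),
                     treatment = "native")
  mk <- function() {
    n <- 60
    cov <- pmax(rpois(n, 7), 1L)
    meth <- rbinom(n, cov, runif(n))
    sample_calls(data.table(chrom = rep(c("chrI", "chrII"), each = n / 2),
                            pos = rep(seq_len(n / 2) * 10L, 2),
                            meth = meth, unmeth = cov - meth))
  }
  calls <- list(a = mk(), b = mk(), c = mk())
  mat <- build_site_matrix(calls, meta, min_cov = 5,
                           drop_invariant_over = c("a", "b", "c"))

  # idempotence: rebuild from the matrix's own serialized counts
  path <- tempfile()
  write_site_matrix(mat, path)
  mat2 <- read_site_matrix(path)
  calls2 <- lapply(meta$sample_id, function(id) {
    data.table(chrom = mat2$sites$chrom, pos = mat2$sites$pos,
               count_meth = mat2$counts_meth[, id],
               count_unmeth = mat2$counts_unmeth[, id],
               pm = mat2$pm[, id])
  })
  names(calls2) <- meta$sample_id
  mat3 <- build_site_matrix(calls2, meta, min_cov = 5,
                            drop_invariant_over = c("a", "b", "c"))
  expect_equal(mat3$sites, mat$sites)
  expect_equal(mat3$counts_meth, mat$counts_meth)

  # monotonicity
  n5 <- nrow(build_site_matrix(calls, meta, min_cov = 5)$sites)
  n6 <- nrow(build_site_matrix(calls, meta, min_cov = 6)$sites)
  expect_lte(n6, n5)
  mask <- data.table(chrom = "chrI", pos = c(10L, 20L))
  nmask <- nrow(build_site_matrix(calls, meta, min_cov = 5, snp_mask = mask)$sites)
  expect_lte(nmask, n5)

  # every retained site satisfies the predicates (exhaustive scan)
  expect_true(all(mat$counts_meth + mat$counts_unmeth >= 5))
  expect_false(any(mat$sites$chrom %in% c("chrM", "chrXIX", "chrY")))
  expect_false(any(rowSums(mat$pm != 0) == 0 | rowSums(mat$pm != 100) == 0))
})
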