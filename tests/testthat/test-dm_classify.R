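test_that("methylation summaries compute mean PM and SD_meth", {
  cm <- matrix(c(8, 9, 10,  5, 5, 5,  4, 0, 0), nrow = 3, byrow = TRUE)
  cu <- matrix(c(2, 1, 0,   5, 5, 5,  6, 0, 0), nrow = 3, byrow = TRUE)
  cu[3, 2:3] <- 10; cm[3, 2:3] <- 0
  mat <- make_matrix(cm, cu)
  s <- methylation_summary(mat, c("s1", "s2", "s3"))
  expect_equal(s$mean_pm[1], 90)
  expect_equal(s$sd_meth[1], 10)
  expect_equal(s$mean_pm[2], 50)
  expect_equal(s$sd_meth[2], 0)

  one <- methylation_summary(mat, "s1")
  expect_equal(one$mean_pm[3], 40)
  expect_true(is.na(one$sd_meth[3]))

  expect_error(methylation_summary(mat, character()), "empty")
})

test_that("no-signal and unbalanced null tables give diff 0 and p near 1", {
  cm <- matrix(rep(c(6L, 3L), each = 5), 1)  # same 6:3 table in all samples
  cu <- matrix(rep(c(3L, 6L), each = 5), 1)
  cm[1, ] <- 6L; cu[1, ] <- 3L
  mat <- make_matrix(cm, cu)
  dm <- test_dm(mat, c("s1", "s2", "s3"), c("s4", "s5"))
  expect_equal(dm$meth_diff, 0)
  expect_gt(dm$p_value, 0.99)
})

test_that("extreme separation yields diff -100 and tiny p, in line with Fisher", {
  cm <- matrix(c(30L, 30L, 30L, 0L, 0L, 0L), 1)
  cu <- matrix(c(0L, 0L, 0L, 30L, 30L, 30L), 1)
  mat <- make_matrix(cm, cu)
  dm <- test_dm(mat, c("s1", "s2", "s3"), c("s4", "s5", "s6"))
  expect_equal(dm$meth_diff, -100)
  expect_lt(dm$p_value, 1e-10)
  fisher_p <- fisher.test(matrix(c(90, 0, 0, 90), 2))$p.value
  expect_lt(fisher_p, 1e-10)
})

test_that("the closed-form statistic equals the glm binomial LRT", {
  set.seed(31)
  n_sites <- 25
  cm <- matrix(rpois(n_sites * 6, 8) + 1L, n_sites)
  cu <- matrix(rpois(n_sites * 6, 6) + 1L, n_sites)
  mat <- make_matrix(cm, cu)
  dm <- test_dm(mat, paste0("s", 1:3), paste0("s", 4:6))
  g <- factor(rep(c("a", "b"), each = 3))
  for (i in seq_len(n_sites)) {
    fit1 <- glm(cbind(cm[i, ], cu[i, ]) ~ g, family = binomial)
    fit0 <- glm(cbind(cm[i, ], cu[i, ]) ~ 1, family = binomial)
    expect_equal(dm$statistic[i], fit0$deviance - fit1$deviance, tolerance = 1e-8)
  }
})

test_that("p-values agree in rank order with Fisher's exact test on pooled counts", {
  set.seed(99)
  n_sites <- 200
  cov <- matrix(rpois(n_sites * 6, 15) + 5L, n_sites)
  p <- runif(n_sites, 0.1, 0.9)
  shift <- runif(n_sites, -0.25, 0.25)
  cm <- matrix(0L, n_sites, 6)
  for (j in 1:3) cm[, j] <- rbinom(n_sites, cov[, j], p)
  for (j in 4:6) cm[, j] <- rbinom(n_sites, cov[, j], pmin(pmax(p + shift, 0.02), 0.98))
  mat <- make_matrix(cm, cov - cm)
  dm <- test_dm(mat, paste0("s", 1:3), paste0("s", 4:6))
  mA <- rowSums(cm[, 1:3]); uA <- rowSums(cov[, 1:3] - cm[, 1:3])
  mB <- rowSums(cm[, 4:6]); uB <- rowSums(cov[, 4:6] - cm[, 4:6])
  fp <- vapply(seq_len(n_sites), function(i) {
    fisher.test(matrix(c(mA[i], uA[i], mB[i], uB[i]), 2))$p.value
  }, 0)
  expect_gt(cor(dm$p_value, fp, method = "spearman"), 0.99)
})

test_that("pooled and mean difference conventions are both available", {
  cm <- matrix(c(10L, 1L, 0L, 0L), 1)
  cu <- matrix(c(0L, 9L, 10L, 10L), 1)
  mat <- make_matrix(cm, cu)
  pooled <- test_dm(mat, c("s1", "s2"), c("s3", "s4"))$meth_diff
  meanwise <- test_dm(mat, c("s1", "s2"), c("s3", "s4"), diff_method = "mean")$meth_diff
  expect_equal(pooled, 0 - 100 * 11 / 20)
  expect_equal(meanwise, 0 - 55)
})

test_that("classification uses inclusive thresholds and partitions all sites", {
  dm <- data.table(chrom = "chrI", pos = c(10L, 20L, 30L, 40L),
                   meth_diff = c(-20, -10, 15, 50),
                   p_value = c(1e-4, 1e-5, 1e-3, 0.9))
  cls <- classify_sites(dm, threshold = 15, alpha = 0.05)
  # q for pos 40 is ~0.9 -> non_DMC despite large diff
  expect_equal(as.character(cls$site_class), c("hypo", "non_DMC", "hyper", "non_DMC"))
  expect_equal(sum(table(cls$site_class)), nrow(dm))

  # boundary: meth_diff exactly +15 and q exactly 0.05 is hyper
  dm2 <- data.table(chrom = "chrI", pos = 1L, meth_diff = 15, p_value = 0.05)
  expect_equal(as.character(classify_sites(dm2)$site_class), "hyper")
})

test_that("under a global null the p distribution and BH q are calibrated", {
  set.seed(4242)
  N <- 4000
  p <- runif(N, 0.2, 0.8)
  cov <- matrix(pmax(rpois(N * 6, 20), 5L), N)
  cm <- matrix(rbinom(N * 6, cov, rep(p, 6)), N)
  mat <- make_matrix(cm, cov - cm)
  dm <- test_dm(mat, paste0("s", 1:3), paste0("s", 4:6))
  frac <- mean(dm$p_value <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / N) + 0.005)
  cls <- classify_sites(dm)
  expect_lte(mean(cls$q_value <= 0.05), 0.05)
})

test_that("inducibility classes combine the two treatment comparisons", {
  mk_dm <- function(pos, diff, p) {
    classify_sites(data.table(chrom = "chrI", pos = pos,
                              meth_diff = diff, p_value = p))
  }
  pop <- mk_dm(c(10L, 20L, 30L, 40L), c(-30, -25, 40, -5), c(1e-6, 1e-6, 1e-6, 0.5))
  mar <- mk_dm(c(10L, 20L, 30L, 40L), c(-20, 5, 30, 2), c(1e-4, 0.8, 1e-4, 0.9))
  fw <- mk_dm(c(10L, 20L, 30L, 40L), c(3, 1, -25, 0), c(0.6, 0.9, 1e-4, 1))
  ind <- classify_inducibility(pop, mar, fw)
  expect_equal(as.character(ind$induced_class),
               c("marine_only", "neither", "both", "neither"))
  expect_equal(ind$abs_induced_change_marine[1], 20)
  expect_true(is.na(ind$abs_induced_change_fw[1]))
  expect_equal(ind$abs_induced_change_fw[3], 25)

  # a treatment-only site is skipped with a warning
  mar2 <- mk_dm(c(10L, 20L, 30L, 40L, 99L), c(-20, 5, 30, 2, 50), c(1e-4, 0.8, 1e-4, 0.9, 1e-5))
  expect_warning(classify_inducibility(pop, mar2, fw), "skipped")
})
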