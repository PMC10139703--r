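#' Per-site methylation summaries for a sample group
#'
#' Computes, per retained site, the mean percentage of methylated copies
#' (mean PM) and the between-sample standard deviation of the percentage
#' (SD_meth, n-1 denominator) over a group of samples.
#'
#' @param matrix A \code{meth_site_matrix}.
#' @param group Character vector of sample ids (>= 1; SD requires >= 2 and is
#'   reported as \code{NA} for a single-sample group).
#' @return data.table with \code{chrom}, \code{pos}, \code{mean_pm},
#'   \code{sd_meth}.
#' @export
methylation_summary <- function(matrix, group) {
  if (length(group) == 0) stop_config("empty sample group")
  if (!all(group %in% colnames(matrix$pm))) stop_config("unknown sample id in group")
  pm <- matrix$pm[, group, drop = FALSE]
  out <- copy_sites(matrix)
  out[, mean_pm := rowMeans(pm)]
  if (length(group) >= 2) {
    mu <- rowMeans(pm)
    out[, sd_meth := sqrt(rowSums((pm - mu)^2) / (length(group) - 1))]
  } else {
    out[, sd_meth := NA_real_]
  }
  out[]
}

#' Per-site differential methylation test
#'
#' Binomial logistic regression of methylated/unmethylated counts on group
#' membership, per site; the p-value is from the likelihood-ratio chi-square
#' with 1 df. Because the only covariate is the two-level group factor, the
#' group MLEs are the coverage-pooled per-group proportions and the
#' likelihood-ratio statistic has a closed form, which is computed vectorised
#' over sites. Non-finite statistics fall back to Fisher's exact test on the
#' pooled 2x2 table and are flagged.
#'
#' @param matrix A \code{meth_site_matrix}.
#' @param groupA,groupB Non-empty, disjoint character vectors of sample ids;
#'   unequal sizes allowed.
#' @param diff_method How the methylation difference is summarised:
#'   \code{"pooled"} (default; difference of coverage-weighted pooled
#'   percentages, B minus A) or \code{"mean"} (difference of unweighted
#'   per-sample means).
#' @return data.table with \code{chrom}, \code{pos}, \code{meth_diff}
#'   (percentage points, B - A), \code{statistic}, \code{p_value},
#'   \code{fallback} (logical; TRUE where Fisher's exact test was used).
#' @export
test_dm <- function(matrix, groupA, groupB, diff_method = c("pooled", "mean")) {
  diff_method <- match.arg(diff_method)
  if (!length(groupA) || !length(groupB)) stop_config("both groups must be non-empty")
  if (length(intersect(groupA, groupB))) stop_config("groups must be disjoint")
  mA <- rowSums(matrix$counts_meth[, groupA, drop = FALSE])
  uA <- rowSums(matrix$counts_unmeth[, groupA, drop = FALSE])
  mB <- rowSums(matrix$counts_meth[, groupB, drop = FALSE])
  uB <- rowSums(matrix$counts_unmeth[, groupB, drop = FALSE])
  tA <- mA + uA
  tB <- mB + uB
  if (any(tA == 0) || any(tB == 0)) {
    stop("internal error: site with zero total counts in a group after filtering")
  }

  # closed-form binomial-logistic LRT: group-wise MLE = pooled proportions
  xlx <- function(x) ifelse(x > 0, x * log(x), 0) # x*log(x) with 0*log(0)=0
  ll_part <- function(m, u) xlx(m) + xlx(u) - xlx(m + u)
  stat <- 2 * (ll_part(mA, uA) + ll_part(mB, uB) - ll_part(mA + mB, uA + uB))
  stat <- pmax(stat, 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)

  fallback <- !is.finite(stat)
  if (any(fallback)) {
    for (i in which(fallback)) {
      p[i] <- fisher.test(matrix(c(mA[i], uA[i], mB[i], uB[i]), 2))$p.value
      stat[i] <- NA_real_
    }
  }

  out <- copy_sites(matrix)
  if (diff_method == "pooled") {
    out[, meth_diff := 100 * (mB / tB - mA / tA)]
  } else {
    out[, meth_diff := rowMeans(matrix$pm[, groupB, drop = FALSE]) -
                       rowMeans(matrix$pm[, groupA, drop = FALSE])]
  }
  out[, statistic := stat]
  out[, p_value := p]
  out[, fallback := fallback]
  out[]
}

#' Classify tested sites by methylation difference and FDR
#'
#' Benjamini-Hochberg q-values are computed over all sites of the comparison;
#' a site is \code{hypo} iff \code{meth_diff <= -threshold} and
#' \code{q <= alpha}, \code{hyper} iff \code{meth_diff >= threshold} and
#' \code{q <= alpha} (both thresholds inclusive), otherwise \code{non_DMC}.
#'
#' @param dm Output of [test_dm()].
#' @param threshold Methylation-difference threshold in percentage points
#'   (default 15).
#' @param alpha FDR cutoff on q (default 0.05).
#' @return \code{dm} with added \code{q_value} and \code{site_class}
#'   (factor \code{non_DMC}/\code{hypo}/\code{hyper}).
#' @export
classify_sites <- function(dm, threshold = 15, alpha = 0.05) {
  stopifnot(threshold > 0, threshold <= 100, alpha > 0, alpha <= 1)
  dm <- as.data.table(dm)
  if (!nrow(dm)) stop_config("cannot classify an empty DM stream")
  dm[, q_value := p.adjust(p_value, method = "BH")]
  cls <- rep("non_DMC", nrow(dm))
  cls[dm$meth_diff <= -threshold & dm$q_value <= alpha] <- "hypo"
  cls[dm$meth_diff >= threshold & dm$q_value <= alpha] <- "hyper"
  dm[, site_class := factor(cls, levels = c("non_DMC", "hypo", "hyper"))]
  dm[]
}

#' Inducibility classification from treatment comparisons
#'
#' A site is induced in a population iff it is significantly differentially
#' methylated (same effect-size and FDR rule as the population comparison) in
#' that population's salinity-treatment comparison; the direction of the
#' induced change is ignored and its magnitude \code{|meth_diff|} is reported.
#'
#' @param population_dm Classified population-comparison table
#'   ([classify_sites()] output); defines the site universe.
#' @param marine_treatment_dm,fw_treatment_dm Classified treatment-comparison
#'   tables for the marine and freshwater populations.
#' @return data.table with \code{chrom}, \code{pos}, \code{site_class} (from
#'   the population comparison), \code{induced_marine}, \code{induced_fw},
#'   \code{induced_class} (\code{neither}/\code{marine_only}/\code{fw_only}/
#'   \code{both}), \code{abs_induced_change_marine},
#'   \code{abs_induced_change_fw} (NA where not induced).
#' @export
classify_inducibility <- function(population_dm, marine_treatment_dm, fw_treatment_dm) {
  pop <- as.data.table(population_dm)[, .(chrom, pos, site_class)]
  prep <- function(trt, label) {
    trt <- as.data.table(trt)
    extra <- trt[!pop, on = c("chrom", "pos")]
    if (nrow(extra)) {
      warning(sprintf("%d %s-treatment sites absent from the population comparison; skipped",
                      nrow(extra), label))
    }
    trt[, .(chrom, pos,
            induced = site_class != "non_DMC",
            abs_change = abs(meth_diff))]
  }
  mar <- prep(marine_treatment_dm, "marine")
  fw <- prep(fw_treatment_dm, "freshwater")
  out <- merge(pop, mar, by = c("chrom", "pos"), all.x = TRUE)
  setnames(out, c("induced", "abs_change"), c("induced_marine", "abs_change_m"))
  out <- merge(out, fw, by = c("chrom", "pos"), all.x = TRUE)
  setnames(out, c("induced", "abs_change"), c("induced_fw", "abs_change_f"))
  out[is.na(induced_marine), induced_marine := FALSE]
  out[is.na(induced_fw), induced_fw := FALSE]
  out[, induced_class := factor(
    ifelse(induced_marine & induced_fw, "both",
    ifelse(induced_marine, "marine_only",
    ifelse(induced_fw, "fw_only", "neither"))),
    levels = c("neither", "marine_only", "fw_only", "both"))]
  out[, abs_induced_change_marine := ifelse(induced_marine, abs_change_m, NA_real_)]
  out[, abs_induced_change_fw := ifelse(induced_fw, abs_change_f, NA_real_)]
  out[, c("abs_change_m", "abs_change_f") := NULL]
  order_sites(out)[]
}
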