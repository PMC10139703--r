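#' Assign equal-width ranks over a per-site variable
#'
#' The value range [min, max] is split into \code{n_ranks} contiguous
#' equal-width intervals, left-closed right-open except the last (closed);
#' a value exactly at an internal boundary goes to the upper interval.
#' Sites with undefined values are skipped and counted.
#'
#' @param values data.table with \code{chrom}, \code{pos}, \code{value}, or
#'   a named numeric vector keyed \code{"chrom:pos"}.
#' @param n_ranks Number of ranks (>= 2; the study convention is 50).
#' @return data.table: \code{chrom}, \code{pos}, \code{value}, \code{rank}
#'   (integer in 1..n_ranks), with attributes \code{breaks} and
#'   \code{n_skipped}.
#' @export
assign_ranks <- function(values, n_ranks = 50L) {
  stopifnot(n_ranks >= 2)
  if (is.numeric(values) && !is.null(names(values))) {
    parts <- strsplit(names(values), ":", fixed = TRUE)
    values <- data.table(chrom = vapply(parts, `[`, "", 1L),
                         pos = as.integer(vapply(parts, `[`, "", 2L)),
                         value = unname(values))
  }
  dt <- as.data.table(values)[, .(chrom, pos, value)]
  n_skipped <- sum(!is.finite(dt$value))
  dt <- dt[is.finite(value)]
  if (length(unique(dt$value)) < 2) {
    stop_config("degenerate value range: need at least 2 distinct values to rank")
  }
  lo <- min(dt$value)
  hi <- max(dt$value)
  width <- (hi - lo) / n_ranks
  dt[, rank := pmin(as.integer(floor((value - lo) / width)) + 1L, as.integer(n_ranks))]
  setattr(dt, "breaks", seq(lo, hi, length.out = n_ranks + 1))
  setattr(dt, "n_skipped", n_skipped)
  dt[]
}

#' Rank-level diversity profile
#'
#' One diversity estimate per rank (the rank is the label passed to
#' [aggregate_diversity()]); ranks whose covered fraction is below
#' \code{min_covered_fraction} are marked excluded, as are empty ranks.
#'
#' @param assignments [assign_ranks()] output.
#' @param records [parse_pileup()] output for the population.
#' @param params A [pool_params()] object.
#' @param min_covered_fraction Coverage floor (default 0.60).
#' @return data.table: \code{rank}, \code{mean_value} (mean of the ranking
#'   variable in the rank), \code{n_sites}, \code{pi}, \code{theta_w},
#'   \code{tajimas_d}, \code{covered_fraction}, \code{excluded}.
#' @export
rank_diversity <- function(assignments, records, params,
                           min_covered_fraction = 0.60) {
  asg <- as.data.table(assignments)
  labels <- asg[, .(chrom, pos, label = sprintf("rank_%03d", rank))]
  div <- aggregate_diversity(records, labels, params, min_covered_fraction)
  mv <- asg[, .(mean_value = mean(value)), by = .(label = sprintf("rank_%03d", rank))]
  out <- merge(mv, div, by = "label", all = TRUE)
  out[, rank := as.integer(sub("rank_", "", label))]
  setorder(out, rank)
  out[, excluded := is.na(pi) | flagged | n_sites == 0]
  out[, .(rank, mean_value, n_sites, pi, theta_w, tajimas_d,
          covered_fraction, excluded)]
}
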