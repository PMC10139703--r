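#' Distance-matched subsampling of non-DMCs around DMCs
#'
#' For each DMC independently (iterated in sorted (chrom, pos) order, so the
#' draw sequence is reproducible given the seed), one non-DMC with
#' |position difference| <= \code{window} on the same chromosome is selected
#' uniformly at random, if any exists; a non-DMC may be drawn for several
#' DMCs and the union is deduplicated afterwards.
#'
#' @param dmcs,non_dmcs Disjoint data.tables of sites (chrom, pos).
#' @param window Matching window in bp on each side (default 2000).
#' @param seed Integer seed; the function restores the caller's RNG state.
#' @return List of class \code{matched_subsample}: \code{selected}
#'   (data.table of unique selected sites), \code{provenance} (data.table
#'   dmc_chrom, dmc_pos, sel_pos with NA where no candidate existed),
#'   \code{seed}, \code{window}.
#' @export
subsample_non_dmcs <- function(dmcs, non_dmcs, window = 2000L, seed = 1L) {
  stopifnot(window > 0)
  dmcs <- order_sites(as.data.table(dmcs)[, .(chrom, pos)])
  non_dmcs <- order_sites(as.data.table(non_dmcs)[, .(chrom, pos)])
  if (nrow(merge(dmcs, non_dmcs, by = c("chrom", "pos")))) {
    stop_config("dmcs and non_dmcs must be disjoint")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))

  nd_by_chr <- split(non_dmcs$pos, non_dmcs$chrom)
  sel_pos <- rep(NA_integer_, nrow(dmcs))
  for (i in seq_len(nrow(dmcs))) {
    cand <- nd_by_chr[[dmcs$chrom[i]]]
    if (is.null(cand)) next
    lo <- findInterval(dmcs$pos[i] - window - 1L, cand) + 1L
    hi <- findInterval(dmcs$pos[i] + window, cand)
    if (hi < lo) next
    sel_pos[i] <- cand[lo + sample.int(hi - lo + 1L, 1L) - 1L]
  }
  prov <- data.table(dmc_chrom = dmcs$chrom, dmc_pos = dmcs$pos, sel_pos = sel_pos)
  selected <- unique(prov[!is.na(sel_pos), .(chrom = dmc_chrom, pos = sel_pos)])
  structure(list(selected = order_sites(selected), provenance = prov,
                 seed = as.integer(seed), window = as.integer(window)),
            class = "matched_subsample")
}

#' @export
print.matched_subsample <- function(x, ...) {
  cat(sprintf("matched_subsample: %d unique sites from %d DMCs (window %d bp, seed %d)\n",
              nrow(x$selected), nrow(x$provenance), x$window, x$seed))
  invisible(x)
}

#' Read a BED file of feature intervals
#'
#' @param path BED path (0-based, half-open; at least 3 columns).
#' @return data.table with \code{chrom}, \code{start} (0-based), \code{end}.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_config("BED file does not exist: %s", path)
  raw <- readLines(path)
  keep <- nzchar(raw) & !startsWith(raw, "#") & !startsWith(raw, "track")
  raw <- raw[keep]
  if (!length(raw)) return(data.table(chrom = character(), start = integer(), end = integer()))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) stop_config("malformed BED line %d in %s", which(nf < 3)[1], path)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop_config("malformed BED line %d in %s", bad[1], path)
  data.table(chrom = vapply(fields, `[`, "", 1L), start = start, end = end)
}

# is 1-based point p inside any 0-based half-open interval? Sorted intervals
# with a running max of ends; covered iff the last interval starting before p
# (prefix max end) reaches p.
points_in_intervals <- function(chrom, pos, iv) {
  out <- logical(length(pos))
  if (!nrow(iv)) return(out)
  iv <- as.data.table(iv)
  setorder(iv, chrom, start)
  for (ch in unique(chrom)) {
    sub <- iv[chrom == ch]
    idx <- which(chrom == ch)
    if (!nrow(sub)) next
    pmax_end <- cummax(sub$end)
    j <- findInterval(pos[idx] - 1L, sub$start)  # intervals with start < p
    out[idx] <- j > 0 & pmax_end[pmax(j, 1L)] >= pos[idx]
  }
  out
}

#' Annotate sites with feature-interval membership
#'
#' Each feature is a BED interval set (0-based half-open); a 1-based site
#' position p is inside iff start < p <= end. Sites in no supplied feature
#' are flagged \code{intergenic}.
#'
#' @param sites data.table (chrom, pos).
#' @param features Named list of BED paths or interval data.tables
#'   (chrom, start, end).
#' @return data.table: \code{chrom}, \code{pos}, one logical column per
#'   feature, and \code{intergenic}.
#' @export
annotate_features <- function(sites, features) {
  sites <- as.data.table(sites)[, .(chrom, pos)]
  out <- data.table(chrom = sites$chrom, pos = sites$pos)
  any_flag <- logical(nrow(sites))
  for (nm in names(features)) {
    iv <- features[[nm]]
    if (is.character(iv)) iv <- read_bed(iv)
    flag <- points_in_intervals(sites$chrom, sites$pos, iv)
    out[[nm]] <- flag
    any_flag <- any_flag | flag
  }
  out[["intergenic"]] <- !any_flag
  out[]
}
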