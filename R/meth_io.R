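#' Read a Bismark-style CpG coverage file
#'
#' Parses a six-column, tab-separated coverage file (chromosome, start, end,
#' percent methylation, methylated count, unmethylated count) with 1-based
#' inclusive coordinates, one row per CpG. The percent column in the file is
#' advisory only: \code{pm} is recomputed from the counts to avoid rounding
#' inconsistencies.
#'
#' @param path Path to the coverage file.
#' @return A \code{data.table} with columns \code{chrom}, \code{pos},
#'   \code{count_meth}, \code{count_unmeth}, \code{pm} (percentage of
#'   methylated copies, in \eqn{[0, 100]}), in file order.
#' @export
read_bismark_coverage <- function(path) {
  if (!file.exists(path)) stop_config("coverage file does not exist: %s", path)
  raw <- readLines(path)
  if (length(raw) == 0) {
    return(data.table(chrom = character(), pos = integer(),
                      count_meth = integer(), count_unmeth = integer(),
                      pm = numeric()))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6)) {
    stop_config("malformed coverage line %d in %s: expected 6 tab-separated fields, got %d",
                which(nf != 6)[1], path, nf[which(nf != 6)[1]])
  }
  m <- matrix(unlist(fields), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  cm <- suppressWarnings(as.numeric(m[, 5]))
  cu <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(pos) | is.na(cm) | is.na(cu) | cm != floor(cm) | cu != floor(cu))
  if (length(bad)) {
    stop_config("malformed coverage line %d in %s: non-numeric position or counts",
                bad[1], path)
  }
  if (any(cm < 0 | cu < 0)) {
    stop_config("negative counts at coverage line %d in %s",
                which(cm < 0 | cu < 0)[1], path)
  }
  dt <- data.table(chrom = m[, 1], pos = pos,
                   count_meth = as.integer(cm), count_unmeth = as.integer(cu))
  dt[, pm := 100 * count_meth / (count_meth + count_unmeth)]
  dt[]
}

#' Read a SNP mask file
#'
#' Accepts either a two-column (chrom, pos) TSV with 1-based positions, or a
#' BED file (>= 3 columns, 0-based half-open), autodetected per file: a file
#' whose rows have >= 3 columns with numeric second and third fields is
#' treated as BED and each covered base is converted to 1-based positions.
#'
#' @param path Path to the mask file.
#' @return A \code{data.table} with columns \code{chrom}, \code{pos}
#'   (1-based) listing masked coordinates.
#' @export
read_snp_mask <- function(path) {
  if (!file.exists(path)) stop_config("SNP mask file does not exist: %s", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#") & !startsWith(raw, "track")]
  if (!length(raw)) return(data.table(chrom = character(), pos = integer()))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (all(nf >= 3)) {
    third <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    second <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    if (!anyNA(third) && !anyNA(second)) {
      # BED: 0-based half-open [start, end) -> 1-based positions start+1 .. end
      dt <- rbindlist(lapply(fields, function(f) {
        s <- as.integer(f[2]); e <- as.integer(f[3])
        if (e <= s) return(NULL)
        data.table(chrom = f[1], pos = (s + 1L):e)
      }))
      return(unique(order_sites(dt)))
    }
  }
  if (any(nf < 2)) stop_config("malformed mask line %d in %s", which(nf < 2)[1], path)
  dt <- data.table(chrom = vapply(fields, `[`, "", 1L),
                   pos = suppressWarnings(as.integer(vapply(fields, `[`, "", 2L))))
  if (anyNA(dt$pos)) stop_config("non-numeric position in mask file %s", path)
  unique(order_sites(dt))
}

#' Assemble a filtered multi-sample CpG site matrix
#'
#' Applies the study's site filters to per-sample methylation calls and
#' returns the unified matrix of methylated/unmethylated counts. A site is
#' retained iff it (a) is present with coverage >= \code{min_cov} in every
#' sample, (b) does not lie on an excluded chromosome, (c) is not in the SNP
#' mask, and (d) is not uniformly 0\% nor uniformly 100\% methylated across
#' the \code{drop_invariant_over} samples. Sites absent from any sample are
#' treated as zero-coverage there (hence excluded); no imputation.
#'
#' @param calls_per_sample Named list of per-sample call tables as returned
#'   by [read_bismark_coverage()]; names are sample ids.
#' @param meta A data.frame with columns \code{sample_id}, \code{population}
#'   (\code{"marine"}/\code{"freshwater"}) and \code{treatment}
#'   (\code{"native"}/\code{"transplanted"}).
#' @param snp_mask Optional data.table (chrom, pos) of masked coordinates.
#' @param min_cov Minimum per-sample coverage (default 5).
#' @param excluded_chroms Chromosomes dropped wholesale (default the
#'   mitochondrial and the two sex chromosomes).
#' @param drop_invariant_over Sample ids over which the 0\%/100\% invariance
#'   filter is evaluated; \code{NULL} (default) skips that filter.
#' @return An object of class \code{meth_site_matrix}: a list with
#'   \code{sites} (data.table chrom, pos), \code{meta}, \code{counts_meth}
#'   and \code{counts_unmeth} (integer matrices, sites x samples) and
#'   \code{pm} (numeric matrix of per-sample percentages).
#' @export
build_site_matrix <- function(calls_per_sample, meta,
                              snp_mask = NULL,
                              min_cov = 5L,
                              excluded_chroms = c("chrM", "chrXIX", "chrY"),
                              drop_invariant_over = NULL) {
  stopifnot(min_cov >= 1)
  meta <- as.data.frame(meta)
  req <- c("sample_id", "population", "treatment")
  if (!all(req %in% names(meta))) stop_config("meta must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop_config("duplicate sample_id in meta")
  missing <- setdiff(meta$sample_id, names(calls_per_sample))
  if (length(missing)) {
    stop_config("sample in meta with no call stream: %s", paste(missing, collapse = ", "))
  }
  if (!is.null(drop_invariant_over) &&
      !all(drop_invariant_over %in% meta$sample_id)) {
    stop_config("drop_invariant_over contains unknown sample ids")
  }
  ids <- meta$sample_id

  tabs <- lapply(ids, function(id) {
    dt <- as.data.table(calls_per_sample[[id]])
    if (anyDuplicated(dt[, .(chrom, pos)])) {
      stop_config("duplicate (chrom,pos) within sample %s", id)
    }
    dt[, .(chrom, pos, cov = count_meth + count_unmeth,
           count_meth, count_unmeth)]
  })
  names(tabs) <- ids

  # intersect sites covered >= min_cov in every sample
  keep <- NULL
  for (id in ids) {
    s <- tabs[[id]][cov >= min_cov, .(chrom, pos)]
    keep <- if (is.null(keep)) s else merge(keep, s, by = c("chrom", "pos"))
  }
  keep <- keep[!chrom %in% excluded_chroms]
  if (!is.null(snp_mask) && nrow(snp_mask)) {
    mask <- as.data.table(snp_mask)[, .(chrom, pos)]
    keep <- keep[!mask, on = c("chrom", "pos")]
  }
  keep <- order_sites(keep)

  nm <- matrix(0L, nrow(keep), length(ids), dimnames = list(NULL, ids))
  nu <- matrix(0L, nrow(keep), length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    m <- merge(keep, tabs[[id]], by = c("chrom", "pos"), sort = FALSE)
    nm[, id] <- m$count_meth
    nu[, id] <- m$count_unmeth
  }
  pm <- 100 * nm / (nm + nu)

  if (!is.null(drop_invariant_over) && nrow(keep)) {
    sub <- pm[, drop_invariant_over, drop = FALSE]
    all0 <- rowSums(sub != 0) == 0
    all100 <- rowSums(sub != 100) == 0
    retain <- !(all0 | all100)
    keep <- keep[retain]
    nm <- nm[retain, , drop = FALSE]
    nu <- nu[retain, , drop = FALSE]
    pm <- pm[retain, , drop = FALSE]
  }

  structure(list(sites = keep, meta = meta,
                 counts_meth = nm, counts_unmeth = nu, pm = pm,
                 min_cov = as.integer(min_cov)),
            class = "meth_site_matrix")
}

#' @export
print.meth_site_matrix <- function(x, ...) {
  cat(sprintf("meth_site_matrix: %d sites x %d samples (min coverage %d)\n",
              nrow(x$sites), nrow(x$meta), x$min_cov))
  invisible(x)
}

#' Serialize / restore a site matrix
#'
#' The matrix is written as a TSV (chrom, pos, then one
#' \code{meth:unmeth} column per sample) plus a JSON-free TSV sidecar with
#' the sample metadata, so a filtered matrix round-trips exactly.
#'
#' @param x A \code{meth_site_matrix}.
#' @param path Output TSV path; the sidecar is written at
#'   \code{paste0(path, ".meta")}.
#' @return \code{path}, invisibly.
#' @export
write_site_matrix <- function(x, path) {
  dt <- copy_sites(x)
  for (id in x$meta$sample_id) {
    dt[[id]] <- paste(x$counts_meth[, id], x$counts_unmeth[, id], sep = ":")
  }
  fwrite(dt, path, sep = "\t")
  fwrite(as.data.table(x$meta), paste0(path, ".meta"), sep = "\t")
  invisible(path)
}

copy_sites <- function(x) data.table(chrom = x$sites$chrom, pos = x$sites$pos)

#' @rdname write_site_matrix
#' @export
read_site_matrix <- function(path) {
  dt <- fread(path, sep = "\t")
  meta <- as.data.frame(fread(paste0(path, ".meta"), sep = "\t"))
  ids <- meta$sample_id
  nm <- matrix(0L, nrow(dt), length(ids), dimnames = list(NULL, ids))
  nu <- matrix(0L, nrow(dt), length(ids), dimnames = list(NULL, ids))
  for (id in ids) {
    parts <- strsplit(dt[[id]], ":", fixed = TRUE)
    nm[, id] <- as.integer(vapply(parts, `[`, "", 1L))
    nu[, id] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  structure(list(sites = dt[, .(chrom, pos)], meta = meta,
                 counts_meth = nm, counts_unmeth = nu,
                 pm = 100 * nm / (nm + nu), min_cov = NA_integer_),
            class = "meth_site_matrix")
}
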