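library(data.table)

# build a meth_site_matrix directly from count matrices (sites x samples)
make_matrix <- function(counts_meth, counts_unmeth, populations = NULL,
                        treatments = NULL, chrom = "chrI") {
  n <- nrow(counts_meth)
  ids <- colnames(counts_meth)
  if (is.null(ids)) {
    ids <- paste0("s", seq_len(ncol(counts_meth)))
    colnames(counts_meth) <- colnames(counts_unmeth) <- ids
  }
  meta <- data.frame(
    sample_id = ids,
    population = populations %||% rep("marine", length(ids)),
    treatment = treatments %||% rep("native", length(ids)),
    stringsAsFactors = FALSE)
  structure(list(sites = data.table(chrom = chrom, pos = seq_len(n) * 100L),
                 meta = meta,
                 counts_meth = counts_meth, counts_unmeth = counts_unmeth,
                 pm = 100 * counts_meth / (counts_meth + counts_unmeth),
                 min_cov = 1L),
            class = "meth_site_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# allele-count records builder
make_records <- function(A = 0L, C = 0L, G = 0L, T = 0L, chrom = "chrI",
                         pos = NULL, ref = "C") {
  n <- max(length(A), length(C), length(G), length(T))
  dt <- data.table(chrom = chrom,
                   pos = pos %||% (seq_len(n) * 10L),
                   ref = ref,
                   A = as.integer(rep_len(A, n)), C = as.integer(rep_len(C, n)),
                   G = as.integer(rep_len(G, n)), T = as.integer(rep_len(T, n)))
  dt[, M := A + C + G + T]
  dt[]
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a medium synthetic pipeline run at the generator defaults, computed once
# per session and shared across test files
.fixture_env <- new.env()
get_default_run <- function() {
  if (is.null(.fixture_env$run)) {
    cfg <- sim_config(seed = 20260920L %% 1000003L)
    .fixture_env$run <- run_pipeline(
      pipeline_config(synthetic = TRUE, sim = cfg, seed = 20260920L %% 1000003L),
      file.path(tempdir(), "methdiv_default_run"))
  }
  .fixture_env$run
}
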