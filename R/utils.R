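#' @importFrom data.table data.table as.data.table setkey setkeyv setorder := fread fwrite rbindlist setnames setattr tstrsplit .N .SD
#' @importFrom stats p.adjust pchisq fisher.test shapiro.test t.test wilcox.test lm coef
#' @importFrom stats rbinom rpois runif rbeta dbinom median setNames complete.cases
#' @importFrom utils head tail
NULL

# harmonic number a1(n) = sum_{i=1}^{n-1} 1/i
harmonic1 <- function(n) {
  if (n < 2) return(0)
  sum(1 / seq_len(n - 1))
}

# a2(n) = sum_{i=1}^{n-1} 1/i^2
harmonic2 <- function(n) {
  if (n < 2) return(0)
  sum(1 / seq_len(n - 1)^2)
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# Deterministic substream seed derived from a master seed and a stream name.
# Keeps the derived seed in [0, 2^31 - 2] so it is a valid R integer seed.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 131 + cp) %% 2147480009
  as.integer((abs(seed) * 7919 + h) %% 2147480009)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

# lexicographic-then-numeric site ordering used throughout
order_sites <- function(dt) {
  setorder(dt, chrom, pos)
  dt
}
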