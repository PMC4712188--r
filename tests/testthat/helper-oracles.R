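# Independent brute-force oracles used across the suite.

# maximal G runs by direct character walk
oracle_g_tracts <- function(sequence, g_min) {
  chars <- strsplit(sequence, "")[[1L]]
  runs <- rle(chars == "G")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= g_min
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             length = runs$lengths[keep])
}

# every window of 4 consecutive maximal tracts with all gaps in range
oracle_g4_windows <- function(sequence, g_min, loop_min, loop_max) {
  tr <- oracle_g_tracts(sequence, g_min)
  out <- list()
  if (nrow(tr) >= 4L) {
    for (i in seq_len(nrow(tr) - 3L)) {
      idx <- i:(i + 3L)
      gaps <- tr$start[idx[-1L]] - tr$end[idx[-4L]]
      if (all(gaps >= loop_min & gaps <= loop_max))
        out[[length(out) + 1L]] <- data.frame(
          start = tr$start[i], end = tr$end[i + 3L], max_loop = max(gaps))
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      max_loop = integer()))
  do.call(rbind, out)
}

# two-sided Fisher p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(x1, x2, r1, r2) {
  m <- x1 + x2                       # first-column margin
  lo <- max(0L, m - r2); hi <- min(r1, m)
  d <- stats::dhyper(lo:hi, r1, r2, m)
  d_obs <- stats::dhyper(x1, r1, r2, m)
  sum(d[d <= d_obs * (1 + 1e-7)])
}

# linear-interpolation percentile by direct sort-and-index arithmetic
oracle_quantile <- function(x, prob) {
  x <- sort(x)
  h <- (length(x) - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

random_dna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

reverse_complement <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = "")
}
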