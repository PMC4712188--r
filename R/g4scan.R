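#' Find maximal G tracts in a DNA sequence
#'
#' Locates every maximal run of at least `g_min` consecutive guanines on the
#' given strand of a DNA sequence. Tracts are the building blocks of
#' G-quadruplex (G4) motifs: a quadruplex requires four or more such tracts
#' separated by short non-G loops.
#'
#' @param sequence A single character string of uppercase A/C/G/T/N.
#' @param g_min Minimum tract length in nucleotides (>= 2).
#' @return A data frame with columns `start` (0-based), `end` (exclusive)
#'   and `length`, one row per maximal G run, ordered left to right.
#'   `N` never joins a tract.
#' @examples
#' find_g_tracts("TTGGTTTTGGTTTTGGTTTTGGT", 2)
#' @export
find_g_tracts <- function(sequence, g_min = 3L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  g_min <- as.integer(g_min)
  if (is.na(g_min) || g_min < 2L)
    stop("`g_min` must be an integer >= 2", call. = FALSE)
  if (nchar(sequence) > 0L && grepl("[^ACGTN]", sequence))
    stop("sequence contains characters other than A/C/G/T/N", call. = FALSE)
  m <- gregexpr(sprintf("G{%d,}", g_min), sequence)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer(), length = integer()))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len,
             length = len)
}

#' Scan a DNA sequence for G-quadruplex motifs
#'
#' A motif is called wherever four or more maximal G tracts (each
#' `>= g_min` nt) follow one another with every inter-tract non-G loop in
#' `[loop_min, loop_max]`. Runs of qualifying tracts are extended maximally:
#' a chain of k >= 4 tracts is reported as one motif with k tracts and
#' k - 1 loops, rather than as sliding 4-tract windows, so loop statistics
#' are per structural unit. With `all_decompositions = TRUE`, every
#' contiguous 4-tract window with valid loops is emitted instead.
#'
#' @param sequence DNA string (uppercase A/C/G/T/N); may be empty.
#' @param g_min Minimum G-tract length (nt). The default 3 matches canonical
#'   G4 consensus scanning; 2 admits weaker GG-tract quadruplexes.
#' @param loop_min,loop_max Allowed non-G loop length range (nt).
#' @param both_strands Also scan the reverse complement; minus-strand motifs
#'   are reported on forward-strand (top-strand) coordinates.
#' @param all_decompositions Emit every 4-tract decomposition instead of
#'   maximal non-overlapping motifs.
#' @param sequence_id Identifier copied into the output.
#' @return A data frame of class `g4_hits` with columns `sequence_id`,
#'   `start`, `end` (0-based half-open, forward axis), `strand`, `n_tracts`,
#'   `max_loop`, and list-columns `tract_start`, `tract_end`, `loops`.
#' @examples
#' scan_g4("TTTTGGGTGGGTGGGTGGGTTTT", g_min = 3)
#' @export
scan_g4 <- function(sequence, g_min = 3L, loop_min = 1L, loop_max = 7L,
                    both_strands = FALSE, all_decompositions = FALSE,
                    sequence_id = "seq") {
  stopifnot(loop_min >= 1L, loop_max >= loop_min)
  hits <- scan_g4_strand(sequence, g_min, loop_min, loop_max,
                         all_decompositions, sequence_id, "+")
  if (both_strands && nchar(sequence) > 0L) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    rev_hits <- scan_g4_strand(rc, g_min, loop_min, loop_max,
                               all_decompositions, sequence_id, "-")
    if (nrow(rev_hits) > 0L) {
      L <- nchar(sequence)
      mirror <- function(s, e) list(start = L - e, end = L - s)
      for (i in seq_len(nrow(rev_hits))) {
        span <- mirror(rev_hits$start[i], rev_hits$end[i])
        rev_hits$start[i] <- span$start
        rev_hits$end[i] <- span$end
        ts <- rev_hits$tract_start[[i]]
        te <- rev_hits$tract_end[[i]]
        rev_hits$tract_start[[i]] <- rev(L - te)
        rev_hits$tract_end[[i]] <- rev(L - ts)
        rev_hits$loops[[i]] <- rev(rev_hits$loops[[i]])
      }
    }
    hits <- rbind(hits, rev_hits)
    hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
    rownames(hits) <- NULL
  }
  class(hits) <- c("g4_hits", "data.frame")
  hits
}

# scan one strand; coordinates are on the scanned strand's own axis
scan_g4_strand <- function(sequence, g_min, loop_min, loop_max,
                           all_decompositions, sequence_id, strand) {
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_tracts = integer(), max_loop = integer())
  empty$tract_start <- list()
  empty$tract_end <- list()
  empty$loops <- list()
  if (nchar(sequence) == 0L) return(empty)
  tr <- find_g_tracts(sequence, g_min)
  if (nrow(tr) < 4L) return(empty)
  gaps <- tr$start[-1L] - tr$end[-nrow(tr)]
  ok <- gaps >= loop_min & gaps <= loop_max
  # chains of consecutive tracts whose every gap is a valid loop
  brk <- c(0L, which(!ok), nrow(tr))
  out <- list()
  for (j in seq_len(length(brk) - 1L)) {
    idx <- (brk[j] + 1L):brk[j + 1L]
    if (length(idx) < 4L) next
    if (all_decompositions) {
      for (w in seq_len(length(idx) - 3L)) {
        win <- idx[w:(w + 3L)]
        out[[length(out) + 1L]] <- motif_row(tr, win, sequence_id, strand)
      }
    } else {
      out[[length(out) + 1L]] <- motif_row(tr, idx, sequence_id, strand)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

motif_row <- function(tr, idx, sequence_id, strand) {
  loops <- tr$start[idx[-1L]] - tr$end[idx[-length(idx)]]
  df <- data.frame(sequence_id = sequence_id,
                   start = tr$start[idx[1L]],
                   end = tr$end[idx[length(idx)]],
                   strand = strand,
                   n_tracts = length(idx),
                   max_loop = max(loops))
  df$tract_start <- list(tr$start[idx])
  df$tract_end <- list(tr$end[idx])
  df$loops <- list(loops)
  df
}

#' Scan a multi-record FASTA file for G4 motifs
#'
#' @param fasta Path to a FASTA file.
#' @inheritParams scan_g4
#' @return A `g4_hits` data frame combining all records.
#' @export
scan_g4_fasta <- function(fasta, g_min = 3L, loop_min = 1L, loop_max = 7L,
                          both_strands = FALSE, all_decompositions = FALSE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequences in ", fasta, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  hits <- lapply(seq_along(seqs), function(i)
    scan_g4(toupper(as.character(seqs[[i]])), g_min, loop_min, loop_max,
            both_strands, all_decompositions, sequence_id = ids[i]))
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  class(res) <- c("g4_hits", "data.frame")
  res
}

#' Classify a G4 motif as a leading- or lagging-strand obstacle
#'
#' Replication stalling at a G4 perturbs local histone recycling only when
#' the G-rich strand serves as the leading-strand template. For a fork
#' entering the locus from the right (moving leftward), the leading-strand
#' template is the top (forward) strand; inverting either the motif strand
#' or the fork entry side flips the call.
#'
#' @param strand Motif strand, `"+"` (G-rich strand on top) or `"-"`, or a
#'   `g4_hits` row / data frame with a `strand` column (vectorized).
#' @param fork_entry Side from which the fork enters the locus:
#'   `"right"` or `"left"`.
#' @return `"leading"` or `"lagging"` (character vector).
#' @examples
#' classify_fork_orientation("+", "right")  # leading
#' classify_fork_orientation("-", "right")  # lagging
#' @export
classify_fork_orientation <- function(strand, fork_entry = c("right", "left")) {
  fork_entry <- match.arg(fork_entry)
  if (is.data.frame(strand)) strand <- strand$strand
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  g_on_top <- strand == "+"
  leading <- g_on_top == (fork_entry == "right")
  ifelse(leading, "leading", "lagging")
}

#' Write G4 scan results as BED6
#'
#' The name field carries `maxloop:<n>` and the score the number of tracts,
#' so downstream tools can filter on loop geometry.
#'
#' @param hits A `g4_hits` data frame from [scan_g4()] / [scan_g4_fasta()].
#' @param path Output path.
#' @export
write_g4_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$sequence_id,
                    start = hits$start,
                    end = hits$end,
                    name = sprintf("maxloop:%d", hits$max_loop),
                    score = hits$n_tracts,
                    strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write G4 scan results as a TSV with per-motif loop lists
#'
#' @param hits A `g4_hits` data frame.
#' @param path Output path.
#' @export
write_g4_tsv <- function(hits, path) {
  flat <- data.frame(sequence_id = hits$sequence_id,
                     start = hits$start,
                     end = hits$end,
                     strand = hits$strand,
                     n_tracts = hits$n_tracts,
                     max_loop = hits$max_loop,
                     loops = vapply(hits$loops, paste, "", collapse = ","))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.g4_hits <- function(x, ...) {
  cat(sprintf("G4 scan: %d motif(s)\n", nrow(x)))
  if (nrow(x) > 0L) {
    show <- x[, c("sequence_id", "start", "end", "strand",
                  "n_tracts", "max_loop")]
    show$loops <- vapply(x$loops, paste, "", collapse = ",")
    print.data.frame(show, ...)
  }
  invisible(x)
}
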