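#' Synthetic-data specification
#'
#' Collects every knob of the synthetic-data generators in one validated
#' object, so that each generator is a pure function of its spec and seed
#' and emits ground-truth sidecars sufficient to score the downstream
#' analysis.
#'
#' @param seed Integer seed; all generator randomness flows from it.
#' @param n_clones Clones per fluctuation dataset.
#' @param true_p True per-division, per-allele event probability.
#' @param alleles An [allele_config()].
#' @param n_divisions Divisions per clonal expansion.
#' @param n_start Founding cells per clone.
#' @param noise A [facs_noise()].
#' @param planted_motifs Named list `sequence -> copies` of motifs to plant
#'   in synthetic FASTA background.
#' @param bg_length Background sequence length (nt) per FASTA record.
#' @param gc Background GC content.
#' @param max_g_run Cap on background G and C runs (`Inf` to disable);
#'   capping at `g_min - 1` guarantees negative controls free of motifs on
#'   either strand.
#' @param chip_truth Data frame `population`, `region`, `ratio` of true
#'   normalized ChIP ratios (reference population at 1).
#' @param chip_sd Lognormal (multiplicative) noise sd on qPCR signals.
#' @param meth_truth Named numeric vector region -> per-CpG methylation
#'   probability.
#' @param n_cpg CpG sites per bisulphite clone.
#' @param n_meth_clones Bisulphite clones per region.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_clones = 50L, true_p = 0.067,
                           alleles = allele_config(),
                           n_divisions = 20L, n_start = 2L,
                           noise = facs_noise(),
                           planted_motifs = list(), bg_length = 1000L,
                           gc = 0.5, max_g_run = Inf,
                           chip_truth = NULL, chip_sd = 0,
                           meth_truth = NULL, n_cpg = 20L,
                           n_meth_clones = 8L) {
  stopifnot(true_p >= 0, true_p <= 1, gc > 0, gc < 1,
            inherits(alleles, "allele_config"), inherits(noise, "facs_noise"))
  structure(list(seed = as.integer(seed), n_clones = as.integer(n_clones),
                 true_p = true_p, alleles = alleles,
                 n_divisions = as.integer(n_divisions),
                 n_start = as.integer(n_start), noise = noise,
                 planted_motifs = planted_motifs,
                 bg_length = as.integer(bg_length), gc = gc,
                 max_g_run = max_g_run, chip_truth = chip_truth,
                 chip_sd = chip_sd, meth_truth = meth_truth,
                 n_cpg = as.integer(n_cpg),
                 n_meth_clones = as.integer(n_meth_clones)),
            class = "synthetic_spec")
}

# i.i.d. background with optional cap on G- and C-run length (the cap
# covers both strands: a C run on the top strand is a G run on the bottom)
random_background <- function(n, gc, max_g_run, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- sample(names(probs), n, replace = TRUE, prob = probs)
  if (is.finite(max_g_run)) {
    repeat {
      r <- rle(s)
      bad <- which(r$values %in% c("G", "C") & r$lengths > max_g_run)
      if (length(bad) == 0L) break
      ends <- cumsum(r$lengths)
      for (i in bad) {
        run <- (ends[i] - r$lengths[i] + 1L):ends[i]
        over <- run[seq(max_g_run + 1L, length(run), by = max_g_run + 1L)]
        s[over] <- sample(c("A", "T"), length(over), replace = TRUE)
      }
    }
  }
  paste(s, collapse = "")
}

#' Generate a synthetic FASTA with planted G4 motifs and a truth BED
#'
#' Emits one FASTA record of random background sequence with each planted
#' motif inserted (replacing background) at random non-overlapping
#' positions, on randomly chosen strands unless specified. A sidecar BED6
#' of the true insert coordinates is written next to the FASTA.
#'
#' @param spec A [synthetic_spec()] whose `planted_motifs` is a list of
#'   entries `list(sequence =, copies =, strand =)` (strand `"+"`, `"-"` or
#'   `NULL` for random).
#' @param fasta_path,bed_path Output paths (`bed_path` defaults to the
#'   FASTA path with a `.truth.bed` suffix).
#' @param record_id FASTA record name.
#' @return Invisibly, a data frame of the planted truth (also written as
#'   BED): `start`, `end`, `strand`, `sequence`.
#' @export
make_fasta <- function(spec, fasta_path, bed_path = NULL,
                       record_id = "synthetic") {
  if (is.null(bed_path)) bed_path <- paste0(fasta_path, ".truth.bed")
  set.seed(spec$seed)
  bg <- strsplit(random_background(spec$bg_length, spec$gc, spec$max_g_run),
                 "")[[1L]]
  truth <- data.frame(start = integer(), end = integer(),
                      strand = character(), sequence = character())
  occupied <- rep(FALSE, spec$bg_length)
  for (m in spec$planted_motifs) {
    stopifnot(!grepl("[^ACGTN]", m$sequence))
    copies <- m$copies %||% 1L
    for (k in seq_len(copies)) {
      w <- nchar(m$sequence)
      strand <- m$strand %||% sample(c("+", "-"), 1L)
      ins <- if (strand == "+") m$sequence else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(m$sequence)))
      # rejection-sample a free slot; 8 nt clearance between inserts so
      # separate plants cannot chain into one motif (loop_max default 7)
      for (try in 1:1000) {
        pos <- sample.int(spec$bg_length - w - 1L, 1L)  # 0-based start
        span <- (pos + 1L):(pos + w)
        clear <- (max(1L, pos - 7L)):(min(spec$bg_length, pos + w + 8L))
        if (!any(occupied[clear])) break
        if (try == 1000L) stop("could not place motif; increase bg_length",
                               call. = FALSE)
      }
      bg[span] <- strsplit(ins, "")[[1L]]
      occupied[pmax(1L, pos - 7L):pmin(spec$bg_length, pos + w + 8L)] <- TRUE
      truth <- rbind(truth, data.frame(start = pos, end = pos + w,
                                       strand = strand,
                                       sequence = m$sequence))
    }
  }
  writeLines(c(paste0(">", record_id), paste(bg, collapse = "")), fasta_path)
  bed <- if (nrow(truth) == 0L) truth else
    data.frame(chrom = record_id, start = truth$start, end = truth$end,
               name = truth$sequence, score = 0L, strand = truth$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(truth)
}

#' Generate a synthetic fluctuation dataset with known ground truth
#'
#' Simulates `n_clones` independent clonal expansions at the spec's
#' `true_p` through the branching-process engine, then the FACS readout
#' model, emulating the fluctuation-assay design (clones expanded from a
#' couple of founder cells over ~20 divisions, percent loss read by flow
#' cytometry). Per-clone RNG substreams are derived deterministically from
#' the top-level seed.
#'
#' @param spec A [synthetic_spec()].
#' @param genotype Label for the dataset.
#' @return A [fluctuation_dataset()] with attribute `true_p`.
#' @export
make_fluctuation <- function(spec, genotype = "synthetic") {
  set.seed(spec$seed)
  clone_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_clones)
  tp <- transition_params(spec$true_p, alleles = spec$alleles)
  pct <- vapply(clone_seeds, function(s) {
    sc <- sim_config(spec$n_divisions, spec$n_start, seed = s,
                     engine = "counts")
    st <- simulate_clone(tp, sc)
    measure_clone(st, spec$noise)$pct_loss
  }, 0)
  ds <- fluctuation_dataset(pct, genotype)
  attr(ds, "true_p") <- spec$true_p
  ds
}

#' Generate synthetic ChIP-qPCR and bisulphite tables with known truth
#'
#' ChIP signals are drawn so that double-normalized ratios equal the spec's
#' `chip_truth` up to multiplicative lognormal noise (sd `chip_sd` on the
#' log scale); bisulphite CpG calls are Bernoulli draws at the spec's
#' per-region `meth_truth` rates.
#'
#' @param spec A [synthetic_spec()] with non-NULL `chip_truth` and/or
#'   `meth_truth`.
#' @return A list with data frames `chip` (population, region,
#'   target_signal, h3_signal) and `meth` (clone_id, region, cpg_index,
#'   call).
#' @export
make_chip_and_meth <- function(spec) {
  set.seed(spec$seed + 1L)
  chip <- NULL
  if (!is.null(spec$chip_truth)) {
    ct <- spec$chip_truth
    h3 <- stats::rlnorm(nrow(ct), meanlog = 0, sdlog = spec$chip_sd)
    noise <- stats::rlnorm(nrow(ct), meanlog = 0, sdlog = spec$chip_sd)
    chip <- data.frame(population = ct$population, region = ct$region,
                       target_signal = ct$ratio * h3 * noise,
                       h3_signal = h3)
  }
  meth <- NULL
  if (!is.null(spec$meth_truth)) {
    rows <- list()
    for (r in names(spec$meth_truth)) {
      for (cl in seq_len(spec$n_meth_clones)) {
        calls <- stats::rbinom(spec$n_cpg, 1L, spec$meth_truth[[r]])
        rows[[length(rows) + 1L]] <-
          data.frame(clone_id = sprintf("bs%02d", cl), region = r,
                     cpg_index = seq_len(spec$n_cpg),
                     call = ifelse(calls == 1L, "M", "U"))
      }
    }
    meth <- do.call(rbind, rows)
    rownames(meth) <- NULL
  }
  list(chip = chip, meth = meth)
}
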