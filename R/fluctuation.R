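#' FACS readout noise model
#'
#' Flow-cytometric quantification of the fraction of cells outside the HIGH
#' gate is modelled as binomial sampling of `n_events` cells with a
#' symmetric per-cell gate misclassification probability. Estimates below
#' the quantification floor are flagged unreliable: the intrinsic noise of
#' the gate-based assay prevents accurate rate determination when the loss
#' population is small (below about 10%).
#'
#' @param n_events Cells analyzed per clone.
#' @param misclass Probability a cell is called on the wrong side of the
#'   HIGH gate (in `[0, 0.5)`). Asymmetric rates can be given as a length-2
#'   vector `c(high_to_loss, loss_to_high)`.
#' @param quant_floor Not-HIGH fraction below which rate estimates are
#'   flagged unreliable.
#' @return An object of class `facs_noise`.
#' @export
facs_noise <- function(n_events = 10000L, misclass = 0.01,
                       quant_floor = 0.10) {
  stopifnot(n_events >= 1L, all(misclass >= 0), all(misclass < 0.5),
            length(misclass) %in% 1:2,
            quant_floor >= 0, quant_floor <= 1)
  if (length(misclass) == 1L) misclass <- c(misclass, misclass)
  structure(list(n_events = as.integer(n_events), misclass = misclass,
                 quant_floor = quant_floor),
            class = "facs_noise")
}

#' Measure a clone's percent loss by simulated flow cytometry
#'
#' Samples `n_events` cells with replacement in proportion to the clone's
#' state counts, flips each HIGH/not-HIGH call with the gate
#' misclassification probability, and returns the observed percentage of
#' cells outside the HIGH gate.
#'
#' @param state A `clone_state` from [simulate_clone()], or any named
#'   vector/matrix-row with `HIGH`, `MEDIUM`, `LOW` counts.
#' @param noise A [facs_noise()].
#' @param seed Optional integer seed.
#' @return A data frame row with `clone_id` (NA, fill as needed) and
#'   `pct_loss` in `[0, 100]`.
#' @export
measure_clone <- function(state, noise = facs_noise(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tot <- sum(state)
  if (tot <= 0) stop("empty clone state", call. = FALSE)
  f <- (sum(state) - state[["HIGH"]]) / tot
  pct <- measure_fraction(f, noise)
  data.frame(clone_id = NA_character_, pct_loss = pct)
}

# vectorized core: true not-HIGH fractions -> observed pct_loss
measure_fraction <- function(f, noise) {
  n <- length(f)
  k_loss <- stats::rbinom(n, noise$n_events, f)
  to_high <- stats::rbinom(n, k_loss, noise$misclass[2L])
  to_loss <- stats::rbinom(n, noise$n_events - k_loss, noise$misclass[1L])
  100 * (k_loss - to_high + to_loss) / noise$n_events
}

#' Build a fluctuation dataset
#'
#' One fluctuation dataset holds, for one genotype, the percentage of cells
#' in each independently expanded clone that have lost HIGH expression.
#'
#' @param pct_loss Numeric vector of per-clone percent-loss values (0-100).
#' @param genotype Label for the dataset.
#' @param clone_id Optional clone identifiers.
#' @return An object of class `fluctuation_dataset` (a data frame with
#'   columns `clone_id`, `pct_loss` and a `genotype` attribute).
#' @export
fluctuation_dataset <- function(pct_loss, genotype = "unknown",
                                clone_id = NULL) {
  stopifnot(length(pct_loss) >= 1L, all(pct_loss >= 0), all(pct_loss <= 100))
  if (is.null(clone_id))
    clone_id <- sprintf("clone%03d", seq_along(pct_loss))
  ds <- data.frame(clone_id = as.character(clone_id), pct_loss = pct_loss)
  attr(ds, "genotype") <- genotype
  class(ds) <- c("fluctuation_dataset", "data.frame")
  ds
}

#' Read / write fluctuation datasets as TSV
#'
#' The on-disk format is a two-column TSV with header
#' `clone_id<TAB>pct_loss`, one row per expanded clone.
#'
#' @param path File path.
#' @param genotype Genotype label attached on read.
#' @return For `read_fluctuation_tsv`, a [fluctuation_dataset()].
#' @export
read_fluctuation_tsv <- function(path, genotype = "unknown") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("clone_id", "pct_loss") %in% names(tab)))
    stop("fluctuation TSV needs columns clone_id and pct_loss: ", path,
         call. = FALSE)
  fluctuation_dataset(tab$pct_loss, genotype, tab$clone_id)
}

#' @rdname read_fluctuation_tsv
#' @param ds A [fluctuation_dataset()].
#' @export
write_fluctuation_tsv <- function(ds, path) {
  utils::write.table(ds[, c("clone_id", "pct_loss")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Median and interquartile range of per-clone percent loss
#'
#' Quartiles use the linear-interpolation convention of
#' [stats::quantile()] type 7 (the R default), so e.g. clones at
#' 10/20/30% give a median of 20 and an IQR of (15, 25).
#'
#' @param ds A [fluctuation_dataset()] or numeric vector of percentages.
#' @return A list with `median`, `iqr` (length-2: 25th and 75th
#'   percentiles) and `n_clones`.
#' @export
fluct_summary <- function(ds) {
  x <- if (is.data.frame(ds)) ds$pct_loss else ds
  stopifnot(length(x) >= 1L)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = qs[2L], iqr = c(qs[1L], qs[3L]), n_clones = length(x))
}

#' @export
print.fluctuation_dataset <- function(x, ...) {
  s <- fluct_summary(x)
  cat(sprintf("fluctuation dataset '%s': %d clones, median %.1f%%, IQR [%.1f, %.1f]%%\n",
              attr(x, "genotype") %||% "unknown", s$n_clones, s$median,
              s$iqr[1L], s$iqr[2L]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate the per-division loss probability by Monte-Carlo inversion
#'
#' Luria-Delbruck-style fluctuation analysis: for each candidate
#' per-division probability `p` on a grid, `n_reps` clones are simulated
#' through the full generative pipeline (clonal expansion with sequential
#' irreversible transitions, then the FACS readout model) and the simulated
#' percent-loss distribution is compared with the observed one. The default
#' distance is the absolute difference of medians (matching the summary
#' statistic used to display fluctuation data); a two-sample
#' Kolmogorov-Smirnov statistic is available via `metric = "ks"`. The
#' estimate is the grid argmin (ties broken toward smaller `p`), refined
#' once on a finer local grid. A bootstrap over observed clones (reusing
#' the simulated samples) gives a percentile confidence interval.
#'
#' @param ds A [fluctuation_dataset()] of observed per-clone percent loss.
#' @param tp_template A [transition_params()] carrying the allele
#'   configuration and `q`; its `p` slot is replaced by each grid value.
#' @param sc A [sim_config()] (its `seed`, if any, is ignored in favour of
#'   `seed`).
#' @param noise A [facs_noise()].
#' @param grid Sorted candidate `p` values. Default 0 to 0.25 in steps of
#'   0.0025, with one refinement pass at step 0.0005 around the coarse
#'   minimum.
#' @param n_reps Simulated clones per grid point (>= 100).
#' @param seed Integer seed; the estimate is deterministic given
#'   `(seed, grid, n_reps)`.
#' @param metric `"median"` or `"ks"`.
#' @param refine Run the local refinement pass.
#' @param n_boot Bootstrap resamples for the confidence interval.
#' @param conf_level Confidence level of the bootstrap interval.
#' @return An object of class `estimate_result`: list with `p_hat`,
#'   `ci_low`, `ci_high`, `grid` (data frame of `p`, `distance`), `n_reps`,
#'   `distance_metric`, `reliable` (FALSE when the observed median is below
#'   the quantification floor) and `observed_median`.
#' @export
estimate_p <- function(ds, tp_template = transition_params(0.05),
                       sc = sim_config(), noise = facs_noise(),
                       grid = seq(0, 0.25, by = 0.0025),
                       n_reps = 500L, seed = 1L, metric = c("median", "ks"),
                       refine = TRUE, n_boot = 200L, conf_level = 0.95) {
  metric <- match.arg(metric)
  stopifnot(inherits(ds, "fluctuation_dataset") || is.data.frame(ds),
            length(grid) >= 1L, !is.unsorted(grid), n_reps >= 100L)
  obs <- ds$pct_loss
  obs_med <- stats::median(obs)
  reliable <- obs_med >= 100 * noise$quant_floor
  degenerate <- all(obs == 0) || all(obs == 100)
  if (degenerate)
    warning("degenerate dataset (all 0% or all 100%): boundary estimate",
            call. = FALSE)

  set.seed(as.integer(seed))
  point_seeds <- sample.int(.Machine$integer.max - 1L, length(grid) + 1000L)

  sim_at <- function(p, point_seed) {
    tp <- transition_params(p, tp_template$q, tp_template$alleles)
    sci <- sim_config(sc$n_divisions, sc$n_start, seed = point_seed,
                      engine = "counts")
    counts <- simulate_clones(tp, sci, n_reps)
    f <- 1 - counts[, "HIGH"] / rowSums(counts)
    measure_fraction(f, noise)
  }
  dist_fun <- function(sim, observed) {
    if (metric == "median") abs(stats::median(sim) - stats::median(observed))
    else suppressWarnings(stats::ks.test(sim, observed,
                                         exact = FALSE)$statistic)
  }

  sims <- lapply(seq_along(grid), function(i) sim_at(grid[i], point_seeds[i]))
  dists <- vapply(sims, dist_fun, 0, observed = obs)
  coarse <- data.frame(p = grid, distance = dists)
  best <- which(dists == min(dists))[1L]  # ties -> smaller p (grid sorted)

  full_grid <- coarse
  full_sims <- sims
  if (refine && length(grid) > 1L) {
    step <- min(diff(grid))
    lo <- max(min(grid), grid[best] - step)
    hi <- min(max(grid), grid[best] + step)
    fine <- setdiff(round(seq(lo, hi, by = step / 5), 10), round(grid, 10))
    if (length(fine) > 0L) {
      fine_seeds <- point_seeds[length(grid) + seq_along(fine)]
      fsims <- lapply(seq_along(fine),
                      function(i) sim_at(fine[i], fine_seeds[i]))
      fdists <- vapply(fsims, dist_fun, 0, observed = obs)
      full_grid <- rbind(full_grid, data.frame(p = fine, distance = fdists))
      full_sims <- c(full_sims, fsims)
      ord <- order(full_grid$p)
      full_grid <- full_grid[ord, , drop = FALSE]
      full_sims <- full_sims[ord]
      rownames(full_grid) <- NULL
    }
  }
  ibest <- which(full_grid$distance == min(full_grid$distance))[1L]
  p_hat <- full_grid$p[ibest]

  # bootstrap over observed clones, reusing the simulated samples
  boot_seed <- point_seeds[length(point_seeds)]
  set.seed(boot_seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    res <- obs[sample.int(length(obs), replace = TRUE)]
    d <- vapply(full_sims, dist_fun, 0, observed = res)
    full_grid$p[which(d == min(d))[1L]]
  }, 0)
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)

  structure(list(p_hat = p_hat,
                 ci_low = min(ci[1L], p_hat), ci_high = max(ci[2L], p_hat),
                 grid = full_grid, n_reps = as.integer(n_reps),
                 distance_metric = metric, reliable = reliable && !degenerate,
                 observed_median = obs_med, n_boot = as.integer(n_boot)),
            class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat("Per-division loss probability (Monte-Carlo inversion)\n")
  cat(sprintf("  p_hat    : %.4f\n", x$p_hat))
  cat(sprintf("  CI       : [%.4f, %.4f] (bootstrap, %d resamples)\n",
              x$ci_low, x$ci_high, x$n_boot))
  cat(sprintf("  metric   : %s, %d simulated clones per grid point\n",
              x$distance_metric, x$n_reps))
  cat(sprintf("  observed : median %.1f%% loss\n", x$observed_median))
  cat(sprintf("  reliable : %s%s\n", x$reliable,
              if (!x$reliable) "  (observed loss below quantification floor)"
              else ""))
  invisible(x)
}

#' Compare two fluctuation datasets by binned Fisher exact test
#'
#' Per-clone percent-loss values are binned into `100 / bin_width`
#' categories (`[0,20) [20,40) [40,60) [60,80) [80,100]` at the default
#' width), the two genotypes form a 2 x k contingency table (columns empty
#' in both groups are dropped), and the exact conditional p-value is
#' computed by enumerating tables with the observed margins and summing the
#' probabilities of those no more probable than the observed table
#' (hypergeometric kernel; [stats::fisher.test()]).
#'
#' @param a,b [fluctuation_dataset()] objects.
#' @param bin_width Bin width in percent; must divide 100.
#' @return The two-sided exact p-value.
#' @export
compare_fluctuations <- function(a, b, bin_width = 20) {
  stopifnot(100 %% bin_width == 0)
  xa <- a$pct_loss; xb <- b$pct_loss
  if (length(xa) == 0L || length(xb) == 0L)
    stop("empty fluctuation dataset", call. = FALSE)
  cuts <- seq(bin_width, 100 - bin_width, by = bin_width)
  k <- 100 %/% bin_width
  bin_a <- tabulate(findInterval(xa, cuts) + 1L, nbins = k)
  bin_b <- tabulate(findInterval(xb, cuts) + 1L, nbins = k)
  tab <- rbind(bin_a, bin_b)
  tab <- tab[, colSums(tab) > 0L, drop = FALSE]
  if (ncol(tab) < 2L) return(1)  # all clones in one bin: no association
  stats::fisher.test(tab, workspace = 2e7)$p.value
}
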