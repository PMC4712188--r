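#' ChIP-qPCR double normalization
#'
#' Normalizes each target ChIP signal first to the total-H3 signal of the
#' same population/region (controlling for nucleosome occupancy), then to
#' the H3-normalized signal of the reference population for that region, so
#' the reference maps to 1 exactly. Signals are linear quantities (already
#' converted from Ct).
#'
#' @param measurements Data frame with columns `population`, `region`,
#'   `target_signal`, `h3_signal` (signals > 0).
#' @param reference Reference population label (default `"high"`).
#' @return A data frame `population`, `region`, `ratio`.
#' @examples
#' m <- data.frame(population = c("high", "low"), region = "tss",
#'                 target_signal = c(4, 2), h3_signal = c(1, 1))
#' chip_normalize(m)  # low/tss -> 0.5
#' @export
chip_normalize <- function(measurements, reference = "high") {
  req <- c("population", "region", "target_signal", "h3_signal")
  if (!all(req %in% names(measurements)))
    stop("measurements need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(measurements$target_signal <= 0) || any(measurements$h3_signal <= 0))
    stop("qPCR signals must be strictly positive", call. = FALSE)
  m <- measurements
  m$h3_norm <- m$target_signal / m$h3_signal
  out <- lapply(split(m, m$region), function(reg) {
    ref <- reg$h3_norm[reg$population == reference]
    if (length(ref) != 1L)
      stop("reference population '", reference,
           "' missing (or duplicated) for region ", reg$region[1L],
           call. = FALSE)
    data.frame(population = reg$population, region = reg$region,
               ratio = reg$h3_norm / ref)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value from the t distribution.
#'
#' @param a,b Numeric vectors, each of length >= 2; at least one group must
#'   have nonzero variance.
#' @return A list with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("both groups have zero variance", call. = FALSE)
  sa <- va / length(a); sb <- vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (length(a) - 1L) + sb^2 / (length(b) - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Percentage of methylated CpG sites
#'
#' Pools bisulphite CpG calls across clones for one region and returns
#' 100 * methylated / total; per-clone percentages are also reported. The
#' pooled value is the primary output.
#'
#' @param calls Data frame with columns `clone_id`, `region`, `call`
#'   (values `"M"` methylated / `"U"` unmethylated).
#' @param region Region to summarize (e.g. `"minus0.5kb"`, `"plus0.5kb"`).
#' @return A list with `percent` (pooled), `per_clone` (data frame
#'   `clone_id`, `percent`, `n_calls`) and `n_calls` (total).
#' @export
methylation_percent <- function(calls, region) {
  req <- c("clone_id", "region", "call")
  if (!all(req %in% names(calls)))
    stop("calls need columns ", paste(req, collapse = ", "), call. = FALSE)
  x <- calls[calls$region == region, , drop = FALSE]
  if (nrow(x) == 0L) stop("no CpG calls for region ", region, call. = FALSE)
  if (!all(x$call %in% c("M", "U")))
    stop("calls must be 'M' or 'U'", call. = FALSE)
  meth <- x$call == "M"
  per <- lapply(split(meth, x$clone_id), function(v)
    c(percent = 100 * mean(v), n_calls = length(v)))
  per_clone <- data.frame(clone_id = names(per),
                          percent = vapply(per, `[[`, 0, "percent"),
                          n_calls = vapply(per, `[[`, 0, "n_calls"))
  rownames(per_clone) <- NULL
  list(percent = 100 * mean(meth), per_clone = per_clone,
       n_calls = length(meth))
}
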