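#' Allele configuration for the reporter locus
#'
#' The reporter surface protein is encoded by the A allele; a G4 motif may
#' sit on the A allele, the B allele, or both. With transvection, a
#' silencing event triggered at either G4-bearing allele leads to loss of
#' expression of the monitored A allele, so both alleles contribute to the
#' per-division hazard.
#'
#' @param g4_on_A,g4_on_B Logical; does the allele carry the G4 motif?
#' @param transvection Logical; couple loss between the alleles. Only
#'   meaningful when both alleles carry a G4.
#' @return An object of class `allele_config`.
#' @export
allele_config <- function(g4_on_A = TRUE, g4_on_B = TRUE,
                          transvection = TRUE) {
  structure(list(g4_on_A = isTRUE(g4_on_A), g4_on_B = isTRUE(g4_on_B),
                 transvection = isTRUE(transvection)),
            class = "allele_config")
}

#' Per-division state-transition parameters
#'
#' @param p Per-division probability, per G4-bearing allele, of the
#'   triggering event that moves a HIGH cell to MEDIUM (in `[0,1]`).
#' @param q Per-division probability of the MEDIUM to LOW step. Defaults to
#'   `p`; the headline statistic (fraction of cells no longer HIGH) does not
#'   depend on `q`.
#' @param alleles An [allele_config()].
#' @return An object of class `transition_params`.
#' @export
transition_params <- function(p, q = p, alleles = allele_config()) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1,
            is.numeric(q), length(q) == 1L, q >= 0, q <= 1,
            inherits(alleles, "allele_config"))
  structure(list(p = p, q = q, alleles = alleles),
            class = "transition_params")
}

#' Simulation configuration for clonal expansion
#'
#' Defaults mirror the fluctuation-assay design: clones expanded from about
#' two cells to about 10^6, i.e. an average of 20 divisions.
#'
#' @param n_divisions Number of synchronous divisions (0-22; the agent
#'   engine materializes every cell, so the population is capped).
#' @param n_start Number of founding HIGH cells.
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @param engine `"counts"` (binomial count propagation, scalable) or
#'   `"agent"` (per-cell Bernoulli draws); the two are distributionally
#'   equivalent.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_divisions = 20L, n_start = 2L, seed = NULL,
                       engine = c("counts", "agent")) {
  engine <- match.arg(engine)
  n_divisions <- as.integer(n_divisions)
  n_start <- as.integer(n_start)
  stopifnot(n_divisions >= 0L, n_start >= 1L)
  if (engine == "agent" && n_divisions > 22L)
    stop("agent engine capped at 22 divisions (population overflow)",
         call. = FALSE)
  structure(list(n_divisions = n_divisions, n_start = n_start,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 engine = engine),
            class = "sim_config")
}

#' Per-division hazard of losing HIGH expression
#'
#' Each G4-bearing allele independently triggers a silencing event with
#' probability `p` at every division. With transvection, an event at either
#' allele silences the monitored A allele, so the hazard is
#' `h = 1 - (1 - p)^k` with `k` the number of G4-bearing alleles; without
#' transvection only the A allele's own G4 counts. A locus with no G4 has
#' hazard 0.
#'
#' @param params A [transition_params()].
#' @return The per-division, per-daughter-cell probability of the
#'   HIGH to MEDIUM step.
#' @examples
#' division_hazard(transition_params(0.1))  # 1 - 0.9^2 = 0.19
#' @export
division_hazard <- function(params) {
  stopifnot(inherits(params, "transition_params"))
  al <- params$alleles
  k <- if (al$transvection) al$g4_on_A + al$g4_on_B else as.integer(al$g4_on_A)
  1 - (1 - params$p)^k
}

#' Simulate the clonal expansion of one clone
#'
#' Starting from `n_start` cells in the HIGH expression state, every
#' division doubles the population and each daughter cell independently
#' steps down at most one state: HIGH to MEDIUM with probability
#' `h = division_hazard(tp)` and MEDIUM to LOW with probability `q`.
#' Transitions are sequential and irreversible, so a cell cannot skip from
#' HIGH to LOW within one division and never moves back up.
#'
#' The `"agent"` engine draws a Bernoulli step for every cell; the
#' `"counts"` engine propagates state counts with binomial draws. Both
#' implement the same stochastic process.
#'
#' @param tp A [transition_params()].
#' @param sc A [sim_config()].
#' @return An object of class `clone_state`: a named integer vector with
#'   components `HIGH`, `MEDIUM`, `LOW` summing to `n_start * 2^n_divisions`.
#' @examples
#' simulate_clone(transition_params(0.067), sim_config(seed = 1))
#' @export
simulate_clone <- function(tp, sc) {
  stopifnot(inherits(tp, "transition_params"), inherits(sc, "sim_config"))
  if (!is.null(sc$seed)) set.seed(sc$seed)
  h <- division_hazard(tp)
  q <- tp$q
  if (sc$engine == "agent") {
    if (sc$n_divisions > 22L)
      stop("agent engine capped at 22 divisions (population overflow)",
           call. = FALSE)
    states <- rep.int(1L, sc$n_start)  # 1 HIGH, 2 MEDIUM, 3 LOW
    for (d in seq_len(sc$n_divisions)) {
      states <- rep(states, each = 2L)
      u <- stats::runif(length(states))
      states <- states +
        as.integer((states == 1L & u < h) | (states == 2L & u < q))
    }
    counts <- c(HIGH = sum(states == 1L), MEDIUM = sum(states == 2L),
                LOW = sum(states == 3L))
  } else {
    n <- c(sc$n_start, 0, 0)
    for (d in seq_len(sc$n_divisions)) {
      n <- 2 * n
      down_h <- stats::rbinom(1L, n[1L], h)
      down_m <- stats::rbinom(1L, n[2L], q)
      n <- n + c(-down_h, down_h - down_m, down_m)
    }
    counts <- c(HIGH = n[1L], MEDIUM = n[2L], LOW = n[3L])
  }
  structure(as.integer(counts), names = names(counts), class = "clone_state")
}

#' Simulate many clones at once (vectorized count propagation)
#'
#' Runs the counts engine across `n_clones` independent clones in parallel
#' vectorized form. Used internally by the Monte-Carlo inversion, where
#' hundreds of clones must be simulated per candidate parameter value.
#'
#' @inheritParams simulate_clone
#' @param n_clones Number of independent clones.
#' @return An integer matrix with `n_clones` rows and columns
#'   `HIGH`, `MEDIUM`, `LOW`.
#' @export
simulate_clones <- function(tp, sc, n_clones) {
  stopifnot(inherits(tp, "transition_params"), inherits(sc, "sim_config"),
            n_clones >= 1L)
  if (!is.null(sc$seed)) set.seed(sc$seed)
  h <- division_hazard(tp)
  q <- tp$q
  H <- rep.int(as.numeric(sc$n_start), n_clones)  # numeric: no int overflow
  M <- L <- numeric(n_clones)
  for (d in seq_len(sc$n_divisions)) {
    H <- 2 * H; M <- 2 * M; L <- 2 * L
    down_h <- stats::rbinom(n_clones, H, h)
    down_m <- stats::rbinom(n_clones, M, q)
    H <- H - down_h
    M <- M + down_h - down_m
    L <- L + down_m
  }
  cbind(HIGH = H, MEDIUM = M, LOW = L)
}

#' Expected fraction of cells no longer HIGH after n divisions
#'
#' A lineage remains HIGH only if all `n` of its division steps avoid the
#' hazard, so the expected not-HIGH fraction is `1 - (1 - h)^n` with `h`
#' from [division_hazard()]. This closed form is the analytic check for the
#' stochastic engines.
#'
#' @param p Per-division, per-allele event probability.
#' @param n Number of divisions.
#' @param alleles An [allele_config()].
#' @return Expected fraction in `[0,1]`.
#' @examples
#' expected_loss_fraction(0.067, 20, allele_config(TRUE, FALSE, FALSE))
#' @export
expected_loss_fraction <- function(p, n, alleles = allele_config()) {
  h <- division_hazard(transition_params(p, p, alleles))
  1 - (1 - h)^n
}

#' @export
print.clone_state <- function(x, ...) {
  cat("clone state (cells per expression level):\n")
  print(unclass(x))
  invisible(x)
}
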