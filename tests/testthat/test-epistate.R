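single_A <- allele_config(g4_on_A = TRUE, g4_on_B = FALSE,
                          transvection = FALSE)
no_g4 <- allele_config(g4_on_A = FALSE, g4_on_B = FALSE,
                       transvection = FALSE)

test_that("division hazard combines alleles and transvection correctly", {
  expect_equal(division_hazard(transition_params(0, alleles = allele_config())), 0)
  expect_equal(division_hazard(transition_params(0.067, alleles = single_A)),
               0.067)
  # transvection: either allele's event silences the reporter
  expect_equal(division_hazard(transition_params(0.1)), 1 - 0.9^2)
  expect_equal(division_hazard(transition_params(0.5, alleles = no_g4)), 0)
  # without transvection only the monitored allele's G4 counts
  both_no_tv <- allele_config(TRUE, TRUE, transvection = FALSE)
  expect_equal(division_hazard(transition_params(0.1, alleles = both_no_tv)),
               0.1)
})

test_that("two-coin enumeration reproduces the transvection hazard", {
  # either of two independent alleles triggering = 1 - P(neither)
  p <- 0.1
  outcomes <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE))
  prob <- ifelse(outcomes$a, p, 1 - p) * ifelse(outcomes$b, p, 1 - p)
  expect_equal(sum(prob[outcomes$a | outcomes$b]),
               division_hazard(transition_params(p)))
})

test_that("deterministic limits of the clone simulators are exact", {
  for (engine in c("agent", "counts")) {
    st <- simulate_clone(transition_params(0, 0),
                         sim_config(10, 2, seed = 1, engine = engine))
    expect_equal(unclass(st), c(HIGH = 2048L, MEDIUM = 0L, LOW = 0L))

    st <- simulate_clone(transition_params(1, 0, alleles = single_A),
                         sim_config(1, 1, seed = 1, engine = engine))
    expect_equal(unclass(st), c(HIGH = 0L, MEDIUM = 2L, LOW = 0L))

    # sequential: HIGH cannot skip to LOW; after 2 certain steps all LOW
    st <- simulate_clone(transition_params(1, 1, alleles = single_A),
                         sim_config(2, 1, seed = 1, engine = engine))
    expect_equal(unclass(st), c(HIGH = 0L, MEDIUM = 0L, LOW = 4L))
  }
})

test_that("simulation is reproducible and conserves/orders counts", {
  tp <- transition_params(0.1, 0.05)
  a <- simulate_clone(tp, sim_config(12, 2, seed = 99, engine = "agent"))
  b <- simulate_clone(tp, sim_config(12, 2, seed = 99, engine = "agent"))
  expect_identical(a, b)
  expect_equal(sum(a), 2L * 2L^12L)

  # conservation at every depth, for both engines
  for (engine in c("agent", "counts")) {
    for (d in 0:10) {
      st <- simulate_clone(tp, sim_config(d, 2, seed = 7, engine = engine))
      expect_equal(sum(st), 2L * 2L^d)
    }
  }

  # sequential transitions: with q = 0 no cell can ever reach LOW
  for (engine in c("agent", "counts")) {
    st <- simulate_clone(transition_params(0.3, 0),
                         sim_config(10, 2, seed = 13, engine = engine))
    expect_equal(st[["LOW"]], 0L)
  }

  # irreversibility: the expected HIGH fraction decays with divisions
  mean_high <- vapply(c(2, 6, 12, 18), function(d) {
    counts <- simulate_clones(tp, sim_config(d, 2, seed = 50 + d), 500L)
    mean(counts[, "HIGH"] / rowSums(counts))
  }, 0)
  expect_true(all(diff(mean_high) < 0))
})

test_that("agent and counts engines agree in mean and variance", {
  n_rep <- 2000L
  tp <- transition_params(0.1, 0.1, alleles = single_A)
  set.seed(101)
  agent <- t(vapply(seq_len(n_rep), function(i)
    unclass(simulate_clone(tp, sim_config(8, 2, engine = "agent"))),
    c(HIGH = 0L, MEDIUM = 0L, LOW = 0L)))
  counts <- simulate_clones(tp, sim_config(8, 2, seed = 202), n_rep)
  for (state in c("HIGH", "MEDIUM", "LOW")) {
    se <- sqrt(var(agent[, state]) / n_rep + var(counts[, state]) / n_rep)
    expect_lt(abs(mean(agent[, state]) - mean(counts[, state])), 3 * se)
    # variances comparable (ratio within Monte-Carlo slack)
    expect_lt(abs(log(var(agent[, state]) / var(counts[, state]))), 0.35)
  }
})

test_that("mean not-HIGH fraction matches the closed form", {
  tp <- transition_params(0.067, alleles = single_A)
  counts <- simulate_clones(tp, sim_config(20, 2, seed = 303), 2000L)
  loss <- 1 - counts[, "HIGH"] / rowSums(counts)
  expect_lt(abs(mean(loss) - expected_loss_fraction(0.067, 20, single_A)),
            0.01)
})

test_that("expected loss fraction is monotone in p, n and allele number", {
  ps <- c(0.005, 0.02, 0.067, 0.15)
  for (al in list(single_A, allele_config())) {
    loss_p <- vapply(ps, expected_loss_fraction, 0, n = 20, alleles = al)
    expect_true(all(diff(loss_p) > 0))
    loss_n <- vapply(c(5, 10, 20), function(n)
      expected_loss_fraction(0.05, n, al), 0)
    expect_true(all(diff(loss_n) > 0))
  }
  expect_gt(expected_loss_fraction(0.05, 20),
            expected_loss_fraction(0.05, 20, single_A))

  # simulated means inherit the ordering in p
  sim_loss <- vapply(seq_along(ps), function(i) {
    counts <- simulate_clones(transition_params(ps[i]),
                              sim_config(20, 2, seed = 400 + i), 1000L)
    mean(1 - counts[, "HIGH"] / rowSums(counts))
  }, 0)
  expect_true(all(diff(sim_loss) > 0))
})

test_that("the not-HIGH fraction is invariant to the MEDIUM->LOW rate q", {
  loss_frac <- function(q) {
    counts <- simulate_clones(transition_params(0.08, q),
                              sim_config(15, 2, seed = 77), 1500L)
    mean(1 - counts[, "HIGH"] / rowSums(counts))
  }
  expect_lt(abs(loss_frac(0) - loss_frac(0.5)), 0.015)
})

test_that("single-allele loss tends to half the transvection loss as p -> 0", {
  ratio <- function(p)
    expected_loss_fraction(p, 20, single_A) / expected_loss_fraction(p, 20)
  ps <- c(0.005, 0.002, 0.001, 1e-4, 1e-5)
  rs <- vapply(ps, ratio, 0)
  expect_true(all(diff(rs) < 0))          # monotone toward the limit
  expect_true(all(rs > 0.5))              # from above
  expect_lt(abs(ratio(0.002) - 0.5), 0.02)
  expect_lt(abs(ratio(1e-5) - 0.5), 1e-3)
})

test_that("agent engine refuses infeasible population sizes", {
  expect_error(sim_config(23, 2, engine = "agent"), "overflow|capped")
  expect_silent(sim_config(30, 2, engine = "counts"))
})
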