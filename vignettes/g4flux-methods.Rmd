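---
title: "Methods: simulating and inverting G4-driven epigenetic instability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and inverting G4-driven epigenetic instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4flux)
```

## The model

A reporter locus carries a G-quadruplex motif that can stall a replication
fork. Expression of the reporter takes one of three discrete, ordered
states — HIGH, MEDIUM, LOW — and transitions are *sequential* (one step
down at most per division; a cell cannot skip from HIGH to LOW within one
division, which is why MEDIUM is observed as a distinct intermediate
population) and *irreversible* (no upward transitions, no recovery of the
HIGH state).

At every division, each daughter cell in the HIGH state undergoes the
silencing-triggering event with the per-division hazard

$$h = 1 - (1 - p)^k,$$

where $p$ is the per-division, per-allele event probability and $k$ the
number of G4-bearing alleles that can trigger loss of the monitored
reporter allele. Three allele configurations matter in practice:

* **both alleles + transvection** (the default): a trigger at either allele
  silences the reporter, so $k = 2$;
* **single-allele knock-in**: $k = 1$, so $h = p$ exactly;
* **no G4**: $h = 0$, the locus is stable.

The transvection-like coupling is modelled as *instantaneous*: the division
in which either allele fires is the division in which the monitored allele
steps down. This is the simplest mechanism consistent with the observation
that loss of expression at one allele leads to loss at the other, and it
reproduces the roughly-half single-allele instability discussed below.
MEDIUM cells step to LOW with an independent per-division probability $q$.
The headline statistic of the assay — the fraction of cells no longer
HIGH — is invariant to $q$ (MEDIUM and LOW are pooled), so $q$ is a
nuisance parameter; it defaults to $q = p$ and is independently settable,
and we deliberately do not attempt to fit it.

Because a lineage is still HIGH after $n$ divisions if and only if all $n$
of its division steps avoided the hazard, the expected not-HIGH fraction
has the closed form

$$E[\text{loss}] = 1 - (1 - h)^n,$$

implemented in `expected_loss_fraction()` and used throughout the test
suite as the analytic anchor for the stochastic engines. The hazard is
applied once per daughter cell per division (not once per parental
division); this convention is what makes the closed form exact.

### A note on the "about 50%" single-allele effect

For small $p$, $h_{2} \approx 2p$, so the single-allele expected loss is
about half the two-allele value. The ratio
$\frac{1-(1-p)^n}{1-(1-h_2)^n}$ converges to $1/2$ only as $p \to 0$,
however, and the convergence is slow in the experimentally relevant range:

```{r ratio}
single <- allele_config(g4_on_A = TRUE, g4_on_B = FALSE, transvection = FALSE)
sapply(c(0.05, 0.01, 0.005, 0.002, 0.001),
       function(p) expected_loss_fraction(p, 20, single) /
                   expected_loss_fraction(p, 20))
```

At $p = 0.005$ and 20 divisions the exact ratio is 0.525, not 0.500; the
"approximately 50%" description of single-allele instability is accurate
as an approximation but should not be read as an exact prediction at
finite $p$. The test suite asserts the monotone convergence to 0.5 from
above rather than a fixed value at one $p$.

## Simulation engines

`simulate_clone()` offers two engines implementing the same process:

* **agent**: every cell is materialized and draws its own Bernoulli step.
  Transparent, but memory-bound; capped at 22 divisions
  ($n_\mathrm{start} \cdot 2^{22}$ cells).
* **counts**: only the three state counts are tracked; each division
  doubles the counts and draws the number of HIGH→MEDIUM and MEDIUM→LOW
  transitions from binomial distributions. Distributionally equivalent to
  the agent engine (verified in the tests by matching per-state means and
  variances at 2000 replicates) and effectively unbounded.

`simulate_clones()` vectorizes the counts engine across clones and is what
the estimator uses internally. Defaults mirror the assay design: clones
grow from `n_start = 2` founder cells over `n_divisions = 20` divisions
(about $10^6$ cells, i.e. three weeks of culture; calendar time itself is
not modelled, and real colonies vary somewhat around 20 divisions — the
parameter is configurable).

Reproducibility contract: every user-facing entry point takes a single
seed, from which per-clone (or per-grid-point) substreams are derived
deterministically, so replicate sets are reproducible regardless of
evaluation order and `sim clone`/`fluct simulate` CLI runs are
byte-identical under the same seed.

## FACS readout model

Flow cytometry does not observe the true not-HIGH fraction $f$ of a clone.
`measure_clone()` models the readout as: sample `n_events` cells
(default 10,000) with replacement in proportion to the state counts, then
flip each HIGH/not-HIGH gate call with a misclassification probability
(default 0.01, symmetric between the gates; asymmetric rates are
configurable as a length-2 vector). The observed mean is therefore
$f(1-\varepsilon) + (1-f)\varepsilon$ — slightly biased toward the middle,
exactly as a gate-based assay is. Estimates from datasets whose observed
median loss is below the quantification floor (default 10%) are flagged
`reliable = FALSE`: near the floor, gate noise dominates the signal and
the assay cannot resolve the underlying rate. The model deliberately stops
at the gate level — no scatter, compensation or staining-intensity model.

## Monte-Carlo inversion

The per-clone percent-loss values of a fluctuation experiment are plotted
and summarized as median and interquartile range; raw distributions are
heavily skewed and bounded, so moment-based estimators behave poorly.
`estimate_p()` therefore inverts the generative model by simulation:

1. For each candidate $p$ on a grid (default 0 to 0.25 in steps of 0.0025),
   simulate `n_reps` clones (default 500) through expansion *and* the FACS
   readout, and compute a distance between simulated and observed
   percent-loss distributions.
2. Take the argmin (ties broken toward smaller $p$), then refine once on a
   local grid at one fifth of the step around the coarse minimum.
3. Bootstrap the observed clones (default 200 resamples) and re-minimize,
   reusing the simulated samples, to get a percentile confidence interval.

The default distance is the absolute difference of medians — robust, and
matching the summary statistic used to display fluctuation data. A
two-sample Kolmogorov–Smirnov statistic (`metric = "ks"`) uses the full
distribution instead; on synthetic data both land in the same
neighbourhood, and the median metric is the default because its
minimization surface is smoother at small `n_reps`. How published
estimates matched simulation to data (medians, means or full
distributions) is generally not stated in the literature; exposing the
metric keeps that choice explicit.

Degenerate datasets (all clones at 0% or 100%) return the boundary
estimate with a warning and `reliable = FALSE` rather than an error.

Calibration is checked by parameter recovery: datasets of 50 clones
generated at a known $p = 0.067$ (both alleles + transvection, 20
divisions, default noise) are re-estimated to within ±0.015 across 20
datasets (the acceptance suite recomputes this; a single dataset of 50
clones carries a sampling error of roughly ±0.005 on the median-matched
estimate).

## Genotype comparison

`compare_fluctuations()` bins percent-loss values into 20%-wide classes
([0,20), [20,40), [40,60), [60,80), [80,100]; the last bin is closed so
100% loss is countable), forms the 2×k genotype-by-bin contingency table
(bins empty in both genotypes are dropped), and computes the exact
conditional two-sided p-value — the sum of probabilities of all tables
with the observed margins that are no more probable than the observed one
(hypergeometric kernel, via `stats::fisher.test`). If all clones of both
genotypes fall into one bin the function returns 1 without forming a
degenerate table. Exactness matters here because group sizes are a few
dozen clones at most; the test's conditional construction also keeps its
size at or below the nominal level (verified empirically in the
acceptance suite: ≤8% rejections at α = 0.05 under the null).

## G4 scanning

`scan_g4()` defines a motif as ≥4 maximal runs of ≥`g_min` guanines
separated by non-G loops of 1–`loop_max` nt. Conventions, chosen where the
field's regex-style scanners differ:

* **Maximal tracts**: a run of $k > g_\mathrm{min}$ Gs is one tract; loops
  are measured between maximal runs. This is what makes the printed
  benchmark motifs scan as loops [4,4,4] and [1,1,1].
* **Maximal motifs**: a chain of more than 4 qualifying tracts is one
  motif covering all of them (loop statistics are per structural unit);
  `all_decompositions = TRUE` emits every 4-tract window instead.
* **Defaults** `g_min = 3`, `loop_min = 1`, `loop_max = 7`; `g_min = 2` is
  selectable because biologically active quadruplexes with GG tracts and
  long loops exist (the weak benchmark motif is one).
* **Coordinates** are 0-based half-open on the forward axis everywhere,
  including minus-strand motifs (mapped from a reverse-complement scan),
  matching BED conventions natively.

`classify_fork_orientation()` encodes the strand logic of replication
stalling: for a fork entering the locus from the right, the top strand is
the leading-strand template, so a plus-strand (G-rich-on-top) motif is a
leading-strand obstacle; inverting the motif or the fork entry side flips
the call. Instability of the downstream locus is expected for
leading-strand G4s only. The scanner makes no thermodynamic or topology
predictions (melting temperature and folding are measured quantities, not
sequence-computable ones at this level).

## Synthetic data

Every input format has a generator, a pure function of a `synthetic_spec`
and its seed, emitting ground-truth sidecars:

* `make_fasta()`: i.i.d. background (GC 50% default) with motifs planted
  at recorded coordinates/strands and a truth BED. The optional cap on
  background G *and* C run lengths guarantees negative controls free of
  motifs on either strand; placement keeps ≥8 nt between inserts so two
  plants cannot chain into one motif. Real genomic sequence is not i.i.d.
  (repeats, GC skew, clustered G-richness), so scanner specificity
  measured on this background does not transfer to genomes — the generator
  is for correctness testing, not benchmarking.
* `make_fluctuation()`: clones simulated at a known `true_p` through the
  full expansion + readout pipeline. This emulates clone-to-clone
  stochasticity and gate noise, but not inter-experiment effects (batch
  staining differences, variable division numbers per clone, cell death or
  selection) — passing recovery tests shows the estimator is calibrated
  for the stated model, not that real experiments are free of those
  effects.
* `make_chip_and_meth()`: qPCR signals with multiplicative lognormal noise
  around planted normalized ratios (reference population anchored at 1)
  and per-CpG Bernoulli bisulphite calls at planted rates. Methylation is
  reported pooled across clones (primary) and per clone, since either
  aggregation is defensible.

## Numerical choices and problem sizes

* Quartiles use the linear-interpolation convention (`stats::quantile`
  type 7), so three clones at 10/20/30% give median 20, IQR (15, 25).
* Grid ties in the inversion break toward smaller $p$ (conservative).
* The ChIP normalizer refuses non-positive signals; Ct-to-quantity
  conversion is upstream of the package.
* Welch's statistic uses Satterthwaite degrees of freedom; with equal
  variances and group sizes it collapses to the pooled $2n-2$.
* The test and acceptance suites use 20 recovery datasets of 50 clones,
  2000-replicate engine-equivalence checks, and 200-replicate null
  calibration — sizes at which Monte-Carlo error is comfortably inside
  the asserted tolerances while the whole suite runs in a few minutes.

## Known limitations

* The estimator assumes the observed clones are independent expansions
  with a common, constant $p$; mixtures (heterogeneous subclones) will be
  averaged, not detected.
* No cell death, selection or growth-rate differences between states; if
  silenced states grow slower, $p$ is underestimated.
* The transvection coupling is all-or-none and instantaneous; delayed or
  partial coupling would need an extra parameter the percent-loss
  distribution alone cannot identify.
* Exact 2×k Fisher enumeration is feasible to a few dozen clones per
  group; far larger studies should switch to asymptotic tests.
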