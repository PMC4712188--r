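# g4flux

Fluctuation analysis of G-quadruplex-driven epigenetic instability.

## The problem

Some loci carry a G-quadruplex (G4) motif — four or more G tracts separated
by short non-G loops — that can stall a replication fork. When specialized
bypass factors are missing, stalling at a leading-strand G4 interrupts
histone recycling behind the fork and the locus stochastically, sequentially
and irreversibly steps down through discrete expression states
(HIGH → MEDIUM → LOW). The classic readout is a Luria–Delbrück-style
fluctuation experiment: many clones are expanded from a couple of founder
cells over roughly 20 divisions, the percentage of cells that have lost the
HIGH state is measured per clone by flow cytometry, and the per-division
probability of the silencing event is inferred from the distribution of
per-clone loss percentages.

`g4flux` is for researchers running (or reanalyzing) such reporter assays.
It provides:

* **G4 motif scanning** — tract/loop geometry of motifs in FASTA sequences,
  BED6/TSV output, and classification of each motif as a leading- or
  lagging-strand obstacle for a given fork direction.
* **Branching-process simulation** of clonal expansion with per-division,
  per-daughter hazards. With a G4 on both alleles and a transvection-like
  coupling (a silencing event at either allele silences the monitored
  reporter allele), the per-division hazard is `h = 1 − (1 − p)^k` with `k`
  the number of G4-bearing alleles; the expected not-HIGH fraction after
  `n` divisions is `1 − (1 − h)^n`.
* **Monte-Carlo inversion** (`estimate_p`): grid search over `p`, simulating
  the full pipeline — expansion plus a FACS readout model with gate
  misclassification and a 10% quantification floor — and matching the
  simulated to the observed percent-loss distribution (median distance by
  default, Kolmogorov–Smirnov optional), with a bootstrap confidence
  interval.
* **Genotype comparison** via Fisher's exact test on percent-loss values
  binned in 20% classes.
* **Chromatin-readout utilities**: ChIP-qPCR double normalization (target/H3,
  then relative to the HIGH population), Welch's t test, and bisulphite CpG
  methylation percentages.
* **Synthetic-data generators** with ground-truth sidecars for every input
  format, so the whole pipeline is testable without external data.

## Worked example

```r
library(g4flux)

# 1. Scan a strong-G4 sequence (GGG tracts, 1-nt loops)
scan_g4("TTTTGGGTGGGTGGGTGGGTTTT", g_min = 3)
#> G4 scan: 1 motif(s)
#>   sequence_id start end strand n_tracts max_loop loops
#> 1         seq     4  19      +        4        1 1,1,1

# 2. Simulate a fluctuation experiment: 50 clones, 20 divisions,
#    true per-division probability 0.067, G4 on both alleles + transvection
ds <- make_fluctuation(synthetic_spec(seed = 42, n_clones = 50, true_p = 0.067))
ds
#> fluctuation dataset 'synthetic': 50 clones, median 92.3%, IQR [91.3, 94.2]%

# 3. Recover the rate by Monte-Carlo inversion
estimate_p(ds, seed = 7)
#> Per-division loss probability (Monte-Carlo inversion)
#>   p_hat    : 0.0655
#>   CI       : [0.0640, 0.0700] (bootstrap, 200 resamples)
#>   metric   : median, 500 simulated clones per grid point
#>   observed : median 92.3% loss
#>   reliable : TRUE
```

The estimate lands within the grid resolution of the generating value
(0.067): the inversion is calibrated because the simulator used for fitting
is the generative model of the assay. `reliable = FALSE` flags datasets
whose observed median loss sits below the 10% FACS quantification floor,
where the assay cannot resolve the rate.

Comparing genotypes:

```r
wt  <- make_fluctuation(synthetic_spec(seed = 1, n_clones = 30, true_p = 0.002),
                        genotype = "wild-type")
mut <- make_fluctuation(synthetic_spec(seed = 2, n_clones = 30, true_p = 0.067),
                        genotype = "mutant")
compare_fluctuations(wt, mut)   # Fisher exact on 20% bins
#> [1] 1.69e-17
```

A command-line interface mirrors these functions
(`g4 scan`, `sim clone`, `fluct simulate|infer|compare`, `chip normalize`,
`meth percent`, `synth ...`); see `?g4flux_main`. Every run stamps a JSON
manifest (command line, seed, config digest, version, timestamp) next to
its output, and all randomness flows from `--seed`.

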