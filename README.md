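# barcodeSim

How many individuals per species do you need to sequence before a DNA
barcode library says something reliable about intraspecific variation?
`barcodeSim` answers this by simulation: it generates single-population
barcode datasets under the neutral coalescent and measures, by seeded
subsampling, how sample size affects four standard estimators of genetic
polymorphism:

* the **mismatch distribution** — the frequency distribution of all pairwise
  distances in a sample (histogram + kernel density estimate), including its
  gaps;
* **nucleotide diversity** π = (X₁ + … + X_k)/k, the mean of the
  k = n(n−1)/2 pairwise distances, compared against the full-dataset value β
  via the percentage of subsample estimates inside β ± 0.001;
* the **number of haplotypes**, with median haplotype accumulation fitted by
  the Michaelis–Menten saturation curve F(x) = ax/(1 + bx) (asymptote a/b,
  slope a/(1 + bx)²);
* the **maximum pairwise distance**, and how often a subsample recovers the
  full dataset's maximum.

The pipeline is self-contained: Kingman coalescent genealogies (waiting
times Exponential(j(j−1)/2) in units of 2N generations) for 300/500/1000
tips, tree-shape diagnostics (Colless imbalance, Aldous-style split profiles
near the root), branch-length rescaling with a case-by-case cap keeping the
realized maximum pairwise Jukes–Cantor distance under 3%, 1,500-bp sequence
evolution under the exact JC transition probability
p(t) = (3/4)(1 − e^(−4t/3)), JC distance correction
d = −(3/4)·ln(1 − 4p/3), min–max normalization of each dataset's distances
onto [0, 0.03], and an infinite-sites mutation overlay at θ = 4Nμ = 3 used
to validate the simulator against coalescent theory (E[pairwise
differences] = θ). Estimator stages equally accept user data: alignments as
FASTA (`Biostrings`), trees as Newick (`ape`).

## Worked example

```r
library(barcodeSim)

g <- simulateGenealogy(500, seed = 101)
tmrca(g)                               # 1.071 (units of 2N generations)
collessIndex(g, normalized = TRUE)     # 0.0165 (0 = balanced, 1 = caterpillar)

ds <- enforceDivergenceCap(g, L = 1500, cap = 0.03, seed = 102)
max(distValues(ds$matrix))             # 0.02715 -- the 3% cap holds
nm <- minmaxNormalize(ds$matrix)       # distances mapped onto [0, 0.03]
(beta <- nucleotideDiversity(nm))      # 0.018, the full-dataset diversity

sch <- subsampleSchedule("diversity", c(2, 5, 10, 20, 50, 100), 1000, seed = 103)
r <- runSchedule(m = nm, sched = sch, datasetId = "example")
bandSummary(r, beta)
#>   size   mean pctInBand
#>      2 0.0182       5.0
#>      5 0.0179      27.6
#>     10 0.0181      46.1
#>     20 0.0181      72.4
#>     50 0.0180      94.7
#>    100 0.0180      99.6
```

The subsample mean matches β at every size (π is exactly unbiased), but the
*concentration* around β is what improves with sampling: only 5% of
2-individual subsamples estimate β to within ±0.001, against 72% at 20 and
99.6% at 100 — the quantitative basis for recommending ≥ 20 individuals per
population.

Haplotype accumulation from the same dataset:

```r
hs <- subsampleSchedule("haplotypes", c(2, seq(10, 150, 10)), 100, seed = 104)
qs <- quartileSummary(runSchedule(aln = ds$alignment, sched = hs))
(fit <- fitMichaelisMenten(qs$size, qs$median))
#> MMFit: F(x) = a x / (1 + b x), a = 0.956189, b = 0.0140471
#>   asymptote a/b = 68.07, residual variance = 0.206 (16 points)
mmSlope(fit, 20)                       # 0.5828 new haplotypes/individual
```

`runStudy(defaultConfig(rootSeed = 1))` executes the full protocol — ten
500-sequence datasets plus one of 300 and one of 1000, with the
per-estimator subsampling schedules (10,000 replicates per size for
diversity and maximum distance, 100 for haplotypes, 10 for mismatch
distributions) — writing Newick/FASTA/CSV outputs and a JSON manifest from
which `configFromManifest()` reruns the study byte-identically.
`summarizeTable1()` assembles the study-wide diversity table.

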