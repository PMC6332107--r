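# HaploPop

Population structure and demographic history from single-locus haplotype
alignments.

HaploPop is an R package for the analysis arc that mitochondrial
control-region surveys run on aligned sequences from several sampled
localities: Who carries which haplotype, and how diverse is each
population? Do the localities form genetically distinct groups, and how
much of the molecular variance sits between them? Does differentiation
grow with geographic distance? And does the site-frequency and mismatch
structure record a past population expansion? The package is aimed at
population geneticists and conservation biologists working with mtDNA
(or any non-recombining locus) who want every step of that arc — from
FASTA to report tables — scriptable, seeded and testable.

## What it computes

Given an aligned multi-FASTA plus a two-column `id<TAB>population` map:

- **Haplotypes and sites** — complete-deletion filtering, haplotype
  collapsing, parsimony-informative vs singleton sites, Ts/Tv counts,
  base composition.
- **Diversity** — Nei's haplotype diversity
  `Hd = n/(n−1)·(1 − Σ p_i²)` with its sampling variance; mean pairwise
  differences `M` and nucleotide diversity `π = M/L` with Tajima's total
  variance.
- **Trees and networks** — Kimura two-parameter distances
  `d = −½ln(1−2P−Q) − ¼ln(1−2Q)`, neighbor-joining with column-bootstrap
  support, and Bandelt median-joining haplotype networks with inferred
  median vectors.
- **Structure** — one-level AMOVA
  (`ΦST = Va/(Va+Vb)` from the sums-of-squares decomposition with
  permutation p-values), haplotype-frequency Weir–Cockerham FST and
  distance-based ΦST pairwise matrices, Nei's corrected divergence
  `Da = ΠXY − (ΠX+ΠY)/2`, Bonferroni flags, and Mantel tests of
  isolation by distance (exact enumeration for small k).
- **Assignment** — Dirichlet-multinomial model-based clustering of
  individuals into panmictic groups with per-individual membership
  probabilities (maximum marginal likelihood over k ≤ 10, seeded
  restarts).
- **Demography** — Tajima's D and Fu's Fs with coalescent-simulation
  p-values, observed mismatch spectra, sudden-expansion model fits
  (τ, θ0, θ1 by least squares), SSD and Harpending raggedness with
  parametric-bootstrap p-values, and an entropy-based
  substitution-saturation check (ISS vs ISS.c).
- **Simulation** — a structured-coalescent sequence simulator (demes,
  migration, divergence, instantaneous expansion, finite- or
  infinite-sites Kimura mutation) so every stage can be validated
  against known truth; `twoRegionPreset()` reproduces the shape of a
  five-population, two-region survey (N = 97, 710 bp).

`runPipeline()` chains all stages and writes the conventional report
tables (diversity per population, AMOVA, Da above / FST below the
diagonal, neutrality and mismatch per population), newick, GML and TSV
exports, plus a run log; reruns under the same seed are byte-identical.

## Worked example

Simulate a survey with known truth and run the main stages:

```r
library(HaploPop)
cfg <- twoRegionPreset()            # 5 demes (15,15,22,21,24), 2 regions
ds  <- simulateDataset(cfg, seed = 42)
aln <- filterSites(ds@alignment)

cls <- classifySites(aln)
nrow(haplotypeCounts(collapseHaplotypes(aln)))  # 96 haplotypes among 97
cls$polymorphicSites                            # 444 (189 informative, 255 singleton)

amova(aln, permutations = 1000, seed = 1)
#> AMOVA (one level)
#>   Among populations : df=4  SS=627.670  Va=7.732  (48.22%)
#>   Within populations: df=92  SS=763.928  Vb=8.304  (51.78%)
#>   PhiST = 0.482  (p = 0, 1000 permutations)

fitClusters(aln, kMax = 10, replicates = 5, seed = 1)
#> ClusterResult: k=2 clusters, log marginal likelihood -5317.202
#> cluster
#>  1  2
#> 52 45

td <- tajimasD(subsetPopulations(aln, "P3"), reps = 1000, seed = 1)
#> Tajima's D (P3) = -2.117 (p = 0.011)

fitSuddenExpansion(mismatchObserved(subsetPopulations(aln, "P3")))
#> Sudden-expansion mismatch fit
#>   tau=15.7288  theta0=4.2167  theta1=103.2526  SSD=0.00545  raggedness=0.00562
```

Reading the output: 48% of the molecular variance lies among
populations (ΦST = 0.482, no permuted relabeling reached it), the
clustering recovers the two generating regions exactly (52 Brazilian-like
vs 45 Caribbean-like individuals), the strongly negative Tajima's D
flags the simulated expansion, and the mismatch fit recovers an
expansion time (τ ≈ 16 mutational units) near the preset's τ = 14 with
a large post-expansion θ1 — the truth that generated the data.

With real data, replace the simulated input:

```r
aln <- readAlignment("crab_cr.fasta", "crab_popmap.tsv")
res <- runPipeline(aln = aln, outDir = "results", config = runConfig(seed = 1))
```

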