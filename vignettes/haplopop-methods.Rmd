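---
title: "Models and methods behind HaploPop"
author: "HaploPop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind HaploPop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

HaploPop implements the standard analysis arc of a single-locus (typically
mitochondrial control-region) phylogeographic survey: from an aligned
multi-FASTA and a population map to diversity indices, trees, haplotype
networks, fixation indices, model-based cluster assignment, neutrality
tests and mismatch-distribution demography, with a structured-coalescent
simulator supplying data with known truth. This vignette explains the
models, the numerical choices, and what the tests do and do not
demonstrate.

## Input handling and site filtering

All statistics operate on a `PopAlignment` after *complete deletion*:
every column containing a gap (`-`) or `N` in any sequence is removed
before anything else is computed, so distances, segregating-site counts
and per-site entropies all refer to the same set of fully resolved
columns. Pairwise deletion is deliberately not offered: mixing per-pair
site sets makes pairwise difference counts incomparable across pairs and
is a common source of irreproducibility. The retained-column map is kept
so reports can cite 1-based positions in the original alignment.
Ambiguity codes other than `N` are rejected at read time: none of the
downstream statistics has a principled treatment for them, and silently
resolving them would fabricate data.

Haplotype identity is exact string equality on the filtered columns.
Transitions and transversions are counted over the unordered pairs of
distinct bases observed at each variable site (not over sequence pairs),
and the ratio is reported as transversions/transitions to match the
orientation commonly printed in control-region survey tables.

## Diversity indices

Haplotype diversity uses Nei's unbiased estimator
$H_d = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ with his sampling
variance of heterozygosity. The mean number of pairwise differences $M$
is the average Hamming distance over all $\binom{n}{2}$ pairs, and
nucleotide diversity is $\pi = M/L$ on the filtered length $L$, so
$\pi L = M$ is checkable in every report. For the standard deviation of
$M$ (and of $\pi$) we use Tajima's total variance
$b_1 M + b_2 M^2$, which includes the evolutionary (stochastic)
component and therefore gives the familiar SD $\approx M/2$ pattern at
control-region diversity levels. Published tables rarely name their
variance estimator, and alternatives (sampling-only, or the
$11(n^2-7n+6)$ form) differ by tens of percent; the choice is stated
here once and used everywhere.

## Distances, trees, networks

Kimura two-parameter distances are computed from the transition and
transversion proportions $P$ and $Q$ per pair,
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, with an explicit error
(naming the pair) when the arguments leave the model's domain —
truncating saturated distances silently would bias trees toward star
shapes. Distances are computed between haplotypes by default, matching
the usual practice of drawing trees over the distinct sequences.
Neighbor joining is delegated to ape's Saitou–Nei implementation;
negative branch lengths are truncated to zero with a flag. Bootstrap
support resamples filtered columns with replacement, rebuilds the
K2P+NJ tree, and counts for each internal edge of the point-estimate
tree the percentage of replicates containing the same bipartition
(mapped with `ape::prop.clades`, not a consensus tree). Replicates whose
resampled distance matrix is undefined are dropped and counted, with a
warning past 5%.

The median-joining network follows Bandelt's procedure on the
segregating columns: build the $\varepsilon$-relaxed minimum spanning
network (an edge survives when its length exceeds the bottleneck
connection cost of its endpoints by at most $\varepsilon$; the default
$\varepsilon = 0$ keeps exactly the union of all minimum spanning
trees), add quasi-median vectors (per-site majority; fully heterogeneous
sites contribute all three states, with the combinatorial blow-up capped
and a warning) for mutually connected triples, iterate to a fixpoint,
and finally prune median vectors that lie on no shortest path between
observed haplotypes. One property worth stating precisely: the finished
network need not contain the observed-only minimum spanning network
edge-for-edge — a median vector can replace a direct link by a shorter
two-step path (that is the point of the algorithm). What does hold, and
what the tests assert, is that every minimum-spanning-tree edge is
covered by a network path of no greater weight, and that the total
network length lies between the Steiner minimum (verified exhaustively
on small instances) and the MST length.

## AMOVA, fixation indices, isolation by distance

The one-level AMOVA uses raw pairwise nucleotide difference counts as
squared distances (the haplotypic convention of the standard software;
squared K2P distances can be supplied instead). With $k$ populations and
sums of squares partitioned among/within,

$$V_b = SS_w/(N-k), \qquad
  V_a = \frac{SS_a/(k-1) - V_b}{n'}, \qquad
  n' = \frac{N - \sum_i n_i^2/N}{k-1},$$

and $\Phi_{ST} = V_a/(V_a+V_b)$. Significance comes from permuting
individuals among populations; individuals are put in a canonical
(id-sorted) order before permutation so the p-value is invariant to the
input row order. Negative variance components and negative fixation
indices are reported as computed — truncation hides sampling noise and
biases means of matrices upward.

Pairwise differentiation is reported both ways that the field's tables
mix: a haplotype-frequency Weir–Cockerham $\theta$ (each haplotype an
allele at one haploid locus) and a distance-based $\Phi_{ST}$ (the
two-population AMOVA). The two can differ by an order of magnitude on
control-region data — with nearly all haplotypes unique, frequency-based
estimators lose most of the signal — which is why both matrices are
always emitted. Being unbiased, the Weir–Cockerham estimate is negative
when populations are effectively identical; this is expected behaviour,
not an error. The corrected average pairwise difference is Nei's
$D_A = \Pi_{XY} - (\Pi_X + \Pi_Y)/2$ applied literally; note that for
$X = Y$ it equals $-\pi/n$, not 0, because the cross-population average
spans $n^2$ ordered pairs. Bonferroni flags use $p \le \alpha/m$ with
the conventional reporting tiers (0.01 and 0.10 after correction).

The Mantel test correlates the condensed halves of the genetic and
geographic matrices and permutes rows and columns of one matrix jointly;
when $k! \le$ the requested permutation count the full permutation group
is enumerated and the p-value is exact. Geographic distances are the
user's responsibility — for coastal species the relevant metric is the
along-coast path, for which the provided great-circle helper is only a
lower bound.

## Model-based clustering

Individuals are grouped into panmictic clusters under a
Dirichlet-multinomial model: a cluster's marginal likelihood is a
product over variable sites of Dirichlet-multinomial terms with a
symmetric prior of $\alpha = 0.25$ per allele *observed at that site*
across the whole alignment. Restricting the prior support to the
observed alleles is the allele-based treatment of Bayesian population
assignment; with a fixed four-letter support, every near-constant column
would penalise any split by roughly $3\alpha\log n$ nats and the model
would prefer a single cluster even at $\Phi_{ST} \approx 0.5$ — a
regime the sensitivity analysis during development showed directly.
Constant columns then contribute nothing and are skipped.

The search runs, for each $k$ up to `kMax` (default 10), five seeded
restarts of a greedy best-single-move reassignment. Restarts are
initialised from a hierarchical-clustering cut of the pairwise-distance
matrix, perturbed by randomly reassigning a quarter of the individuals;
uniformly random initial partitions are a known failure mode for greedy
single moves (any mixed pair of clusters collapses into one before
structure can form). Model selection is by maximum marginal likelihood
over all $k$ and restarts; all restart scores are reported rather than
averaged, since averaging partitions across different $k$ has no clear
meaning. Assignment probabilities are leave-one-out predictive
probabilities under each fitted cluster profile, renormalised per
individual.

## Neutrality tests

Tajima's $D = (M - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ uses the 1989
coefficients exactly; $S = 0$ yields a flagged undefined result, never a
silent 0. Fu's $F_s$ computes $S' = P(K \ge k_{obs} \mid \theta = M, n)$
under the Ewens sampling formula, with unsigned Stirling numbers of the
first kind built by the standard recurrence in log space (exact to
double precision for the sample sizes involved and validated against
integer arithmetic for $n \le 8$), and $F_s = \ln(S'/(1-S'))$, clamped
with a warning if $S'$ hits machine 0 or 1. For both tests
$\hat\theta = M$, matching the statistics' definitions, and p-values
come from neutral constant-size coalescent replicates conditioned on $n$
and $\hat\theta$ (default 10,000): two-tailed on $|D|$ for Tajima,
one-sided low tail for $F_s$.

## Mismatch distributions and the sudden-expansion model

For a population whose scaled size jumped from $\theta_0$ to $\theta_1$
at $\tau$ mutational units before present, integrating the pairwise
coalescence density through the size change gives the expected mismatch
probability

$$F(i) = F_{eq}(i,\theta_1)\,P\!\left[\mathrm{Pois}(a\tau) > i\right]
 + e^{-\tau/\theta_1} \sum_{j=0}^{i}
   \frac{e^{-\tau}\tau^j}{j!}\, F_{eq}(i-j,\theta_0),
 \qquad a = \tfrac{1+\theta_1}{\theta_1},$$

with $F_{eq}(i,\theta) = \theta^i/(1+\theta)^{i+1}$ the equilibrium
geometric spectrum; at $\tau = 0$ it reduces to $F_{eq}(\cdot,\theta_0)$
and for $\theta = 1$ to $2^{-(i+1)}$, the closed forms the tests pin to
machine precision. Tail mass beyond the largest observed class is
aggregated into it so observed and expected spectra are comparable
distributions.

Fitting minimises the plain sum of squared deviations over
$(\tau, \theta_0, \theta_1)$ by a deterministic coarse grid followed by
Nelder–Mead on log-transformed parameters, with box bounds
($\tau \le 2d$, $\theta \le \max(100, 10d)$ by default) enforced through
a penalty — unbounded $\theta_1$ excursions are both biologically
meaningless and numerically hazardous. Generalised least squares
weighting is not used; the weighting scheme of the classical software is
undocumented and plain SSD keeps the objective reproducible. If the
refinement cannot improve on the grid, the grid optimum is returned
flagged as non-converged.

Goodness of fit is a parametric bootstrap: coalescent samples of size
$n$ are simulated under the fitted expansion (infinite-sites mutations
at rate $\theta_1/2$, size change at $\tau/\theta_1$ coalescent units),
each replicate spectrum is refitted, and $p$ is the fraction of
replicates whose SSD (or Harpending raggedness
$r = \sum_{i} (x_i - x_{i-1})^2$ with $x_{d+1} := 0$, classes from 0)
meets or exceeds the observed value. The raggedness boundary convention
is stated because published sources differ; all worked examples use this
one.

## Substitution saturation

The saturation index is the mean per-site Shannon entropy of the
observed alignment divided by the Monte-Carlo mean entropy of fully
saturated alignments of the same dimensions — sites drawn i.i.d. from
the global base frequencies, i.e. a symmetric star topology at infinite
depth. The critical value `ISS.c` is the lower 5% quantile of the
saturated replicates' index, so "not saturated" is a one-sided test
against the full-saturation distribution. This is a re-derivation from
the definition, not a port of the classical program's tabulated
constants; its engine-specific values are not comparable. Because the
finite-sample entropy baseline depends mildly on $N$, the index is only
approximately invariant to duplicating every sequence.

## The coalescent simulator

The generator implements the backward-in-time structured coalescent:
per-deme coalescence at rate $\binom{k_d}{2}$, per-lineage migration by
a scaled rate matrix, an optional merge of all demes into one ancestral
population at `splitTime`, and an optional instantaneous expansion
(coalescent rate scaled by $\theta_1/\theta_0$ beyond
$\tau/\theta_1$). Mutations are Poisson with rate $\theta/2$ per lineage
per coalescent unit, scattered uniformly over $L$ sites through a
Kimura-type kernel (transition probability $\kappa/(\kappa+2)$), with
the root drawn from the configured base frequencies. Finite-sites
mutation is the default precisely so that multiple hits, Ts/Tv
saturation and network homoplasy are exercisable; an infinite-sites mode
provides clean oracles. Every public entry point takes an explicit seed
and regenerates bit-identically; datasets written to disk carry a JSON
manifest with the configuration, seed and FASTA checksum.

`twoRegionPreset()` emulates a five-population survey: sample sizes 15,
15, 22, 21, 24 at 710 sites, two regions (demes 1–3 and 4–5) with free
within-region migration (rate 500) and none between, and a strong
within-deme expansion ($\theta$: 2 → 2000 at $\tau = 14$ mutational
units). The expansion is essential to the realism of the preset: a
constant-size history at the same mean pairwise difference level leaves
roughly a quarter of the sequences as repeated haplotypes (the Ewens
expectation), whereas real control-region surveys — and this preset —
show nearly every individual carrying a unique haplotype at moderate
$M$. With the divergence frozen at 0.024 coalescent units of the
post-expansion size, pilot runs across seeds give median within-population
$M \approx 19$, realized Tv/Ts $\approx 0.16$ (with $\kappa = 30$; the
per-site pair counting inflates the event-level ratio $2/\kappa$ through
multiple hits), >95% unique haplotypes and a median AMOVA
$\Phi_{ST} \approx 0.5$ ranging over roughly 0.35–0.6 — the regime the
recovery tests target. What the preset does **not** emulate: recurrent
gene flow between regions, more than one locus, selection,
recombination, or sequencing error; passing recovery tests on it says
nothing about those complications.

## Problem sizes and defaults

Report defaults mirror standard practice: 10,000 permutations for
fixation-index tests, 1000 tree bootstrap replicates, 10,000 coalescent
replicates for neutrality p-values, clustering to $k \le 10$ with five
restarts. The test suite exercises the same code paths at smaller,
stated sizes chosen to keep the whole suite a matter of minutes: e.g.
calibration of the permutation and simulation tests uses 200 datasets
with 99–250 inner replicates (a nominal 5% level is then checked against
the wide binomial band 1–10%), expansion-time recovery uses 500
replicates at $n = 50$, and the goodness-of-fit uniformity check runs at
reduced meta-replication with a correspondingly loose bound. Permutation
p-values are reported as plain exceedance fractions; the Mantel test
includes the observed configuration in numerator and denominator.

## Known limitations

Single non-recombining locus throughout; no hierarchical (region-level)
AMOVA; no admixture or spatial priors in the clustering; the
sudden-expansion model is the only demographic alternative fitted (a
ragged, poorly fitting spectrum is evidence against it, not an estimate
of the true history); and the saturation index is a definition-faithful
entropy ratio, not a reimplementation of any particular program's
calibrated tables.
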