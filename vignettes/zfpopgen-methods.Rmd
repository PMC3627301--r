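---
title: "Models and methods behind zfpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind zfpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models the package implements,
the assumptions they rest on, the tunable parameters and their
defaults, and the design decisions taken where more than one reasonable
implementation existed. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

# The data model

A `GenotypeDataset` holds biallelic SNP genotypes coded as
alternate-allele counts (0/1/2, `NA` missing) for samples mapped to
populations and, optionally, populations mapped to groups — the two-level
structure (regional groups of local populations) that all hierarchical
analyses use. Positions are 1-based basepairs as in VCF; every window
and bin in the package is a half-open interval `[start, end)`, so a
position belongs to exactly one window. A `HaplotypeAlignment` holds an
aligned mitochondrial fragment (the default simulated length, 1122 bp,
matches a *cytb* amplicon) with a population label per sequence.

Missing genotypes are excluded locus-wise from every frequency
computation; nothing is imputed. The minor-allele-frequency filter
(`filterLoci()`, default 1%) is computed on the pooled sample across
all populations, because the filter's purpose is to remove globally
uninformative markers before any population comparison.

# Within-population statistics

Unbiased expected heterozygosity is Nei's gene diversity with the
small-sample factor, `2n/(2n-1) * (1 - p^2 - q^2)`. Population means
(H~S~) average over *all* retained loci, including monomorphic ones —
the averaging base matters when comparing absolute H~S~ between
datasets, so it is fixed here once.

The Hardy–Weinberg test is the exact conditional test: given the allele
counts, the heterozygote count follows Levene's distribution, and the
two-sided P sums the probabilities of all outcomes no more probable
than the observed one. Exact conditional tests are *valid but
conservative* on discrete data: on simulated Hardy–Weinberg data the
rejection rate at α is at or below α, never above. The test suite
asserts exactly this (super-uniformity), and checks the P-values against
an independent oracle that enumerates every placement of the minor
alleles into genotypes.

Mitochondrial statistics (S, h, π, D~a~) use complete deletion: any
column containing a gap or N in an included sequence is dropped. The
TN93 distance is the standard closed form with distinct purine and
pyrimidine transition rates; base frequencies are estimated from the
whole alignment (not per pair) so all pairwise distances share one
model. The invariant-sites extension some model-selection pipelines add
(+I) is deliberately not implemented: estimating the invariant fraction
is a model-fitting problem outside this package's scope, and the plain
TN93 correction is the comparable, reproducible choice. Saturated pairs
(a logarithm argument ≤ 0) raise an error rather than returning an
arbitrary large value.

The hierarchical AMOVA decomposes a matrix of squared distances into
among-group (σ~a~), among-population-within-group (σ~b~) and
within-population (σ~c~) components with the classical unequal-size
coefficients, and tests each Φ-statistic with its own permutation
scheme: sequences among populations within groups for Φ~SC~, whole
populations among groups for Φ~CT~, sequences across everything for
Φ~ST~. Groups containing a single population contribute no within-group
component (this is allowed, matching designs where several groups are
singletons). An all-zero distance matrix returns Φ = 0 with a
`degenerate` flag instead of 0/0. Permutation P-values throughout the
package use the add-one rule `(1 + #{perm >= obs}) / (1 + n_perm)`, so
no P-value is ever exactly zero.

# Differentiation

Weir–Cockerham θ is computed from the variance components a, b, c; the
multilocus estimate is the ratio of sums Σa/Σ(a+b+c) (the convention of
the estimator's standard implementations), with a percentile bootstrap
over loci for the 95% CI and individual-permutation P-values for
pairwise comparisons. Negative per-locus estimates are retained — they
are part of the estimator's sampling distribution and truncating them
would bias the multilocus combination.

Jost's D~est~ uses the Nei–Chesser corrections with the harmonic-mean
sample size; the overall value is the arithmetic mean of per-locus
values (the behaviour of the reference R implementation of this
estimator). The permutation test shuffles individuals among
populations; the CI bootstraps individuals within populations. Loci
with H~S~ = 1 are skipped. The test suite pins both estimators to
independent transcriptions: θ against the nested-ANOVA mean-squares
route, D~est~ against a direct spreadsheet-style evaluation.

# The hierarchical island-model null

The outlier test needs the neutral joint distribution of
(heterozygosity, F~ST~) under the observed hierarchical structure.
The package simulates it directly with a structured coalescent on a
hierarchical island model:

* demes nested in groups (defaults 20 groups × 100 demes);
* lineages co-located in a deme coalesce at rate k(k−1)/2 (time in
  units of 2N per deme);
* each lineage migrates to another deme of its own group at rate M1/2
  and to a deme of a different group at rate M2/2, destinations
  uniform (M are scaled rates, 2Nm);
* the genealogy runs to the MRCA and carries exactly one mutation,
  placed uniformly on total branch length. Conditioning on a single
  segregating site suits SNP data and removes the mutation rate as a
  nuisance parameter; every simulated locus is polymorphic in the
  genealogy by construction.

Sampled populations occupy one deme each; populations of the same
empirical group share a simulated group; gene-copy counts match the
per-locus average usable sample sizes (one layout per run — per-locus
missingness patterns are not re-simulated). Gene copies are paired at
random into diploids within demes, so Hardy–Weinberg structure and the
observed-heterozygosity term of θ are preserved.

A subtlety worth recording: with one mutation per genealogy, the
derived-allele count spectrum is E[L~i~/L~tot~], not the classical
(1/i)/H~n−1~ ratio of expectations — short genealogies overweight their
external branches, producing a small singleton excess. The engine test
therefore uses an independent pure-R coalescent with the same
one-mutation rule as its oracle, and checks the 1/i law only to first
order.

**Calibration.** `calibrateMigration()` holds M1/M2 fixed (default
ratio 10 — within-group exchange an order of magnitude stronger than
between groups, which produces realistic within-group F~ST~ of a few
percent when the overall target is ~0.17) and bisects on M2 in log
space until the multilocus θ of a 500-locus probe batch is within
`tol = 0.01` of the target. Probes reuse one derived seed (common
random numbers), making the objective monotone in M2 and the result
deterministic. The bracket expands upward from small M2 because the
event count of the structured coalescent grows linearly with the
migration rate: probing the near-panmictic regime first would dominate
the runtime for no information.

**Classification.** For each observed locus, tail P-values are the
fractions of the k simulated loci *nearest in heterozygosity* with
simulated θ at or beyond the observed value. k defaults to
`n_sims / 30` (capped at 1000, i.e. 1000 at the default 30,000
simulations): keeping the neighbourhood a fixed *fraction* of the table
matters because the null quantiles of θ vary with heterozygosity, and a
fixed absolute k on a smaller table smears heterozygosity strata enough
to visibly distort the tails. Loci with scaled heterozygosity
≤ `het_min = 0.2` are reported as `filtered`; scaling is
heterozygosity × (1 − θ) by default, which maps total onto within-deme
heterozygosity under the island model; division instead of
multiplication is available via `scaling = "divide"` since the
convention is not universal. Note an interaction users should know:
with the multiplicative scaling, strongly differentiated loci have low
scaled heterozygosity, so the 0.2 floor removes part of the high tail —
a conservative behaviour.

The false-positive calibration checks (tests and acceptance script) run
the classifier on datasets simulated from the same hierarchical model
and apply the pooled MAF ≥ 1% filter first, mirroring the analysis
pipeline: sub-MAF loci are singleton-type markers whose θ takes a few
discrete atoms, and tied atoms structurally suppress tail calls in any
FDIST-style rank test — that is precisely why low-information markers
are filtered before outlier analysis.

# Genome scans

**Outlier clustering.** The genome is tiled into 20 Mb bins per
chromosome from position 1, keeping the partial final bin; the packaged
Zv9-style chromosome-length table (synthetic — assembled so the 20 Mb
tiling yields the canonical 76 bins over 25 chromosomes, since the
original lengths and tiling rule are not published) is available via
`defaultChromLengths()`. The clustering probability is the Poisson
*point* probability P(X = k) with mean λ = outliers/bins: of the two
possible readings of the published rate (outliers per bin vs its
inverse) only this one reproduces all six printed probabilities, which
the test suite verifies by direct evaluation.

**Heterozygosity valleys.** Around each significant outlier a window
(default 10 Mb, clipped at chromosome ends) is scored by the mean
unbiased expected heterozygosity over its SNPs, excluding the focal
locus (the test concerns *linked* variation). With several populations
selected, the statistic is within-population H~e~ averaged across them —
the quantity a sweep depresses — rather than pooled-frequency
heterozygosity, which mixes in among-population variance and dilutes
the signal. The null is the distribution of the same statistic over
nonoverlapping windows tiled outside all outlier windows with at least
`min_snps = 6` polymorphic SNPs; the empirical lower-tail percentile
(add-one rule) is the P-value.

**LD.** r² for unphased diploids is estimated by EM over the
double-heterozygote ambiguity (convergence when the largest haplotype
frequency change is below 1e-8, at most 1000 iterations). The EM runs
from three starts — linkage equilibrium and both ends of the admissible
p~AB~ range — keeping the highest-likelihood solution, because the
equilibrium start is an exact fixed point for some tables (e.g. at
allele frequency ½) and single-start EM can return r² = 0 where the
maximum-likelihood estimate is large. Decay curves bin syntenic pairs
(default 5 Mb bins), fit ordinary least squares of bin means on
ln(distance in Mb), and derive the distance at which the fit crosses
r² = 0.2 (closed form, with an extrapolation warning outside the data
range). The half-length deliberately uses the empirical binned curve
with linear interpolation, not the logarithmic fit: a two-parameter log
curve fitted over tens of megabases cannot be trusted at the sub-bin
scale where the half-length of a steep decay lives.

# The synthetic-data generator

`simulateSnpDataset()` shares the coalescent engine with the null, so
simulated datasets are exactly the model the outlier test assumes. The
defaults are the study conditions the package emulates: 1,832 SNPs on
25 chromosomes of 40 Mb, ten wild populations (sample sizes 14–20
diploids) in five groups — three singleton groups, one group of five,
one of two — 2% missing genotypes, and migration calibrated to an
overall F~ST~ of 0.17. Loci are simulated independently: the neutral
engine has no intra-chromosome linkage. LD structure for testing the LD
machinery is created explicitly, by `plantSweeps()` (genotype copying
within a swept region) or `blockCopyLoci()` (noisy duplication of a
focal column with a distance-dependent flip probability, giving
controllable decay).

`plantSweeps()` implements a sweep's diversity valley on genotypes, not
allele frequencies, so Hardy–Weinberg structure remains testable: in
each population of the favored group, heterozygous genotypes at loci
within the radius are converted to the locally-majority homozygote.
`intensity` is defined as the proportional reduction of
within-population diversity at the sweep centre, decaying linearly to
zero at `radius` (default 3 Mb). Because a *fixed* conversion fraction
cannot produce a given diversity reduction when the minor allele is
common, the conversion count is solved per locus and population from
the quadratic relating H~e~ to the post-conversion minor frequency, and
capped when the heterozygotes are exhausted — the cap means realized
reductions fall short of nominal intensity at intermediate allele
frequencies. `differentiation_boost` additionally re-draws the focal
SNP so favored-group populations are near-fixed for the alternate
allele (binomial at 0.975 per allele copy) and all others for the
reference.

`simulateMtdna()` builds a root sequence at the requested base
composition (default 61% AT), diverges each clade along its own stem by
a Poisson number of substitutions with expectation
(net divergence × length)/2, and adds star-shaped within-clade
variation. Substitutions choose transition vs transversion at odds
`ts_tv_ratio : 1` (default 22). Multiple hits are allowed, so at ~5–6%
divergence with strong transition bias the realized pairwise distances
sit somewhat below the nominal divergence (reversals at repeatedly hit
sites); the acceptance script reports the realized value rather than
hiding this saturation.

## What the generator does not emulate

Real SNP panels of this kind are ascertained (discovered in a small
panel, often laboratory strains), which flattens the allele-frequency
spectrum toward common variants; the generator draws from the neutral
coalescent spectrum instead, so it contains many more low-frequency
loci than a genotyping-array dataset would. There is no recombination
model, no demographic history (bottlenecks, growth), and no
linked-selection model beyond the planted-sweep construction. Passing
tests on synthetic data therefore demonstrate the correctness and
calibration of the estimators under the stated model, not robustness to
ascertainment or demography.

# Problem sizes and a known limitation

The simulation-based checks run at deliberately chosen sizes: 5,000
null genealogies (instead of the 30,000 a full analysis would use),
2,000-locus replicate datasets, three seeds. These sizes give binomial
resolution of roughly ±0.3 percentage points on a 1% tail rate while
keeping a complete run in minutes.

One property deserves a frank statement. At the emulated marker density
(~1,800 SNPs over a ~1.3 Gb genome, i.e. ~12 SNPs per 6 Mb window), the
between-window variance of mean heterozygosity under the neutral
coalescent is large (the per-locus H~e~ distribution is wide), and the
percentile test for heterozygosity valleys consequently has modest
power: across the planted-sweep conditions used in the acceptance
checks (intensity 0.9, radius 3 Mb, scan window 6 Mb matched to the
sweep diameter), detection power is well below one-half even though the
false-flag rate is controlled. This is a property of the statistic at
this density, not of the implementation — increasing marker density or
sweep radius raises power, and the same variance bound explains why
sweep-window scans of real datasets at this density flag only a small
minority of outliers. The acceptance suite reports the measured power
honestly rather than weakening the check.
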