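---
title: "Methods: ROH, IBD and effective population size in insulaR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH, IBD and effective population size in insulaR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulaR)
```

`insulaR` analyses diploid genotype panels for the footprints of small,
closed mating networks: runs of homozygosity (ROH) within genomes,
identity-by-descent (IBD) sharing between genomes, and the effective
population size (Ne) implied by both. This vignette is the package's own
account of its models, parameter choices, numerical decisions and
limitations.

## Coordinates and data model

Physical positions are 1-based bp as in VCF; segment files use 0-based
half-open BED coordinates. All analysis happens in genetic distance:
a `genetic_map` stores per-chromosome anchors (bp, cM) and sites acquire cM
by linear interpolation between flanking anchors, clamping beyond the
terminal anchors. Genotypes are unphased alt-allele counts 0/1/2 with `NA`
for missing; missing calls never enter allele frequencies, LOD scores or
r². Binary genotype formats are deliberately unsupported — VCF (read via
vcfR) and a plain TSV matrix dialect cover the use cases.

Site-level filters mirror common practice for imputed panels: missingness
≤ 2%, MAF ≥ 5%, and optional LD pruning in 50-SNP windows stepped by 2.
Pruning drops the later member of any within-window pair with genotype
r² > 0.5. This is a deterministic r²-based stand-in for variance-inflation
pruning; the downstream statistics (window-based ROH calls, LOD sums,
kinship counts) are insensitive to the precise pruning rule, so we prefer
the reproducible variant and expose the threshold.

## ROH calling

The caller reproduces the PLINK sliding-window semantics with the familiar
parameter set (window of 50 SNPs, 0 heterozygotes and ≤ 5 missing calls per
homozygous window, 5% window hit fraction, ≥ 50 SNPs and ≥ 1 kb per
segment, 5000 kb gap split, ≤ 5000 kb/SNP density). Stated parameters are
frozen to that conventional string; window-level parameters the string
leaves unstated (`window_missing_max = 5`, `window_hit_fraction = 0.05`)
take the PLINK-documented defaults. The density test is
(segment bp length / n_snps) ≤ 5000 kb; gap splitting is applied before the
size and density tests. The implementation is vectorised over cumulative
sums but is required — by a property test over hundreds of randomized
instances — to agree *exactly* with a literal loop-based implementation of
the window semantics.

F_ROH divides the total cM in ROH above a length threshold by the total
genetic length of the analysed autosomes. Whether the denominator should be
genetic or physical length is a genuine ambiguity; we default to cM
(consistent with measuring segments in cM) and keep the physical route
available by supplying a bp-based denominator.

## Pedigree nulls and consanguinity classification

Six gene-dropping scenarios produce the focal offspring of: sibling and
parent–offspring unions (degree 1, E[F] = 1/4), uncle–niece and
grandparent–grandchild (degree 2, 1/8), first-cousin and great-avuncular
(degree 3, 1/16). Founders are drawn without replacement from a synthetic
founder panel — unrelated, unstructured haplotypes — and every transmission
is a Poisson-crossover meiosis. Each scenario is replicated 400 times; the
resulting cloud of (number of ROH, F_ROH) points is summarised by its mean
and covariance (diagonal regularised by 1e-9).

The published practice of judging a query genome "at the edge" of a
simulated cloud is made quantitative: Mahalanobis distance to each cloud
mean, converted to an empirical quantile among the cloud's own points,
with verdict *inside* below 0.90, *edge* in [0.90, 0.99], *outside* above.
Nearest-cloud ties break toward the lower degree. Length-restricted
re-analyses (only ROH > 5, > 10, > 15 cM) are parameterisations of the same
code path via `min_report_cM`, not separate implementations.

Two behaviours deserve note. First, cloud separation scales with map
length: on the full ~36-Morgan autosomal map an outbred genome is
unambiguously outside the first-degree clouds, while on a toy 9-Morgan
genome the clouds are wide enough that the same point may only reach the
"edge" verdict — the tests exercise both regimes. Second, in the pipeline a
genome is treated as consanguineous (and excluded from Ne fitting) not only
when inside/edge of a 1st/2nd-degree cloud but also when it lies *beyond*
such a cloud on the high-F_ROH side: genomes more extreme than a sib-mating
null inflate the long-ROH spectrum just as surely, and individuals with
both recent inbreeding and small-population background routinely land
there.

## Ne from the ROH length spectrum

The two chromosomes of an individual coalesce T generations back with
geometric probability P(T = t) = (1/2Ne)(1 − 1/2Ne)^(t−1). Conditional on
t, recombination breakpoints over the 2t connecting meioses form a Poisson
process of rate 2t per Morgan, so a chromosome of G Morgans is expected to
carry (2t)²(G − x)e^(−2tx) interior segments of length x plus
2·(2t)e^(−2tx) chromosome-edge segments; chromosomes shorter than x
contribute nothing. Summing over chromosomes and t gives the expected
density λ(x) per genome, fitted to pooled segment counts in 1000 bins on
[0.04, 0.5] Morgans (segments restricted to 4–20 cM) by a Poisson composite
likelihood, maximised over log Ne by bounded 1-D optimisation (tolerance
1e-4). The time sum truncates at t_max = 2000, where the geometric tail
mass is below 1e-6 across the whole search range [10, 1e6]; a fit landing
on a search bound is flagged explicitly.

The 95% CI is the profile-likelihood interval at a log-likelihood drop of
1.92 (χ²₁/2) — adopted and documented here as the package's construction,
validated by simulation: over model-simulated replicates the interval
covers the truth ~95% of the time, and a parametric-bootstrap generator
(`simulate_roh_spectrum()`) is provided for exactly that check. The density
formula itself is verified against an independent Monte-Carlo oracle that
draws T, drops breakpoints and tallies segment lengths.

Two caveats are inherent to the model, not bugs. The composite likelihood
treats segments as independent, so the CI is approximate (slightly
anti-conservative) at small genome counts. And when the true history is a
bounded number of generations (as in a forward simulation started from
unrelated founders), coalescences older than the simulated span are
missing, which thins the shortest bins and biases the fit mildly upward;
end-to-end recovery on 40-generation Wright–Fisher panels at N = 500 stays
within a factor 1.5 of truth.

The harmonic-mean summariser (`harmonic_mean_ne`, generations 5–30 by
default) condenses an externally supplied trajectory; trajectory
*inference* from IBD is out of scope, though the ≥ 90-within-group-segment
input-eligibility rule is implemented (`ne_eligibility`).

## IBD detection and geography

Single-site evidence is a log₁₀ likelihood ratio of IBD1 (the pair shares
one allele; each adds an independent population allele) against
independent Hardy–Weinberg genotypes, both models perturbed by a per-allele
miscall rate ε = 0.005. Sites are scanned per chromosome with a
prefix-sum/maximal-subsegment recursion: report disjoint maximal-scoring
intervals with total LOD ≥ 3, keep those ≥ 2 cM (shorter IBD calls on
unphased common-SNP data are unreliable and conventionally excluded), and
take the outermost contributing SNPs as endpoints. Sites are treated as
independent given IBD state — no LD model — which is adequate after MAF
filtering on imputed common SNPs and is the documented limitation of this
detector. The implementation is an independent realisation of the
LOD-scan contract; its acceptance standard is planted-segment recovery on
synthetic truth (recall ≥ 90% at ≥ 4 cM, FDR ≤ 5% under ε = 0.005), not
byte-equality with any particular tool.

Relatedness filtering uses the KING-robust estimator
φ̂ = (N_hethet − 2·N_opphom)/(N_het(i) + N_het(j)) over pairwise-complete
sites. "Closer than 4th degree" is implemented as φ̂ > 0.0442, the
conventional midpoint between 3rd- and 4th-degree expectations; the greedy
resolver removes the missing-heavier member of the worst pair first.

Group summaries average the *per-pair total* shared cM within and between
groups with ≥ 2 members. (The alternative reading — mean per-segment
length — is a genuine ambiguity; per-pair totals are consistent with
building the total-IBD matrix and are what the PCA consumes.) The PCA
treats rows of the symmetric total-sharing matrix as feature vectors,
mean-centres columns and takes the SVD; variance fractions are reported
per component.

## The synthetic-data generator

Founder haplotypes have allele frequencies drawn from a Beta distribution
truncated to [0.05, 0.95] (uniform by default), emulating a MAF-filtered
common-SNP panel, with alleles independent across sites and haplotypes.
There is no mutation model — over tens of generations at common SNPs new
mutations are negligible — and no crossover interference (pure Poisson on
the cM axis). Demography is Wright–Fisher with monogamy-free random mating:
two distinct parents per offspring (selfing excluded), per-deme sizes from
a trajectory, and symmetric migration as the probability that an
offspring's parents come from another deme.

Haplotypes are represented as founder-ancestry mosaics on a concatenated
cM axis, so meioses cost O(segments) rather than O(sites) and alleles are
materialised only when a genotype matrix is needed. The mosaics double as
exact ground truth: true ROH/IBD segments are maximal intervals where two
mosaics carry the same founder, and the realised inbreeding coefficient of
any simulated individual is directly measurable. Invariants tested include
tiling of every chromosome, Poisson crossover moments, and convergence of
realised F to the analytic pedigree expectations.

What the generator does *not* emulate — and hence what green tests do not
certify about real data: linkage disequilibrium among founders, allele
frequency drift shared across demes, imputation artefacts correlated along
the genome, reference bias, and non-equilibrium frequency spectra. Error
injection is an independent per-allele miscall (rate ≤ 0.05) plus
independent dropout, which is a deliberately simple surrogate for
imputation noise.

## Default problem sizes

Defaults are chosen so a desk-scale run is statistically meaningful: the
default synthetic genome is 6 chromosomes × 150 cM (9 Morgans) at 10–25
SNPs/cM, and the full 22-autosome ~36-Morgan map (`human_autosomes()`, an
approximate uniform-rate stand-in for an empirical refined map) is used
wherever absolute F_ROH calibration matters — pedigree nulls use 400
replicates per scenario at 25 SNPs/cM. Validation simulations use 10–50
genomes per replicate and 10–200 replicates per check, sizes at which the
targeted 3-standard-error and coverage bands are informative. The bundled
demo (two demes, island N = 60 against mainland N = 300, migration 0.01,
one planted sib-mating offspring) completes in about a minute.

## Degenerate inputs and tie-breaking

Fatal errors: unreadable or empty panels, unsorted sites, chromosomes
missing from the map, zero F_ROH denominator, all sites removed by
filtering, identical ids passed to the IBD detector, constant matrices
passed to PCA. Warnings with graceful results: all-missing individuals
(empty ROH call), insufficient pair overlap for kinship (pair skipped),
zero usable segments for the Ne fit (estimate pinned at the upper search
bound with a boundary flag). Deterministic tie-breaks: nearest-cloud ties
toward lower degree, relatedness removal toward the missing-heavier then
later-ordered individual, LD pruning toward keeping the earlier site.
All simulation entry points take explicit seeds; the pipeline derives
per-stage child seeds by stable string hashing so stages can be re-run in
isolation and full runs are bit-reproducible.
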