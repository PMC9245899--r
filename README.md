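# insulaR

Runs of homozygosity, identity by descent, and the genetic signature of
population insularity.

`insulaR` is an R package for population geneticists working with imputed
diploid genotype panels — typically ancient-DNA datasets of a few hundred
individuals at common biallelic SNPs. It asks the questions that matter for
small, isolated populations: *were this individual's parents close
relatives?* *How small was the breeding population?* *Which communities
exchanged mates, and which were cut off?*

## What it computes

**ROH and F_ROH.** A sliding-window caller for runs of homozygosity in the
PLINK style (windows of 50 SNPs, zero heterozygotes allowed, 5% window hit
fraction, gap/density filters), with segment lengths in centiMorgans and the
inbreeding estimator

> F_ROH = (total cM in ROH above a length threshold) / (total autosomal cM).

**Consanguinity classification.** Gene-dropping simulation of six pedigree
scenarios — sibling and parent–offspring unions (expected offspring
F = 1/4), avuncular and grandparent–grandchild (1/8), first-cousin and
great-avuncular (1/16) — each replicated 400 times over random founders to
build null clouds in the (number of ROH, F_ROH) plane. Query genomes are
placed by Mahalanobis distance with an empirical-quantile verdict
(inside / edge / outside).

**Effective population size from the ROH spectrum.** A maximum-likelihood
fit of constant Ne to the 4–20 cM ROH length spectrum. Coalescence times are
geometric, P(T = t) = (1/2Ne)(1 − 1/2Ne)^(t−1); conditional on t,
breakpoints accumulate as a Poisson process of rate 2t per Morgan, giving an
expected segment density per genome

> λ(x) = Σ_c Σ_t P(T = t) · [(2t)² (G_c − x) + 2·(2t)] · e^(−2tx),

maximised by a Poisson composite likelihood over 1000 bins on
[0.04, 0.5] Morgans, with a 1.92-unit profile-likelihood 95% CI. A harmonic
mean summariser condenses population-size trajectories over generations
5–30.

**IBD geography.** Error-tolerant single-site LOD scores (IBD1 versus
Hardy–Weinberg, per-allele miscall rate 0.005) scanned for maximal-scoring
segments (total LOD ≥ 3, length ≥ 2 cM); KING-robust kinship filtering
(φ̂ > 0.0442 removes 3rd-degree or closer); within/between-group mean
sharing; PCA of the pairwise total-IBD matrix; and the ≥90-segment
eligibility rule for trajectory-based Ne estimation.

**Synthetic panels with ground truth.** A Wright–Fisher forward simulator
with Poisson-crossover meiosis on an arbitrary genetic map. Haplotypes are
founder-ancestry mosaics, so every simulated panel carries exact true ROH
and IBD segments — the oracle against which the detectors are validated.

## Worked example

```r
library(insulaR)

map <- uniform_map(rep(150, 6))                  # 6 chromosomes x 150 cM
founders <- make_founders(1000, 150 * 25, map, seed = 1)
pop <- simulate_population(founders, ne_trajectory(rep(500L, 41)),
                           map, seed = 2, n_sample = 10)

prof <- roh_profile(pop$genotypes, roh_params(min_report_cM = 4))
fit <- fit_ne_roh(prof$segments_by_id, roh_ne_model(rep(150, 6)))
fit
#> ROH-spectrum Ne estimate: 410 (95% CI 294-594)
#>   33 segments in [4, 20] cM from 10 genome(s)
```

Ten sampled genomes from a population simulated at constant N = 500 for 40
generations yield 33 ROH segments in the 4–20 cM window, and the spectrum
fit recovers an effective size of 410 with a 95% interval that comfortably
covers the truth — the point estimate is noisy at this sample size, which is
exactly what the width of the interval says.

The bundled demo pipeline runs the whole analysis (filtering, ROH,
pedigree nulls, classification, per-deme Ne, relatedness filtering, IBD
matrix, group summary, PCA) on a two-deme island/mainland scenario with one
planted sib-mating offspring:

```r
res <- run_pipeline(default_demo_config(out_dir = "demo", seed = 7))
res$classification[res$classification$id == "PLANTED", c("nearest", "consanguineous")]
#>             nearest consanguineous
#> 33 first_degree_sib           TRUE
```

A thin command-line wrapper lives at `inst/cli/insular.R`
(`Rscript insular.R demo` or `run --config run.yaml`).

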