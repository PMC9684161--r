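# SGBkit

Dereplicating thousands of metagenome-assembled genomes (MAGs) and
reference genomes into **species-level genome bins (SGBs)** is the core
bookkeeping step of large microbiome catalog studies: every genome cluster
at ≥ 95% average nucleotide identity (ANI) with ≥ 30% aligned overlap is
one "species", and samples are then profiled against the cluster
representatives. SGBkit implements this construction — and the abundance
profiling built on top of it — as a tested, self-contained R package for
microbiome researchers who want the clustering machinery without a
cluster-scale pipeline.

## The method

The catalog is built by a two-step clustering:

1. **MinHash pre-clustering.** Every genome is reduced to a bottom-*s*
   sketch of its canonical *k*-mers (*k* = 21, *s* = 10,000). The Mash
   distance between two genomes is estimated from the sketch Jaccard
   *j* as *D* = −(1/*k*)·ln(2*j* / (1 + *j*)), which under a Poisson
   substitution model estimates the per-site divergence. Average-linkage
   hierarchical clustering on the all-versus-all distance matrix, cut at
   *D* ≤ 0.05, yields fast pre-clusters.
2. **Fragment-ANI refinement.** Mash underestimates the similarity of
   incomplete genomes, so same-species MAGs can be split across
   pre-clusters. Each pre-cluster selects a representative — the largest
   genome if the cluster contains a reference genome (kSGB), otherwise
   the MAG minimizing the sum of five competition ranks (completeness ↓,
   contamination ↑, mean depth ↓, strain heterogeneity ↑, N50 ↓) — and
   representative pairs within Mash distance 0.10 are re-compared with
   fragment-based ANI (ANIb-style: 1020-bp query fragments, best local
   placement, 70%-length / 30%-identity acceptance). Pairs whose
   min-direction aligned coverage exceeds 0.3 enter complete-linkage
   clustering on 100 − ANI; clusters merging strictly below 5 (ANI > 95%)
   are unioned into final SGBs.

MAGs are gated beforehand by the MIMAG tiers (medium: completeness > 50%
and contamination < 10%; high: > 90% and < 5%; strict inequalities), with
tRNA isotype (≥ 18 of 20 amino acids) and rRNA (5S + 16S + 23S) audits
reported alongside. Profiling converts normalized per-contig depths to
SGB relative abundances via the length-weighted mean depth of each
representative genome, with richness counted above 0.1% relative
abundance and Bray-Curtis dissimilarity for between-sample comparison.

A synthetic-community generator with planted truth (known strain
divergences, controlled MAG degradation, known mixture weights) makes
every stage verifiable end to end.

## Worked example

```r
library(SGBkit)

com <- simulateCommunity(nSpecies = 5, genomeLength = 5e4, seed = 42)
com$genomes
#> GenomeSet with 15 genomes, 15 contigs
#>   total length: 750000 bp; 1 reference genome(s)

res <- buildCatalog(com$genomes)
res$catalog
#> SGBCatalog with 5 SGBs ( 1 kSGB / 4 uSGB ), 15 genomes, 5 oral
as.data.frame(res$catalog)[, 1:5]
#>    sgb_id kind oral representative_id n_members
#> 1 SGB0001 kSGB TRUE           sp01_g1         5
#> 2 SGB0002 uSGB TRUE           sp02_g2         3
#> 3 SGB0003 uSGB TRUE           sp03_g3         3
#> 4 SGB0004 uSGB TRUE           sp04_g2         2
#> 5 SGB0005 uSGB TRUE           sp05_g2         2

## profile a sample with known mixture weights
reps <- com$genomes[unname(representativeIds(res$catalog))]
w <- c(sp01 = 0.4, sp02 = 0.25, sp03 = 0.2, sp04 = 0.1, sp05 = 0.05)
sim <- simulateDepths(reps, w, depthScale = 30, noiseCv = 0, seed = 7)
cids <- unique(sim$depths$contig_id)
prof <- profileSamples(sim$depths, res$catalog,
                       setNames(sub("\\|.*", "", cids), cids))
round(prof, 4)
#>    SGB0001 SGB0002 SGB0003 SGB0004 SGB0005
#> s1     0.4    0.25     0.2     0.1    0.05
richness(prof[1, ], 0.001)
#> [1] 5
```

The 15 genomes (five planted species, 2–5 strains each at known pairwise
divergence) are clustered into exactly the five planted species — the
Adjusted Rand Index against the planted labels is 1 — and the noise-free
depth table returns the planted mixture weights exactly.

A command-line wrapper over the same functions is available at
`inst/scripts/sgbforge.R` (`simulate` and `run` subcommands).

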