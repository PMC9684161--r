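---
title: "Constructing species-level genome bins: methods and design notes"
author: "SGBkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing species-level genome bins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SGBkit)
```

## The problem

Large metagenomic studies assemble tens of thousands of draft genomes
(MAGs) that must be collapsed into species-level units before any
ecology or association analysis is possible. The operational species
definition is genomic: two genomes belong to the same species-level
genome bin (SGB) when their average nucleotide identity (ANI) exceeds
95% over at least 30% of the aligned genome. Computing fragment ANI for
every genome pair is quadratic and far too slow, hence the two-step
strategy implemented here: a cheap MinHash/Mash distance prunes the
pair space, and the expensive fragment ANI is recomputed only where it
can change the outcome.

## Step 1: MinHash pre-clustering

Each genome is reduced to the `s` smallest distinct hash values over its
canonical k-mers (`sketchGenome()`; canonical = lexicographic minimum of
a k-mer and its reverse complement, which requires odd `k`). For two
sketches the Jaccard similarity `j` is estimated on the bottom
`min(s, |union|)` values of the merged hash union, and converted to the
Mash distance

$$D = -\frac{1}{k}\,\ln\frac{2j}{1+j},$$

with the conventions `D = 1` at `j = 0` and clamping to [0, 1]. Under a
model in which point substitutions hit k-mers as a Poisson process, `D`
estimates the per-site divergence between the genomes: on simulated
strain pairs at substitution rates 0.01–0.05 the estimate lands within
±0.01 of the planted rate (this is asserted by the test suite).

Average-linkage (UPGMA) hierarchical clustering of the all-versus-all
distance matrix is cut at height 0.05 to give pre-clusters
(`precluster()`). Cut semantics: a cluster is a maximal set whose merge
heights are all ≤ the cutoff, so a pair at exactly 0.05 merges; the cut
happens strictly above the cutoff. Average/complete-linkage heights are
monotone, so the cut is implemented as a union–find over the merge
sequence, stopping at the threshold (with a 1e-12 float guard).

Two numerical choices worth stating:

* **Hash width.** Hashes are the top 53 bits of a splitmix64-mixed
  2-bit-packed canonical k-mer under a fixed seed. 53 bits is what an R
  double represents exactly; collisions among the ~10^5 k-mers of a
  genome are vanishingly rare and the analysis depends only on distance
  structure, not on hash identity with any external tool.
* **Ambiguity handling.** Non-ACGT characters break the k-mer window:
  k-mers spanning them are skipped, so an `N` behaves like a contig
  boundary.

## Step 2: fragment-ANI refinement

Mash systematically *under*-estimates the similarity of incomplete
genomes — a 60%-complete MAG shares at most 60% of its parent's k-mers,
which inflates `D` by roughly `ln((1+c)/2c)/k` for completeness `c` —
so step 1 can split a species whose members include fragmentary MAGs.
Step 2 repairs this.

Each pre-cluster selects a representative (`selectRepresentative()`):

* **kSGB** (contains a reference genome): the member with the largest
  genome, ties broken lexicographically by id. All members compete, not
  only the references; a config flag could restrict this, but the larger
  pool is the natural reading and changes nothing when references are
  the longest genomes.
* **uSGB** (MAGs only): members are ranked by completeness (descending),
  contamination (ascending), coverage (descending), strain heterogeneity
  (ascending) and N50 (descending); the member minimizing the rank sum
  wins. *Competition ranking* is used (equal values share the smallest
  rank) and rank-sum ties again break lexicographically, making the
  choice deterministic. "Coverage" here is the mean sequencing depth of
  the MAG from the binning depth file — the ranking happens before any
  ANI exists in the workflow, so it cannot mean aligned coverage.

Representative pairs within Mash distance 0.10 (`refinementPairs()`)
are re-evaluated with fragment ANI (`anib()`): the query is cut into
1020-bp windows (terminal remainders ≥ 100 bp kept), each fragment is
placed against the subject on either strand, and placements aligning at
least 70% of the fragment at ≥ 30% identity are accepted. ANI is the
mean identity of accepted fragments; coverage is their summed aligned
length over the query length. Both directions are computed; the pair
ANI is their arithmetic mean and the pair coverage the *minimum* of the
two directions — the conservative reading of the 30%-overlap rule,
which makes the coverage of a parent/partial-MAG pair track the MAG's
completeness. The candidate cutoff of 0.10 comfortably covers the
region where merging is possible: a pair mergeable at ANI > 95 has true
divergence < 0.05, and even with the incompleteness inflation above at
coverage 0.3 the Mash distance stays below ~0.11.

The aligner is an exact-seed (13-mer, every 25 bp, both strands) search
with ungapped extension over the fragment window, clipped at contig
boundaries. The synthetic data are substitution-only by construction, so
ungapped extension realises the local-alignment contract exactly and
keeps the whole pipeline deterministic and dependency-free; real indel
divergence would bias identities slightly downward (see Limitations).
The seed design keeps the miss probability negligible at the divergences
that matter: at 10% divergence a fragment carries ~41 seeds each clean
with probability 0.9^13 ≈ 0.25, so the chance that no seed survives is
~8×10⁻⁶, while two unrelated sequences pass the 30%-identity filter
essentially never (random DNA aligns at ~25%).

Accepted pairs (coverage strictly > 0.3) then go through
complete-linkage clustering on `100 − ANI`, cut *strictly* below
`100 − 95` because the species rule is ANI strictly greater than 95;
pairs at exactly 95% ANI stay separate. Pre-clusters whose
representatives co-cluster are unioned whole (`mergeByAni()`), and
representatives are re-selected on the merged membership
(`assembleCatalog()`), using the kSGB rule if any member is a reference.
SGB ids are assigned in sorted order of representative id, so catalog
labels are stable across runs. Re-running the merge on its own output
changes nothing (idempotence, covered by a test).

## Quality gating and audits

MAGs must meet the MIMAG medium-quality standard (completeness > 50%
and contamination < 10%, strict inequalities) to enter clustering;
high quality is > 90% and < 5%. Boundary values resolve downward — a
(90, 5) genome is medium, a (50, 10) genome fails. Reference genomes
bypass the gate: the gate models MAG quality control, and curated
references carry no CheckM metrics. The tRNA audit (≥ 18 of the 20
standard amino-acid isotypes decoded) and rRNA audit (5S, 16S and 23S
all present) are computed and reported as flags, not used as filters:
whether they gate catalog membership is left to the analyst, so the
package records them without deciding.

## Profiling

`genomeDepth()` collapses a per-contig depth table (depths are assumed
already normalized upstream, jgi-style) to the length-weighted mean
depth per genome; `relativeAbundance()` assigns each SGB the depth of
its representative genome and normalizes to sum to 1. An all-zero
sample yields an all-zero profile flagged `flagged_empty` rather than a
division by zero. Richness counts SGBs strictly above 0.1% relative
abundance; `unknownFraction()` reports the uSGB share of that richness
and the summed uSGB abundance; `brayCurtis()` implements
`sum(|p−q|)/sum(p+q)` over the key union (it agrees with
`vegan::vegdist` to machine precision in the tests, which use vegan as
an independent cross-check only). Profiles are invariant to uniform
rescaling of a sample's depths, so the depth scale never matters.

## The synthetic community

`simulateCommunity()` is the package's ground-truth instrument, not a
fixture: it plants exactly the structure the clustering must recover.

* **Species** are i.i.d. base sequences (default 20 species × 100 kb,
  GC drawn in [0.35, 0.60]) — unrelated by construction, so
  inter-species distances sit at the Mash ceiling.
* **Strains**: each species draws one divergence `r` from
  {0.005, 0.01, 0.02, 0.03} and mutates each of its 2–6 strains from
  the hidden ancestor at rate `r/2`, substitution-only. Pairwise strain
  ANI is therefore ~`100·(1−r)`, spanning 97–99.5% — all safely inside
  the 95% species boundary while exercising it from above. (Mutating
  strains directly at the listed rates would put two 0.03-strains at
  ~94% pairwise ANI, *across* the boundary, which is exactly the
  confound the halved rates avoid.) The expected intra-species ANI,
  including the 1/3 chance that two independent substitutions coincide,
  is recorded as planted truth.
* **MAG degradation** (`degradeToMag()`) keeps uniformly placed,
  non-overlapping segments totalling the requested completeness, each
  at least 1500 bp (the binning convention), and injects whole foreign
  contigs for contamination; realized completeness/contamination are
  recorded as truth. Requesting completeness below one minimum contig
  is an error, not silent truncation.
* **Depths** (`simulateDepths()`): every contig of species *i* gets
  depth `depthScale · w_i · ε` with `ε` gamma-distributed, mean 1,
  coefficient of variation `noiseCv` (exactly 1 at `noiseCv = 0`), so
  planted weights are recovered exactly in the noise-free case and the
  gamma form keeps depths positive under noise.

What the generator deliberately does **not** model: indels and
rearrangements, repeat structure, chimeric contigs, read-level error,
GC-dependent coverage bias, and horizontal transfer. Passing tests
therefore demonstrate that the clustering and profiling mathematics are
implemented correctly under the stated species model — not that the
pipeline is robust to every artifact of real assemblies; with real data
the Mash and ANI stages inherit whatever biases the upstream assembler
and binner introduce.

All generator and pipeline operations are deterministic given a seed
(each derives sub-seeds from its own seed argument and restores the
caller's RNG state), which is what makes byte-identical pipeline reruns
testable.

## Problem sizes and runtime choices

The test and acceptance runs use 100-kb genomes for anything that
measures calibration (Mash vs substitution rate, ANI vs divergence,
boundary pairs at 96%/93% ANI, the 60%-complete rescue scenario) and
30–50-kb genomes with 3–6 species for structural checks (round-trips,
pipeline determinism, profiling). At these sizes the statistical
tolerances are comfortable — the bottom-10,000 sketch of a 100-kb
genome estimates Jaccard with a standard error of ~0.005 — and the full
suite runs in well under a minute of compute. The rescue scenario uses
4 retained contigs so that fragment clipping at contig ends (each
boundary truncates the windows that straddle it below the 70%-length
acceptance) costs only a few percent of coverage; with many small
contigs that clipping loss is real and expected, and the tests assert
coverage ≈ completeness with a tolerance that reflects it.

## Known limitations

* The ungapped seed-and-extend aligner understates identity in the
  presence of indels; swapping in a gapped aligner behind
  `alignFragment()`'s contract would change nothing else.
* SGB abundance uses the representative genome's contigs only, mirroring
  profiling against a representative index; member-level aggregation is
  out of scope.
* The catalog carries no taxonomy; kSGB/uSGB and the oral flag are the
  only annotations.
* All-versus-all sketch comparison is quadratic in genome count; it is
  instantaneous at hundreds of genomes but would need blocking or an
  index at the scale of full catalog studies.
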