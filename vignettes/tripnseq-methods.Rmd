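---
title: "Mapping transcription-replication interactions: models and methods"
author: "tripnseq maintainers"
date: "`r Sys.Date()`"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping transcription-replication interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(tripnseq)
  library(GenomicRanges)
})
```

## The problem

Replication forks and transcribing RNA polymerase II share the same DNA
template, and their encounters — transcription–replication interactions
(TRIs) — are a source of replication stress, DNA breaks and mutation.
TRIPn-Seq maps them directly: chromatin is immunoprecipitated first for
RNA polymerase II phosphorylated at serine 5 (RNAP2s5, marking initiated
polymerase), then for BrdU incorporated into nascent DNA during a short
pulse. A locus enriched in the BrdU+ library over the BrdU− control, at
an FDR of at most 0.05, is a TRI: a place where transcription and
replication machinery demonstrably co-occupied the same fragments.

`tripnseq` implements the downstream computational analysis as a tested R
package: TRI discovery from replicate fragment libraries, and the battery
of statistics used to characterize the called loci (replication fork
directionality, replication timing, GC skew and content, G-quadruplex
propensity, transcription orientation classes, metagene profiles,
randomization-based overlap statistics, and region-level variant
enrichment). A deterministic synthetic-data generator plants ground-truth
loci so that every stage can be validated end to end without any external
download.

## TRI discovery

Discovery combines three ingredients, mirroring the assay's published
analysis chain while keeping every algorithm fully specified inside the
package.

**Candidate peaks.** Pooled BrdU+ fragments are scanned at 50 bp
resolution against a local Poisson rate estimated from the pooled BrdU−
background: `lambda_local = max(lambda_genome, lambda_5kb, lambda_10kb)`,
scaled to the experimental library size. Per-bin p-values are BH-corrected,
significant bins within 200 bp are merged, and peaks shorter than 150 bp
are dropped. This is deliberately a self-contained local-lambda caller
rather than a wrapper around an external peak caller: acceptance is
truth recovery on planted loci, not numeric identity with any specific
tool.

**Replicate-aware differential test.** For each window the pooled
experimental count $k$ out of the window total $t$ is tested one-sided
against the library-size null proportion $p_0 = L_E / (L_E + L_C)$, with
$X \sim \mathrm{BetaBin}(t, p_0, \rho)$ and
$p = P(X \ge k)$, reducing exactly to the binomial when $\rho \le 10^{-8}$.
The common overdispersion $\rho$ is estimated once per run by method of
moments from the replicate-level within-condition variation across all
windows with $t \ge 10$ — the same negative-binomial model family used by
standard differential-binding tools, but fully specified and
dependency-light. The test is one-sided because a TRI is by definition
*more* signal in BrdU+ than control. Library normalization is by total
fragment count; genome-wide IP libraries with a matched protocol do not
warrant trimmed-mean normalization, a documented limitation for strongly
composition-biased designs.

**TSS sliding-window scan.** Around every annotated TSS, 1 kb windows
slide across TSS ± 1 kb in 100 bp steps, giving 11 offset sets. Each
offset set is counted, tested and BH-corrected *independently* (per-set
FDR); overlapping windows across nearby TSSs within a set are merged
before counting so no fragment is tested twice within a set. A pooled-FDR
mode across sets exists behind a flag for sensitivity analysis. The window
length defaults to 1000 bp and is configurable (800 bp is a documented
alternative used in parts of the original analysis).

**Combine and merge.** All peaks and scan windows at FDR ≤ 0.05 are
unioned and merged (gap 0; bookended intervals merge by default, a config
knob since only-overlapping merging is an equally defensible reading).
Each merged locus keeps the *highest* member FDR — the conservative
choice — plus full provenance. Genes are associated when their TSS lies
within ±1.5 kb of the locus center; control TSSs (cTSSs) are active TSSs
(pooled fragments above a configurable occupancy floor, default any
fragment) not associated with any TRI.

## Characterization statistics

* **RFD** (replication fork directionality): $(R - F)/(R + F)$ per 1 kb
  bin of strand-split Okazaki-fragment counts; +1 is purely rightward
  forks. Bins with zero coverage are *missing*, never 0 — zero is a
  meaningful balanced-fork value and must not be conflated with no data.
* **TimEX**: per-bin $\log_2((S + c)/(G_0 + c))$ between S-phase and
  resting coverage (bin 100 bp), smoothed by a centered running mean over
  500 bp; pseudocount $c = 0.1$ RPM guards empty bins. Higher = earlier
  replication.
* **GC skew**: $(G - C)/(G + C)$ in 200 bp windows sliding by 1 bp, the
  value assigned to the window center (floor-centering for even windows).
  Windows without G or C are missing.
* **G4 propensity**: run-length base scoring (a G in a maximal run of
  $L$ Gs scores $+\min(L, 4)$, C-runs score negatively, A/T/N zero),
  averaged over 25 nt windows; positions with |score| ≥ 1.4 inside 400 bp
  regions are hits, and overlapping qualifying windows merge into maximal
  hits (raw-window counting is available behind a flag since merged
  versus raw counting is not uniquely determined by the tool flags the
  method cites).
* **Orientation classes**: a TRI TSS is a *divergent pair* when an
  opposite-strand annotated TSS sits within 3 kb on its upstream side and
  both TSSs intersect strand-matched transcription signal; *convergent*
  when downstream; *single bidirectional* when no annotated neighbor is
  within 3 kb but signal intersects both strands; otherwise
  *unclassified*. Upstream/downstream are relative to the focal TSS's own
  strand, distances are TSS-to-TSS, and divergent takes precedence when
  both qualify (all qualifying labels are kept as evidence). "Intersects
  signal" means ≥1 bp overlap of the TSS ± 500 bp window with a
  strand-matched peak; 500 bp mirrors the TSS-region convention used for
  variant windows.
* **Resampling inference**: empirical $P = (r + 1)/(n + 1)$ with ties
  counted as extreme (so $P > 0$ always); fold enrichment is
  observed / mean(null) with a median alternative behind a flag, since
  the fold definition is not uniquely pinned down by convention.
  Gene-list nulls draw |query| genes from the universe without
  replacement, 999 times by default. The workspace overlap test flattens
  the workspace, clips query and annotations to it, and re-places each
  query segment (original length, unsplit, uniformly over all positions
  where it fits) 999 times; placed segments may overlap one another — a
  simplification traded for exactness, acceptable because the analytic
  null mean is verified within 3 SE in the tests.
* **Profiles**: point-anchored or scaled-gene-body matrices with
  median ± SE aggregation per bin; blacklisted regions are excluded
  whole (per-bin masking applies inside tracks); region groups are
  compared by mapping the median track value onto sub-windows, averaging
  across the region, and applying the rank-sum test (exact enumeration of
  labelings up to a combined n of 16 — valid under ties — and a
  tie-corrected, continuity-corrected normal approximation above).
  Strand-flipping defaults off for point anchors and on for body
  profiles, both configurable, since the flip convention is a genuinely
  open plotting choice.
* **Variants**: alleles classify as SBS / insertion / deletion / other;
  multi-allelic records are split per alternate allele and duplicate
  (chrom, pos, ref, alt) records deduplicate by default (a
  keep-duplicates mode mirrors the alternative reading of merged call
  sets). Regions merge before counting so shared variants count once;
  gene mode splits regions into 1 kb windows to normalize for length.
  Enrichment resamples |query| control regions 999 times.

## The synthetic experiment

The generator's defaults define the study conditions every acceptance
check runs under: a 4 × 5 Mb genome carrying 2000 genes — 150 TRI-class,
1350 control-TSS-class, 500 inactive, one gene per 10 kb slot —
3 + 3 replicates of exactly 10^6 fragments each, fragment lengths uniform
in 200–500 bp, and a 4-fold BrdU+ enrichment planted at TRI loci
(TSS ± 600 bp). The 150/1350 split mirrors the roughly 1:10 TRI:cTSS
ratio of the assay at a tenth of the gene count; the enrichment fold is
an artifact choice (the assay itself reports no fold) and is swept in
tests. Promoter occupancy is a single central kernel at control genes and
two flanking kernels at TRI genes, echoing the bimodal polymerase pattern
at TRIs. Negative-binomial noise enters as a per-bin, per-replicate gamma
random effect (dispersion 0.05, the standard count-model assumption when
no dispersion estimate is available) before exactly the configured number
of fragments is drawn multinomially — so library sizes are exact and
enrichment at TRIs slightly depresses all other BrdU+ windows, the same
composition effect depth-normalized real libraries show.

Deliberate simplifications, and what they mean for the tests: gene bodies
are clipped to their 10 kb slot so gene-level region classes are disjoint
(real annotations overlap); TSS jitter is bounded so inter-slot TSSs stay
more than 3 kb apart, making orientation classes unambiguous (real
genomes contain boundary cases the classifier reports as evidence rather
than resolving); the fork model assigns each position to its nearest
fired origin, so termination zones appear as a sharp RFD step at the
inter-origin midpoint rather than the broad gradient stochastic fork
progression produces; and no read-level sequence, sequencing error or
duplicate simulation is attempted. Passing tests therefore demonstrate
correctness of the algorithms under the stated model, not robustness to
every artifact of real libraries.

Sequence generation plants GC-rich promoters at TRI genes (GC 0.65, a
positive downstream GC skew of about 0.29, a (GGG TTA)×3 tract and a
(GGC)×6 tract downstream of the TSS), moderate-GC control promoters
(0.55) and background composition (0.42) elsewhere — enough structure for
the GC/G4 statistics to separate the classes the way the real assay's
loci separate from controls.

## Numerical choices and degenerate inputs

Windows clipped below full length at chromosome edges are dropped, not
truncated, so window sets stay length-matched. Empty windows test as
$p = 1$ with zero log-fold-change and a flag. The beta-binomial tail is
summed on the shorter side of the distribution for accuracy and cost. BH
correction is the standard step-up (verified against its brute-force
definition in the tests). All randomized procedures take explicit integer
seeds and use R's Mersenne-Twister; identical config and seed give
byte-identical outputs. Simulation problem sizes in the test-suite
(fixtures of 2 × 1.5 Mb with 130 genes; the full default 20 Mb
configuration for the recovery and calibration checks) were chosen as the
smallest sizes at which the planted effects are unambiguous.

## Known limitations

The package analyzes fragment interval files, not raw reads — trimming,
alignment and deduplication are upstream. bigWig I/O is out of scope
(bedGraph serves as the track format). The differential test uses one
common overdispersion rather than per-window shrinkage; with few
replicates and matched libraries this is a reasonable trade, but strongly
heteroscedastic data would warrant a per-window dispersion model.
Mutational-signature decomposition, motif discovery and gene-set
enrichment against web services are intentionally out of scope.

## A minimal session

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 1)
gen <- generateGenome(cfg, withSequence = FALSE)
frags <- simulateTripnFragments(cfg, gen$genome, gen$genes, gen$truth)
res <- runDiscovery(frags, gen$genes, gen$genome)
res$triLoci
```
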