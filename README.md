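# tripnseq

Discovery and characterization of transcription–replication interaction
(TRI) loci from TRIPn-Seq fragment data.

TRIPn-Seq maps where transcription and replication machinery co-occupy
chromatin: sequential immunoprecipitation of RNA polymerase II
phosphorylated at serine 5 (RNAP2s5), then of BrdU-labeled nascent DNA,
followed by sequencing. A TRI is a locus whose BrdU+ libraries carry
significantly more fragments than matched BrdU− controls at FDR ≤ 0.05.
This package is for genomicists analyzing such data (or any paired
enrichment/control fragment design anchored at TSSs): it implements the
full discovery chain and the statistics used to characterize the loci,
with a deterministic synthetic-data generator that plants ground truth so
every stage is testable end to end.

## The model at the core

For each candidate window, let $k$ be the pooled BrdU+ fragment count,
$t = k + m$ the window total over both conditions, and
$p_0 = L_E/(L_E + L_C)$ the null proportion from the library totals. The
one-sided enrichment p-value is

$$p = P(X \ge k), \qquad X \sim \mathrm{BetaBin}(t,\ p_0,\ \rho),$$

with a single overdispersion $\rho$ estimated by method of moments from
replicate-level within-condition variation (exactly binomial when
$\rho \to 0$). Windows come from two sources: a Poisson local-lambda
candidate peak scan (50 bp bins, $\lambda_{\text{local}} =
\max(\lambda_{\text{genome}}, \lambda_{5\text{kb}},
\lambda_{10\text{kb}})$ from the control), and a sliding TSS scan (1 kb
windows across TSS ± 1 kb in 100 bp steps, each of the 11 offset sets
BH-corrected independently). Everything at FDR ≤ 0.05 is merged; each
locus keeps the highest member FDR; genes associate within ±1.5 kb of
locus centers.

Characterization statistics: replication fork directionality
$\mathrm{RFD} = (R - F)/(R + F)$ from Okazaki strand counts; TimEX
replication-timing $\log_2$ ratios (bin 100 bp, smooth 500 bp); GC skew
$(G - C)/(G + C)$ in 200 bp sliding windows; G4Hunter run-length
propensity scores (window 25, threshold 1.4); transcription orientation
classes (divergent / convergent / single-bidirectional within a 3 kb
radius); metagene profile matrices with median ± SE aggregation;
empirical resampling $P = (r+1)/(n+1)$ with 999 draws; hypergeometric and
rank-sum tests; and per-class variant enrichment against resampled
control regions.

## Worked example

A small synthetic experiment, end to end:

```r
library(tripnseq)

cfg <- simulationConfig(seed = 7, nChrom = 2, chromLength = 1500000,
                        nTri = 15, nCtss = 70, nInactive = 25,
                        fragmentsPerReplicate = 200000)
gen   <- generateGenome(cfg)
frags <- simulateTripnFragments(cfg, gen$genome, gen$genes, gen$truth)
res   <- runDiscovery(frags, gen$genes, gen$genome)
res$triLoci
```

```
GRanges object with 3 ranges and 4 metadata columns:   # head shown
      seqnames        ranges strand |         fdr  nMembers  provenance              genes
  [1]     chr1 174462-176912      * | 6.87041e-06        12  denovo,tss_k00,...  gene0007,gene0007p
  [2]     chr1 273716-276162      * | 3.41691e-03        13  denovo,tss_k00,...  gene0010,gene0010p
  [3]     chr1 313106-315105      * | 1.18970e-13        12  denovo,tss_k00,...  gene0012
```

All 15 planted loci are recovered (15 called, 15 overlap truth). Each
locus records its worst member FDR, how many peak/scan windows merged
into it, which offset sets contributed, and the genes whose TSSs lie
within ±1.5 kb of its center. Characterization against the derived cTSS
control set:

```r
tx  <- simulateStrandTranscription(gen$genome, gen$genes)
tab <- runCharacterization(res$triLoci, res$ctss, gen$genes, gen$genome,
                           transcription = tx, nIter = 99, seed = 1)
tab$sequenceMetrics
#       metric       tri      ctss            p
# 1 gc_content 0.6190625 0.5155789 4.618665e-08
tab$g4
#    group regions hits  meanDensity fracWithHit
# 1 tritss      24   34 0.0035416667   0.7083333
# 2   ctss      95   25 0.0006578947   0.2421053
```

TRI promoters are significantly more GC-rich than controls (rank-sum
p ≈ 5e-8) and carry predicted G4 structures at a far higher rate — the
planted sequence features, recovered by the package's own metrics.

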