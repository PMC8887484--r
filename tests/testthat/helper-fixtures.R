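# Shared synthetic fixture built once per test run: a small two-chromosome
# experiment with all four orientation classes represented.

.fixtureEnv <- new.env()

smallFixture <- function() {
  if (!is.null(.fixtureEnv$gen)) return(as.list(.fixtureEnv))
  cfg <- simulationConfig(
    seed = 42L, nChrom = 2L, chromLength = 1500000L,
    nTri = 20L, nCtss = 80L, nInactive = 30L,
    fragmentsPerReplicate = 200000L,
    orientationProps = c(divergent_pair = 0.25, convergent_pair = 0.25,
                         single_bidirectional = 0.25, unclassified = 0.25))
  gen <- generateGenome(cfg)
  frags <- simulateTripnFragments(cfg, gen$genome, gen$genes, gen$truth)
  tx <- simulateStrandTranscription(gen$genome, gen$genes)
  .fixtureEnv$cfg <- cfg
  .fixtureEnv$gen <- gen
  .fixtureEnv$frags <- frags
  .fixtureEnv$tx <- tx
  as.list(.fixtureEnv)
}

# width-1 stranded TSS points of an annotation
tssPoints <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
  GRanges(seqnames(genes), IRanges(pos, pos), strand = strand(genes),
          geneId = mcols(genes)$geneId)
}

# pooled-count activity floor separating promoter occupancy from background:
# three times the genome-uniform expectation for the window
uniformFloor <- function(fragmentSets, genome, windowBp = 2000L) {
  total <- sum(vapply(fragmentSets, librarySize, integer(1)))
  gsize <- sum(as.double(seqlengths(genome)))
  3 * total * (windowBp + 350) / gsize
}
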