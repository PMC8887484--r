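#' End-to-end TRI discovery
#'
#' Runs the full discovery chain: candidate peak calling on pooled BrdU+
#' versus pooled BrdU- fragments, per-sample counting and the one-sided
#' beta-binomial differential test with BH FDR on the candidate peak set,
#' the sliding-window TSS scan (each offset set tested and corrected
#' independently), the combine/merge rule keeping the highest member FDR,
#' gene association within +/- geneFlank of locus centers, and derivation
#' of the control-TSS set.
#'
#' @param fragmentSets list of \code{\linkS4class{FragmentSet}}s covering
#'   both conditions.
#' @param genes gene annotation \code{GRanges} with \code{geneId}.
#' @param genome \code{GenomeModel}.
#' @param fdrThreshold locus FDR cutoff (default 0.05).
#' @param windowLength,flank,step TSS-scan geometry (defaults 1000/1000/100
#'   bp).
#' @param geneFlank gene association radius (default 1500 bp).
#' @param activityFloor pooled-count floor defining active TSSs for the
#'   cTSS set (default 0: any fragment).
#' @param mode fragment counting mode.
#' @param pooledFdr pool BH across TSS-scan sets (sensitivity mode).
#' @return list with \code{triLoci} (gene-annotated \code{GRanges}),
#'   \code{ctss}, \code{peaks} (tested candidate peaks), \code{scan}
#'   (tested TSS windows), \code{rho}, and \code{params}.
#' @export
runDiscovery <- function(fragmentSets, genes, genome,
                         fdrThreshold = 0.05,
                         windowLength = 1000L, flank = 1000L, step = 100L,
                         geneFlank = 1500L, activityFloor = 0,
                         mode = "overlap", pooledFdr = FALSE) {
  conds <- vapply(fragmentSets, condition, character(1))
  expSets <- fragmentSets[conds == "BrdU+"]
  ctlSets <- fragmentSets[conds == "BrdU-"]
  if (!length(expSets) || !length(ctlSets)) {
    stop("fragmentSets must include both BrdU+ and BrdU- samples")
  }
  peaks <- callCandidatePeaks(expSets, ctlSets, genome)
  peakWin <- GRanges()
  if (length(peaks)) {
    counts <- countFragments(fragmentSets, peaks, mode = mode)
    dt <- differentialWindowTest(counts)
    peakWin <- peaks
    mcols(peakWin)$setId <- "denovo"
    mcols(peakWin)$log2FC <- dt$log2FC
    mcols(peakWin)$p <- dt$p
    mcols(peakWin)$fdr <- bhFdr(dt$p)
  }
  tssPos <- anchorPositions(genes)
  tss <- GRanges(seqnames(genes), IRanges(tssPos, tssPos), strand = strand(genes),
                 geneId = mcols(genes)$geneId)
  scan <- tssWindowScan(fragmentSets, tss, genome, windowLength = windowLength,
                        flank = flank, step = step, mode = mode,
                        pooledFdr = pooledFdr)
  triLoci <- combineAndMerge(peakWin, scan, fdrThreshold = fdrThreshold)
  triLoci <- assignGenes(triLoci, genes, flank = geneFlank)
  ctss <- ctssSet(genes, fragmentSets, triLoci, windowHalf = flank,
                  activityFloor = activityFloor, flank = geneFlank)
  list(triLoci = triLoci, ctss = ctss, peaks = peakWin, scan = scan,
       rho = attr(scan, "rho"),
       params = list(fdrThreshold = fdrThreshold, windowLength = windowLength,
                     flank = flank, step = step, geneFlank = geneFlank,
                     activityFloor = activityFloor, mode = mode,
                     pooledFdr = pooledFdr))
}

#' TRI-associated TSS positions (TRITSSs)
#'
#' The TSS-anchored representation of TRI loci: annotated TSSs lying within
#' the association flank of a locus center, used for like-for-like
#' comparison with cTSSs.
#'
#' @param triLoci gene-annotated loci from \code{\link{runDiscovery}}.
#' @param genes gene annotation \code{GRanges}.
#' @return stranded width-1 \code{GRanges} with \code{geneId}.
#' @export
tritssSet <- function(triLoci, genes) {
  ids <- unique(unlist(strsplit(mcols(triLoci)$genes, ",", fixed = TRUE)))
  ids <- ids[nzchar(ids)]
  g <- genes[mcols(genes)$geneId %in% ids]
  pos <- anchorPositions(g)
  GRanges(seqnames(g), IRanges(pos, pos), strand = strand(g),
          geneId = mcols(g)$geneId)
}

gcContentOfRegions <- function(genome, regions) {
  seqs <- genomeSequence(genome, regions)
  freq <- letterFrequency(seqs, c("G", "C", "A", "T"))
  (freq[, "G"] + freq[, "C"]) / pmax(1, rowSums(freq))
}

#' Characterize called loci
#'
#' Produces the figure-level characterization tables for a set of TRI loci
#' against the cTSS control set: TSS-overlap summary, orientation class
#' table, GC content / GC skew / G4 comparisons (when the genome carries
#' sequence), RFD and replication-timing metagene aggregates (when tracks
#' are supplied), and per-class variant enrichment (when variants are
#' supplied). Missing optional inputs skip their analysis; the rest
#' proceed.
#'
#' @param triLoci gene-annotated loci from \code{\link{runDiscovery}}.
#' @param ctss control TSS set.
#' @param genes gene annotation \code{GRanges}.
#' @param genome \code{GenomeModel}.
#' @param transcription optional list with \code{plusPeaks},
#'   \code{minusPeaks}.
#' @param rfdTrack optional RFD \code{\linkS4class{BinnedTrack}}.
#' @param timexTrack optional replication-timing \code{BinnedTrack}.
#' @param variants optional variant \code{data.frame}.
#' @param nIter resampling iterations for variant enrichment.
#' @param seed RNG seed for resampling and control subsampling.
#' @return named list of data.frames (entries NULL when skipped):
#'   \code{tssOverlap}, \code{orientation}, \code{sequenceMetrics},
#'   \code{g4}, \code{rfdProfile}, \code{timexProfile},
#'   \code{variantEnrichment}.
#' @export
runCharacterization <- function(triLoci, ctss, genes, genome,
                                transcription = NULL, rfdTrack = NULL,
                                timexTrack = NULL, variants = NULL,
                                nIter = 999L, seed = 1L) {
  out <- list()
  tritss <- tritssSet(triLoci, genes)
  tssAll <- GRanges(seqnames(genes),
                    IRanges(anchorPositions(genes), anchorPositions(genes)),
                    strand = strand(genes), geneId = mcols(genes)$geneId)
  ov <- tssOverlapSummary(triLoci, tssAll)
  out$tssOverlap <- data.frame(overlapping = ov$overlapping, total = ov$total,
                               fraction = ov$fraction)

  if (!is.null(transcription)) {
    oc <- classifyOrientation(tritss, tssAll, transcription$plusPeaks,
                              transcription$minusPeaks)
    tab <- table(factor(oc$class, levels = c("divergent_pair", "convergent_pair",
                                             "single_bidirectional", "unclassified")))
    out$orientation <- data.frame(class = names(tab), n = as.integer(tab))
    out$orientationCalls <- oc
  }

  if (hasSequence(genome) && length(tritss) && length(ctss)) {
    half <- 200L
    reg <- function(gr) GRanges(seqnames(gr),
      IRanges(pmax(1L, start(gr) - half), start(gr) + half - 1L), strand = strand(gr))
    gcTri <- gcContentOfRegions(genome, reg(tritss))
    gcC <- gcContentOfRegions(genome, reg(ctss))
    rs <- ranksumTest(gcTri, gcC)
    out$sequenceMetrics <- data.frame(
      metric = "gc_content",
      tri = mean(gcTri), ctss = mean(gcC), p = rs$p)

    g4reg <- function(gr) GRanges(seqnames(gr),
      IRanges(pmax(1L, start(gr) - 200L), start(gr) + 199L))
    g4t <- findG4(g4reg(tritss), genome)
    g4c <- findG4(g4reg(ctss), genome)
    out$g4 <- data.frame(
      group = c("tritss", "ctss"),
      regions = c(length(tritss), length(ctss)),
      hits = c(sum(g4t$summary$nHits), sum(g4c$summary$nHits)),
      meanDensity = c(mean(g4t$summary$density), mean(g4c$summary$density)),
      fracWithHit = c(mean(g4t$summary$nHits > 0), mean(g4c$summary$nHits > 0)))
  }

  profileFor <- function(track, lbl) {
    ctssUse <- if (length(ctss) > length(tritss))
      matchSample(ctss, length(tritss), seed = seed) else ctss
    pmT <- buildProfileMatrix(tritss, track, flankUp = 10000L, flankDown = 10000L,
                              bin = 1000L, genome = genome)
    pmC <- buildProfileMatrix(ctssUse, track, flankUp = 10000L, flankDown = 10000L,
                              bin = 1000L, genome = genome)
    rbind(cbind(group = "tritss", aggregateProfile(pmT)),
          cbind(group = "ctss", aggregateProfile(pmC)))
  }
  if (!is.null(rfdTrack) && length(tritss) && length(ctss)) {
    out$rfdProfile <- profileFor(rfdTrack, "rfd")
  }
  if (!is.null(timexTrack) && length(tritss) && length(ctss)) {
    out$timexProfile <- profileFor(timexTrack, "timex")
  }

  if (!is.null(variants) && length(tritss) && length(ctss)) {
    half <- 500L
    win <- function(gr) GRanges(seqnames(gr),
      IRanges(pmax(1L, start(gr) - half), start(gr) + half - 1L))
    if (length(ctss) >= length(tritss)) {
      ve <- variantEnrichment(win(tritss), win(ctss), variants,
                              nIter = nIter, seed = seed)
      out$variantEnrichment <- data.frame(
        class = names(ve),
        observed = vapply(ve, observedStat, numeric(1)),
        nullMean = vapply(ve, function(x) mean(nullDraws(x)), numeric(1)),
        fold = vapply(ve, foldEnrichment, numeric(1)),
        p = vapply(ve, pValue, numeric(1)))
    }
  }
  out
}
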