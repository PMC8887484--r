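#' Construct a SimulationConfig
#'
#' Defaults define the desk-scale study conditions: a 4 x 5 Mb genome with
#' 2000 genes (150 TRI-class, 1350 control-TSS-class, 500 inactive,
#' mirroring the assay's roughly 1:10 TRI:cTSS ratio at one tenth the gene
#' count), 3 + 3 replicates of 1e6 fragments each with fragment lengths
#' uniform in 200-500 bp, negative-binomial dispersion 0.05, and a 4-fold
#' BrdU+ enrichment planted at TRI loci.
#'
#' @param seed integer seed; every generator output is deterministic given
#'   the config including this seed.
#' @param nChrom,chromLength genome shape.
#' @param nTri,nCtss,nInactive gene class counts.
#' @param enrichmentFold planted BrdU+ / BrdU- ratio at TRIs (>= 1).
#' @param nRepExp,nRepCtl replicates per condition.
#' @param fragmentsPerReplicate library size of every replicate.
#' @param fragLenRange fragment length range (bp).
#' @param dispersion negative-binomial dispersion of per-bin counts.
#' @param orientationProps proportions of TRI genes per orientation class.
#' @param originsPerChrom,originEfficiency replication origin model.
#' @param variantRates per-kb Poisson rates (sbs, insertion, deletion) in
#'   control regions and background.
#' @param deletionFoldTri deletion-rate multiplier in TRI gene bodies.
#' @return A \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(seed = 1L,
                             nChrom = 4L, chromLength = 5000000L,
                             nTri = 150L, nCtss = 1350L, nInactive = 500L,
                             enrichmentFold = 4,
                             nRepExp = 3L, nRepCtl = 3L,
                             fragmentsPerReplicate = 1000000L,
                             fragLenRange = c(200L, 500L),
                             dispersion = 0.05,
                             orientationProps = c(divergent_pair = 0.4,
                                                  convergent_pair = 0.2,
                                                  single_bidirectional = 0.3,
                                                  unclassified = 0.1),
                             originsPerChrom = 3L,
                             originEfficiency = 0.8,
                             variantRates = c(sbs = 1, insertion = 0.2, deletion = 0.2),
                             deletionFoldTri = 2) {
  new("SimulationConfig", seed = as.integer(seed),
      nChrom = as.integer(nChrom), chromLength = as.integer(chromLength),
      nTri = as.integer(nTri), nCtss = as.integer(nCtss),
      nInactive = as.integer(nInactive),
      enrichmentFold = as.numeric(enrichmentFold),
      nRepExp = as.integer(nRepExp), nRepCtl = as.integer(nRepCtl),
      fragmentsPerReplicate = as.integer(fragmentsPerReplicate),
      fragLenRange = as.integer(fragLenRange),
      dispersion = as.numeric(dispersion),
      orientationProps = orientationProps[c("divergent_pair", "convergent_pair",
                                            "single_bidirectional", "unclassified")],
      originsPerChrom = as.integer(originsPerChrom),
      originEfficiency = as.numeric(originEfficiency),
      variantRates = variantRates,
      deletionFoldTri = as.numeric(deletionFoldTri))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %d x %s bp genome, %d TRI / %d cTSS / %d inactive genes\n",
              object@nChrom, format(object@chromLength, big.mark = ","),
              object@nTri, object@nCtss, object@nInactive))
  cat(sprintf("  %d+%d replicates x %s fragments, fold %.3g, dispersion %.3g, seed %d\n",
              object@nRepExp, object@nRepCtl,
              format(object@fragmentsPerReplicate, big.mark = ","),
              object@enrichmentFold, object@dispersion, object@seed))
})

# fixed layout constants of the generator
.slotSize <- 10000L      # one gene slot per 10 kb keeps inter-slot TSSs > 3 kb apart
.triHalfWidth <- 600L    # planted TRI locus = TSS +/- 600 bp
.promoterHalf <- 500L    # promoter patch / signal window half-width

#' Generate the synthetic genome, gene annotation and planted truth
#'
#' Genes are laid out one per 10 kb slot with the TSS jittered about the
#' slot center, guaranteeing at least 7 kb between TSSs of different slots
#' so orientation classes are unambiguous. TRI genes of the divergent/
#' convergent classes receive an annotated opposite-strand partner gene
#' 600-1200 bp away. When sequence is generated, TRI promoters are GC-rich
#' with positive GC skew downstream of the TSS and planted G-run tracts
#' ((GGC)n and G>=3 runs); control promoters get moderate GC; everything
#' else is background composition.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param withSequence generate genome sequence (needed only for the
#'   sequence-based metrics).
#' @return list with \code{genome} (\code{GenomeModel}), \code{genes}
#'   (\code{GRanges} with \code{geneId}, \code{class}, \code{orientation},
#'   \code{partnerOf}), and \code{truth} (list: \code{triLoci} with planted
#'   fold and orientation, \code{triGenes}, \code{origins},
#'   \code{triGeneBodies}, \code{controlGeneBodies}).
#' @export
generateGenome <- function(config, withSequence = TRUE) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(config@seed, generateGenomeImpl(config, withSequence))
}

generateGenomeImpl <- function(config, withSequence) {
  chroms <- paste0("chr", seq_len(config@nChrom))
  sl <- setNames(rep(config@chromLength, config@nChrom), chroms)
  nGenes <- config@nTri + config@nCtss + config@nInactive
  slotsPerChrom <- config@chromLength %/% .slotSize
  totalSlots <- slotsPerChrom * config@nChrom
  slotIdx <- sort(sample.int(totalSlots, nGenes))
  slotChrom <- chroms[(slotIdx - 1L) %/% slotsPerChrom + 1L]
  slotStart <- ((slotIdx - 1L) %% slotsPerChrom) * .slotSize + 1L

  classes <- sample(rep(c("tri", "ctss", "inactive"),
                        c(config@nTri, config@nCtss, config@nInactive)))
  orient <- rep(NA_character_, nGenes)
  nPerClass <- round(config@orientationProps * config@nTri)
  # rounding drift goes to the largest class
  nPerClass[which.max(nPerClass)] <- nPerClass[which.max(nPerClass)] +
    config@nTri - sum(nPerClass)
  orient[classes == "tri"] <- sample(rep(names(nPerClass), nPerClass))

  tss <- slotStart + .slotSize %/% 2L + as.integer(floor(runif(nGenes, -1000, 1000)))
  geneStrand <- sample(c("+", "-"), nGenes, replace = TRUE)
  geneLen <- pmin(30000L, pmax(2000L, as.integer(round(
    exp(log(8000) + rnorm(nGenes, 0, 0.5))))))

  # gene bodies are clipped to their slot so gene-level region classes stay
  # disjoint (no two genes share bases)
  geneStart <- ifelse(geneStrand == "+", tss, tss - geneLen + 1L)
  geneEnd <- ifelse(geneStrand == "+", tss + geneLen - 1L, tss)
  geneStart <- pmax(slotStart, geneStart)
  geneEnd <- pmin(slotStart + .slotSize - 1L, pmin(sl[slotChrom], geneEnd))

  genes <- GRanges(slotChrom, IRanges(geneStart, geneEnd), strand = geneStrand,
                   geneId = sprintf("gene%04d", seq_len(nGenes)),
                   class = classes, orientation = orient,
                   partnerOf = NA_character_)

  # annotated opposite-strand partners for divergent / convergent TRI genes
  needPartner <- which(classes == "tri" & orient %in% c("divergent_pair", "convergent_pair"))
  if (length(needPartner)) {
    d <- as.integer(floor(runif(length(needPartner), 600, 1201)))
    focalTss <- tss[needPartner]
    focalNeg <- geneStrand[needPartner] == "-"
    up <- orient[needPartner] == "divergent_pair"
    # divergent: partner on the focal upstream side; convergent: downstream
    sign <- ifelse(xor(up, focalNeg), -1L, 1L)   # + focal upstream = left
    pTss <- focalTss + sign * d
    pStrand <- ifelse(focalNeg, "+", "-")
    pLen <- pmin(30000L, pmax(2000L, as.integer(round(
      exp(log(8000) + rnorm(length(needPartner), 0, 0.5))))))
    pStart <- ifelse(pStrand == "+", pTss, pTss - pLen + 1L)
    pEnd <- ifelse(pStrand == "+", pTss + pLen - 1L, pTss)
    pStart <- pmax(slotStart[needPartner], pStart)
    pEnd <- pmin(slotStart[needPartner] + .slotSize - 1L,
                 pmin(sl[slotChrom[needPartner]], pEnd))
    partners <- GRanges(slotChrom[needPartner], IRanges(pStart, pEnd),
                        strand = pStrand,
                        geneId = sprintf("gene%04dp", needPartner),
                        class = "partner", orientation = NA_character_,
                        partnerOf = mcols(genes)$geneId[needPartner])
    genes <- c(genes, partners)
  }

  triIdx <- which(classes == "tri")
  triLoci <- GRanges(slotChrom[triIdx],
                     IRanges(pmax(1L, tss[triIdx] - .triHalfWidth),
                             pmin(sl[slotChrom[triIdx]], tss[triIdx] + .triHalfWidth - 1L)),
                     geneId = mcols(genes)$geneId[triIdx],
                     fold = config@enrichmentFold,
                     orientation = orient[triIdx],
                     center = tss[triIdx])

  # genes whose TSS lies within +/- 1.5 kb of a planted locus center
  allTss <- anchorPositions(genes)
  triGenes <- unique(unlist(lapply(seq_along(triLoci), function(i) {
    sameChrom <- as.character(seqnames(genes)) == as.character(seqnames(triLoci)[i])
    mcols(genes)$geneId[sameChrom & abs(allTss - mcols(triLoci)$center[i]) <= 1500L]
  })))

  origins <- do.call(rbind, lapply(chroms, function(chr) {
    pos <- as.integer(round(seq(config@chromLength * 0.15, config@chromLength * 0.85,
                                length.out = config@originsPerChrom)))
    data.frame(chrom = chr, pos = pos, efficiency = config@originEfficiency)
  }))

  sequences <- if (withSequence) syntheticSequences(config, sl, genes) else NULL
  genome <- GenomeModel(sl, sequences = sequences)

  truth <- list(
    triLoci = triLoci,
    triGenes = triGenes,
    origins = origins,
    triGeneBodies = genes[mcols(genes)$class == "tri"],
    controlGeneBodies = genes[mcols(genes)$class == "ctss"]
  )
  list(genome = genome, genes = genes, truth = truth)
}

# base composition probabilities, A/C/G/T order
.bgProbs <- c(0.29, 0.21, 0.21, 0.29)          # GC 0.42
.ctssProbs <- c(0.225, 0.275, 0.275, 0.225)    # GC 0.55, no skew
.triUpProbs <- c(0.175, 0.325, 0.325, 0.175)   # GC 0.65, no skew
.triDownProbs <- c(0.175, 0.23, 0.42, 0.175)   # GC 0.65, skew (G-C)/(G+C) = 0.29

syntheticSequences <- function(config, sl, genes) {
  bases <- c("A", "C", "G", "T")
  seqs <- lapply(names(sl), function(chr) {
    sample(bases, sl[[chr]], replace = TRUE, prob = .bgProbs)
  })
  names(seqs) <- names(sl)
  tssAll <- anchorPositions(genes)
  g3tract <- strsplit("GGGTTAGGGTTAGGGTTAGGG", "")[[1]]
  ggcTract <- strsplit(paste(rep("GGC", 6L), collapse = ""), "")[[1]]
  for (i in seq_along(genes)) {
    cls <- mcols(genes)$class[i]
    if (cls == "inactive") next
    chr <- as.character(seqnames(genes)[i])
    p <- tssAll[i]
    neg <- as.character(strand(genes)[i]) == "-"
    n <- .promoterHalf
    if (cls == "tri") {
      upstream <- sample(bases, n, replace = TRUE, prob = .triUpProbs)
      downstream <- sample(bases, n, replace = TRUE, prob = .triDownProbs)
      downstream[51:71] <- g3tract
      downstream[151:168] <- ggcTract
      patch <- c(upstream, downstream)   # in transcription orientation
    } else {
      patch <- sample(bases, 2L * n, replace = TRUE, prob = .ctssProbs)
    }
    if (neg) patch <- rev(chartr("ACGT", "TGCA", patch))
    lo <- p - n; hi <- p + n - 1L
    if (lo < 1L || hi > sl[[chr]]) next
    seqs[[chr]][lo:hi] <- patch
  }
  DNAStringSet(setNames(vapply(seqs, paste, character(1), collapse = ""), names(sl)))
}

# per-bin RNAP2s5 occupancy weights (100 bp bins): background 1 everywhere,
# promoter kernels at active genes (single central peak for cTSS-like genes,
# two flanking peaks for TRI-class genes, echoing the bimodal pattern)
occupancyWeights <- function(config, genome, genes, binSize = 100L,
                             promoterWeight = 600) {
  sl <- seqlengths(genome)
  w <- lapply(names(sl), function(chr) rep(1, ceiling(sl[[chr]] / binSize)))
  names(w) <- names(sl)
  # kernels over bin offsets -6..6 relative to the TSS bin
  central <- c(0, 0, 0.5, 1, 2, 3, 4, 3, 2, 1, 0.5, 0, 0)
  bimodal <- c(0.5, 1, 2.5, 3, 2.5, 1, 0.5, 1, 2.5, 3, 2.5, 1, 0.5)
  central <- central / sum(central) * promoterWeight
  bimodal <- bimodal / sum(bimodal) * promoterWeight
  tssAll <- anchorPositions(genes)
  cls <- mcols(genes)$class
  for (i in seq_along(genes)) {
    if (cls[i] == "inactive") next
    chr <- as.character(seqnames(genes)[i])
    kern <- if (cls[i] == "tri") bimodal else central
    centerBin <- (tssAll[i] - 1L) %/% binSize + 1L
    idx <- centerBin + (-6:6)
    ok <- idx >= 1L & idx <= length(w[[chr]])
    w[[chr]][idx[ok]] <- w[[chr]][idx[ok]] + kern[ok]
  }
  w
}

#' Simulate replicate TRIPn-Seq fragment libraries
#'
#' Per-bin expected fragment counts follow the RNAP2s5 occupancy profile
#' (background plus promoter kernels); in BrdU+ replicates the expectation
#' at planted TRI loci is multiplied by the enrichment fold. Per-bin,
#' per-replicate negative-binomial noise is realized as a gamma random
#' effect on the expectation, and exactly \code{fragmentsPerReplicate}
#' fragments are then drawn multinomially, so the library size equals the
#' configured total. Fragment midpoints are uniform within their bin and
#' lengths uniform within the configured range.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param genome \code{GenomeModel} from \code{\link{generateGenome}}.
#' @param genes gene annotation from \code{\link{generateGenome}}.
#' @param truth planted truth from \code{\link{generateGenome}}.
#' @return list of \code{\linkS4class{FragmentSet}}s (BrdU+ replicates
#'   first, then BrdU-).
#' @export
simulateTripnFragments <- function(config, genome, genes, truth) {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(config@seed + 1L, {
    binSize <- 100L
    sl <- seqlengths(genome)
    baseW <- occupancyWeights(config, genome, genes, binSize)
    chroms <- names(sl)
    nBins <- lengths(baseW)
    expW <- baseW
    triLoci <- truth$triLoci
    for (i in seq_along(triLoci)) {
      chr <- as.character(seqnames(triLoci)[i])
      from <- (start(triLoci)[i] - 1L) %/% binSize + 1L
      to <- min((end(triLoci)[i] - 1L) %/% binSize + 1L, nBins[[chr]])
      expW[[chr]][from:to] <- expW[[chr]][from:to] * mcols(triLoci)$fold[i]
    }
    drawReplicate <- function(weights, sid, cond, rep) {
      wAll <- unlist(weights, use.names = FALSE)
      noise <- if (config@dispersion > 0) {
        rgamma(length(wAll), shape = 1 / config@dispersion, rate = 1 / config@dispersion)
      } else rep(1, length(wAll))
      counts <- as.integer(rmultinom(1, config@fragmentsPerReplicate, wAll * noise))
      binChrom <- rep(chroms, nBins)
      chromBin0 <- unlist(lapply(nBins, function(n) seq_len(n) - 1L), use.names = FALSE)
      nz <- which(counts > 0L)
      binIdx <- rep(nz, counts[nz])
      mids <- chromBin0[binIdx] * binSize +
        as.integer(floor(runif(length(binIdx)) * binSize)) + 1L
      lens <- as.integer(floor(runif(length(binIdx)) *
        (config@fragLenRange[2] - config@fragLenRange[1] + 1L))) + config@fragLenRange[1]
      starts <- mids - lens %/% 2L
      chr <- binChrom[binIdx]
      starts <- pmax(1L, starts)
      ends <- pmin(as.integer(sl[chr]), starts + lens - 1L)
      FragmentSet(GRanges(chr, IRanges(starts, ends), seqinfo = seqinfo(genome)),
                  sampleId = sid, condition = cond, replicate = rep)
    }
    c(
      lapply(seq_len(config@nRepExp), function(r)
        drawReplicate(expW, sprintf("brduPos%d", r), "BrdU+", r)),
      lapply(seq_len(config@nRepCtl), function(r)
        drawReplicate(baseW, sprintf("brduNeg%d", r), "BrdU-", r))
    )
  })
}

#' Simulate strand-specific nascent-transcription peaks and tracks
#'
#' Every active gene gets a peak on its own strand covering its TSS region;
#' single_bidirectional TRI genes additionally get an opposite-strand peak
#' with no annotated partner; unclassified TRI genes get own-strand signal
#' only; inactive genes get none. Divergent/convergent partners carry their
#' own peaks, realizing the orientation geometry.
#'
#' @param genome \code{GenomeModel}.
#' @param genes gene annotation from \code{\link{generateGenome}}.
#' @return list with \code{plusPeaks}, \code{minusPeaks} (\code{GRanges})
#'   and \code{plusTrack}, \code{minusTrack}
#'   (\code{\linkS4class{BinnedTrack}}, 100 bp bins, peak height 10).
#' @export
simulateStrandTranscription <- function(genome, genes) {
  sl <- seqlengths(genome)
  tssAll <- anchorPositions(genes)
  cls <- mcols(genes)$class
  orient <- mcols(genes)$orientation
  chrAll <- as.character(seqnames(genes))
  negAll <- as.character(strand(genes)) == "-"
  active <- which(cls != "inactive")
  # sense peak: TSS -200 .. +800 in transcription direction
  ownLo <- ifelse(negAll[active], tssAll[active] - 800L, tssAll[active] - 200L)
  ownHi <- ifelse(negAll[active], tssAll[active] + 200L, tssAll[active] + 800L)
  ownStrand <- ifelse(negAll[active], "-", "+")
  # single_bidirectional genes get an opposite-strand unannotated peak
  # overlapping the TSS window
  extraIdx <- which(cls == "tri" & !is.na(orient) & orient == "single_bidirectional")
  chrom <- c(chrAll[active], chrAll[extraIdx])
  lo <- c(ownLo, tssAll[extraIdx] - 500L)
  hi <- c(ownHi, tssAll[extraIdx] + 100L)
  strandChar <- c(ownStrand, ifelse(negAll[extraIdx], "+", "-"))
  peaks <- GRanges(factor(chrom, levels = names(sl)),
                   IRanges(pmax(1L, lo), pmin(sl[chrom], hi)),
                   strand = strandChar, seqinfo = seqinfo(genome))
  plusPeaks <- peaks[as.character(strand(peaks)) == "+"]
  minusPeaks <- peaks[as.character(strand(peaks)) == "-"]
  toTrack <- function(pk) {
    vals <- lapply(names(sl), function(chr) rep(0, ceiling(sl[[chr]] / 100L)))
    names(vals) <- names(sl)
    for (i in seq_along(pk)) {
      chr <- as.character(seqnames(pk)[i])
      from <- (start(pk)[i] - 1L) %/% 100L + 1L
      to <- min((end(pk)[i] - 1L) %/% 100L + 1L, length(vals[[chr]]))
      vals[[chr]][from:to] <- vals[[chr]][from:to] + 10
    }
    BinnedTrack(vals, 100L, sl, "raw")
  }
  list(plusPeaks = plusPeaks, minusPeaks = minusPeaks,
       plusTrack = toTrack(plusPeaks), minusTrack = toTrack(minusPeaks))
}

#' Simulate Okazaki-fragment strand counts from the planted origin model
#'
#' Each origin fires independently with its efficiency; a position is
#' replicated by the nearest fired origin, rightward if that origin lies to
#' its left. With no fired origin the direction is balanced. Each sampled
#' fragment at a position with rightward-fork fraction f_R is reverse-strand
#' with probability f_R, so the expected RFD is 2 f_R - 1 (+1 right of a
#' fully efficient origin, -1 left of it).
#'
#' @param genome \code{GenomeModel}.
#' @param origins \code{data.frame} with \code{chrom}, \code{pos},
#'   \code{efficiency} (in (0, 1]).
#' @param depth expected fragments per bin (> 0).
#' @param binSize bin width in bp (default 1000, the RFD convention).
#' @param seed integer RNG seed.
#' @return list with \code{fwd}, \code{rev} count
#'   \code{\linkS4class{BinnedTrack}}s and \code{fR} (expected rightward
#'   fraction per bin).
#' @export
simulateOkseq <- function(genome, origins, depth, binSize = 1000L, seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  if (any(origins$efficiency <= 0 | origins$efficiency > 1)) {
    stop("origin efficiencies must lie in (0, 1]")
  }
  sl <- seqlengths(genome)
  fR <- lapply(names(sl), function(chr) {
    nb <- ceiling(sl[[chr]] / binSize)
    centers <- (seq_len(nb) - 0.5) * binSize
    ors <- origins[origins$chrom == chr, , drop = FALSE]
    rightwardFraction(centers, ors$pos, ors$efficiency)
  })
  names(fR) <- names(sl)
  withSeed(seed, {
    fwd <- list(); rev <- list()
    for (chr in names(sl)) {
      n <- rpois(length(fR[[chr]]), depth)
      r <- rbinom(length(n), n, fR[[chr]])
      fwd[[chr]] <- as.numeric(n - r)
      rev[[chr]] <- as.numeric(r)
    }
    list(fwd = BinnedTrack(fwd, binSize, sl, "raw"),
         rev = BinnedTrack(rev, binSize, sl, "raw"),
         fR = BinnedTrack(fR, binSize, sl, "raw"))
  })
}

# exact expected rightward-fork fraction by enumeration over origin firing
# subsets (origin counts per chromosome are small)
rightwardFraction <- function(positions, originPos, eff) {
  k <- length(originPos)
  if (k == 0L) return(rep(0.5, length(positions)))
  f <- rep(0, length(positions))
  for (mask in 0:(2^k - 1L)) {
    fired <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    pSubset <- prod(c(eff[fired], 1 - eff[setdiff(seq_len(k), fired)]))
    if (pSubset == 0) next
    if (!length(fired)) {
      f <- f + pSubset * 0.5
    } else {
      fpos <- originPos[fired]
      dir <- vapply(positions, function(x) {
        d <- abs(x - fpos)
        o <- fpos[which.min(d)]
        if (o < x) 1 else 0
      }, numeric(1))
      f <- f + pSubset * dir
    }
  }
  f
}

#' Simulate variant calls with a planted deletion excess in TRI gene bodies
#'
#' SBS, insertion and deletion events are placed by per-kb Poisson rates:
#' control gene bodies and intergenic background use the configured base
#' rates; TRI gene bodies use \code{deletionFoldTri} times the deletion
#' rate. Reference alleles come from the genome sequence when present.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param genome \code{GenomeModel}.
#' @param truth planted truth from \code{\link{generateGenome}}.
#' @return \code{data.frame} with \code{chrom}, \code{pos} (1-based,
#'   VCF-style anchored), \code{ref}, \code{alt}, \code{class}, sorted by
#'   (chrom, pos).
#' @export
simulateVariants <- function(config, genome, truth) {
  stopifnot(is(config, "SimulationConfig"))
  withSeed(config@seed + 2L, {
    sl <- seqlengths(genome)
    rates <- config@variantRates
    regions <- c(
      granges(truth$triGeneBodies),
      granges(truth$controlGeneBodies)
    )
    delRate <- c(rep(rates[["deletion"]] * config@deletionFoldTri,
                     length(truth$triGeneBodies)),
                 rep(rates[["deletion"]], length(truth$controlGeneBodies)))
    out <- list()
    bases <- c("A", "C", "G", "T")
    drawIn <- function(region, count, type) {
      if (count == 0L) return(NULL)
      chr <- as.character(seqnames(region))
      pos <- start(region) + as.integer(floor(runif(count) * (width(region) - 4L)))
      refBase <- if (hasSequence(genome)) {
        vapply(pos, function(p) as.character(subseq(genome@sequences[[chr]], p, p)),
               character(1))
      } else sample(bases, count, replace = TRUE)
      refBase[!refBase %in% bases] <- "A"
      if (type == "sbs") {
        alt <- vapply(refBase, function(b) sample(setdiff(bases, b), 1L), character(1))
        data.frame(chrom = chr, pos = pos, ref = refBase, alt = alt,
                   stringsAsFactors = FALSE)
      } else if (type == "insertion") {
        ins <- vapply(seq_len(count), function(i)
          paste(sample(bases, sample(1:3, 1L), replace = TRUE), collapse = ""),
          character(1))
        data.frame(chrom = chr, pos = pos, ref = refBase,
                   alt = paste0(refBase, ins), stringsAsFactors = FALSE)
      } else {
        delLen <- sample(1:3, count, replace = TRUE)
        refFull <- vapply(seq_len(count), function(i) {
          if (hasSequence(genome)) {
            s <- as.character(subseq(genome@sequences[[chr]], pos[i], pos[i] + delLen[i]))
            if (grepl("[^ACGT]", s)) s <- paste(c(refBase[i],
              sample(bases, delLen[i], replace = TRUE)), collapse = "")
            s
          } else {
            paste(c(refBase[i], sample(bases, delLen[i], replace = TRUE)), collapse = "")
          }
        }, character(1))
        data.frame(chrom = chr, pos = pos, ref = refFull, alt = refBase,
                   stringsAsFactors = FALSE)
      }
    }
    for (i in seq_along(regions)) {
      kb <- width(regions)[i] / 1000
      for (type in c("sbs", "insertion", "deletion")) {
        rate <- if (type == "deletion") delRate[i] else rates[[type]]
        n <- rpois(1L, rate * kb)
        out[[length(out) + 1L]] <- drawIn(regions[i], n, type)
      }
    }
    vars <- do.call(rbind, out)
    if (is.null(vars)) {
      vars <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0))
    }
    vars$class <- classifyVariant(vars$ref, vars$alt)
    vars[order(vars$chrom, vars$pos), , drop = FALSE]
  })
}
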