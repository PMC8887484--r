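#' Count fragments per window per sample
#'
#' A fragment counts in every window its interval overlaps by at least 1 bp
#' (default, mirroring consensus-site counting over all windows); midpoint
#' mode assigns each fragment to the single window containing its midpoint.
#'
#' @param fragmentSets list of \code{\linkS4class{FragmentSet}}s (or one).
#' @param windows \code{GRanges}; windows should not overlap within a set.
#' @param genome optional \code{GenomeModel} for validation.
#' @param mode \code{"overlap"} or \code{"midpoint"}.
#' @return integer matrix (windows x samples) with sample ids as column
#'   names; attributes \code{librarySizes} and \code{conditions}.
#' @export
countFragments <- function(fragmentSets, windows, genome = NULL,
                           mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  if (is(fragmentSets, "FragmentSet")) fragmentSets <- list(fragmentSets)
  if (!is.null(genome)) validateIntervals(windows, genome)
  counts <- vapply(fragmentSets, function(fs) {
    fr <- fragments(fs)
    if (mode == "midpoint") {
      mid <- (start(fr) + end(fr)) %/% 2L
      fr <- GRanges(seqnames(fr), IRanges(mid, mid))
    }
    countOverlaps(windows, fr, ignore.strand = TRUE)
  }, integer(length(windows)))
  counts <- matrix(counts, nrow = length(windows))
  colnames(counts) <- vapply(fragmentSets, sampleId, character(1))
  attr(counts, "librarySizes") <- vapply(fragmentSets, librarySize, integer(1))
  attr(counts, "conditions") <- vapply(fragmentSets, condition, character(1))
  counts
}

#' Call candidate enrichment peaks by a Poisson local-lambda scan
#'
#' Fragment pileup at fixed resolution (default 50 bp bins) is tested
#' against a local Poisson rate estimated from the pooled background set:
#' lambda_local = max(lambda_genome, lambda_5kb, lambda_10kb), scaled to the
#' experiment's library size. Per-bin p-values are BH-corrected; bins at
#' q <= qThreshold are merged within \code{mergeGap} bp and peaks shorter
#' than \code{minWidth} bp are dropped. With no background the experiment's
#' own genome-wide rate serves as lambda.
#'
#' @param expFragments pooled experimental fragments (\code{GRanges} or list
#'   of \code{FragmentSet}s).
#' @param bgFragments pooled background fragments, or \code{NULL}.
#' @param genome \code{GenomeModel}.
#' @param binSize scan resolution (bp).
#' @param qThreshold BH q-value cutoff.
#' @param mergeGap maximum gap between significant bins merged into one peak.
#' @param minWidth minimum peak width (bp).
#' @return \code{GRanges} of candidate peaks.
#' @export
callCandidatePeaks <- function(expFragments, bgFragments, genome,
                               binSize = 50L, qThreshold = 0.05,
                               mergeGap = 200L, minWidth = 150L) {
  expGr <- poolFragments(expFragments)
  if (!length(expGr)) stop("experimental fragment set is empty")
  bgGr <- if (is.null(bgFragments)) NULL else poolFragments(bgFragments)
  bins <- genomeBins(genome, binSize)
  kExp <- countOverlaps(bins, expGr, ignore.strand = TRUE)
  if (is.null(bgGr) || !length(bgGr)) {
    lamLocal <- rep(mean(kExp), length(bins))
  } else {
    kBg <- countOverlaps(bins, bgGr, ignore.strand = TRUE)
    scale <- length(expGr) / length(bgGr)
    lamG <- mean(kBg) * scale
    chrVec <- as.character(seqnames(bins))
    lamLocal <- numeric(length(bins))
    n5 <- max(3L, round(5000 / binSize)); if (n5 %% 2L == 0L) n5 <- n5 + 1L
    n10 <- max(3L, round(10000 / binSize)); if (n10 %% 2L == 0L) n10 <- n10 + 1L
    for (chr in unique(chrVec)) {
      idx <- which(chrVec == chr)
      v <- as.numeric(kBg[idx])
      lam5 <- frollmean(v, n5, align = "center") * scale
      lam10 <- frollmean(v, n10, align = "center") * scale
      lam5[is.na(lam5)] <- lamG
      lam10[is.na(lam10)] <- lamG
      lamLocal[idx] <- pmax(lamG, lam5, lam10)
    }
  }
  p <- ppois(kExp - 1L, lamLocal, lower.tail = FALSE)
  q <- bhFdr(p)
  sig <- bins[q <= qThreshold]
  if (!length(sig)) return(GRanges())
  peaks <- reduce(sig, min.gapwidth = mergeGap + 1L)
  peaks[width(peaks) >= minWidth]
}

poolFragments <- function(x) {
  if (is(x, "GRanges")) return(x)
  if (is(x, "FragmentSet")) return(fragments(x))
  do.call(c, lapply(x, function(f) granges(fragments(f))))
}

#' Replicate-aware one-sided differential enrichment test
#'
#' A pooled beta-binomial conditional test: with library totals libE
#' (experimental) and libC (control), the null proportion of experimental
#' counts is p0 = libE / (libE + libC). For each window the pooled
#' experimental count k out of the window total t = k + control is tested
#' one-sided for enrichment, P(X >= k) with X ~ beta-binomial(t, p0, rho),
#' reducing exactly to binomial(t, p0) when rho <= 1e-8. The common
#' overdispersion rho is estimated once per run by method of moments from
#' the replicate-level within-condition proportion variance across windows
#' with t >= 10. log2 fold change uses library-normalized counts with
#' pseudocount 0.5 / min(library size).
#'
#' @param counts integer matrix (windows x samples), e.g. from
#'   \code{\link{countFragments}}.
#' @param librarySizes per-sample library sizes (defaults to the matrix
#'   attribute).
#' @param conditions per-sample condition labels, \code{"BrdU+"} /
#'   \code{"BrdU-"} (defaults to the matrix attribute).
#' @param rho overdispersion override; \code{NULL} estimates it.
#' @return \code{data.frame} with \code{log2FC}, \code{p}, \code{flag}
#'   (TRUE for empty windows, where p = 1 and log2FC = 0); attribute
#'   \code{rho} records the dispersion used.
#' @export
differentialWindowTest <- function(counts, librarySizes = attr(counts, "librarySizes"),
                                   conditions = attr(counts, "conditions"),
                                   rho = NULL) {
  stopifnot(!is.null(librarySizes), !is.null(conditions))
  if (any(librarySizes <= 0)) stop("library sizes must be positive")
  expIdx <- which(conditions == "BrdU+")
  ctlIdx <- which(conditions == "BrdU-")
  if (!length(expIdx) || !length(ctlIdx)) {
    stop("need at least one replicate per condition")
  }
  libE <- sum(librarySizes[expIdx]); libC <- sum(librarySizes[ctlIdx])
  p0 <- libE / (libE + libC)
  k <- rowSums(counts[, expIdx, drop = FALSE])
  m <- rowSums(counts[, ctlIdx, drop = FALSE])
  t <- k + m
  if (is.null(rho)) {
    rho <- estimateRho(counts, librarySizes, expIdx, ctlIdx, t)
  }
  pseudo <- 0.5 / min(librarySizes)
  log2FC <- log2((k / libE + pseudo) / (m / libC + pseudo))
  p <- betaBinomialUpperTail(k, t, p0, rho)
  flag <- t == 0L
  p[flag] <- 1
  log2FC[flag] <- 0
  out <- data.frame(log2FC = log2FC, p = p, flag = flag)
  attr(out, "rho") <- rho
  out
}

# method-of-moments common overdispersion from replicate-level
# within-condition variation, over windows with pooled total >= 10
estimateRho <- function(counts, librarySizes, expIdx, ctlIdx, t) {
  use <- which(t >= 10L)
  if (!length(use)) return(0)
  num <- 0; den <- 0
  for (idx in list(expIdx, ctlIdx)) {
    J <- length(idx)
    if (J < 2L) next
    q <- librarySizes[idx] / sum(librarySizes[idx])
    sub <- counts[use, idx, drop = FALSE]
    tc <- rowSums(sub)
    ok <- tc >= 2L
    if (!any(ok)) next
    expd <- outer(tc[ok], q)
    x2 <- rowSums((sub[ok, , drop = FALSE] - expd)^2 / (expd * (1 - matrix(q, sum(ok), J, byrow = TRUE))))
    num <- num + sum(x2 - (J - 1))
    den <- den + sum((J - 1) * (tc[ok] - 1))
  }
  if (den <= 0) return(0)
  max(0, min(0.999, num / den))
}

# one-sided upper tail P(X >= k) of the beta-binomial(t, p0, rho) with
# intra-class correlation parameterization; exact binomial when rho ~ 0
betaBinomialUpperTail <- function(k, t, p0, rho) {
  if (rho <= 1e-8) {
    return(pbinom(k - 1, t, p0, lower.tail = FALSE))
  }
  a <- p0 * (1 - rho) / rho
  b <- (1 - p0) * (1 - rho) / rho
  lbab <- lbeta(a, b)
  vapply(seq_along(k), function(w) {
    tw <- t[w]; kw <- k[w]
    if (tw == 0L) return(1)
    if (kw <= 0L) return(1)
    logpmf <- function(i) lchoose(tw, i) + lbeta(i + a, tw - i + b) - lbab
    if (kw <= tw - kw) {
      # shorter lower side: 1 - P(X <= k-1)
      max(0, min(1, 1 - sum(exp(logpmf(0:(kw - 1L))))))
    } else {
      max(0, min(1, sum(exp(logpmf(kw:tw)))))
    }
  }, numeric(1))
}

#' Benjamini-Hochberg FDR within one window set
#'
#' Standard step-up BH with monotonicity enforcement (equal to the
#' brute-force definition q_(i) = min over j >= i of m p_(j) / j).
#'
#' @param p numeric p-values in [0, 1].
#' @return numeric FDR values.
#' @export
bhFdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Sliding-window differential scan around TSSs
#'
#' Builds, for every TSS, fixed-length windows sliding across the
#' TSS +/- flank region (defaults: 1 kb windows, +/- 1 kb, 100 bp steps,
#' giving 11 offset sets), and analyzes each offset set independently:
#' overlapping windows across TSSs within one set are merged before
#' counting, the differential test runs per set, and BH correction is
#' applied within each set (a pooled-FDR mode across sets is available for
#' sensitivity analysis).
#'
#' @param fragmentSets list of \code{\linkS4class{FragmentSet}}s.
#' @param tss \code{GRanges} of TSS anchor points (stranded or not).
#' @param genome \code{GenomeModel}.
#' @param windowLength,flank,step scan geometry (bp).
#' @param mode fragment counting mode.
#' @param pooledFdr apply BH across all sets jointly instead of per set.
#' @return \code{GRanges} of tested (merged) windows with \code{setId},
#'   \code{log2FC}, \code{p}, \code{fdr}; attribute \code{rho}.
#' @export
tssWindowScan <- function(fragmentSets, tss, genome,
                          windowLength = 1000L, flank = 1000L, step = 100L,
                          mode = "overlap", pooledFdr = FALSE) {
  allWin <- makeWindows(tss, flankUp = flank, flankDown = flank,
                        windowLength = windowLength, step = step, genome = genome)
  results <- list()
  rhoUsed <- NA_real_
  for (kOff in sort(unique(mcols(allWin)$offset))) {
    win <- mergeIntervals(allWin[mcols(allWin)$offset == kOff])
    counts <- countFragments(fragmentSets, win, mode = mode)
    dt <- differentialWindowTest(counts)
    rhoUsed <- attr(dt, "rho")
    mcols(win)$setId <- sprintf("tss_k%02d", kOff)
    mcols(win)$log2FC <- dt$log2FC
    mcols(win)$p <- dt$p
    mcols(win)$fdr <- if (pooledFdr) NA_real_ else bhFdr(dt$p)
    results[[length(results) + 1L]] <- win
  }
  out <- do.call(c, results)
  if (pooledFdr) mcols(out)$fdr <- bhFdr(mcols(out)$p)
  attr(out, "rho") <- rhoUsed
  out
}

#' Combine and merge significant windows into TRI loci
#'
#' The union of all inputs at FDR <= threshold is merged (gap 0, bookended
#' intervals merge); each merged locus keeps the highest (worst) FDR among
#' its members and the provenance of contributing sets. Output is disjoint
#' and sorted; re-running on its own output is a fixed point.
#'
#' @param ... one or more \code{GRanges} carrying \code{fdr} and
#'   \code{setId} metadata columns (de novo peak sets, TSS-scan sets).
#' @param fdrThreshold inclusion cutoff (default 0.05).
#' @param mergeBookended merge touching (gap-0) members too (default TRUE,
#'   the common merge behavior; FALSE merges only overlapping members).
#' @return \code{GRanges} of TRI loci with \code{fdr} (max over members),
#'   \code{nMembers}, and \code{provenance} (comma-separated member set
#'   ids).
#' @export
combineAndMerge <- function(..., fdrThreshold = 0.05, mergeBookended = TRUE) {
  inputs <- list(...)
  inputs <- inputs[vapply(inputs, length, integer(1)) > 0L]
  if (!length(inputs)) return(GRanges())
  all <- do.call(c, lapply(inputs, function(gr) {
    stopifnot(!is.null(mcols(gr)$fdr), !is.null(mcols(gr)$setId))
    gr[, c("fdr", "setId")]
  }))
  sig <- all[mcols(all)$fdr <= fdrThreshold]
  if (!length(sig)) return(GRanges())
  merged <- reduce(granges(sig), min.gapwidth = if (mergeBookended) 1L else 0L,
                   with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- mcols(merged)$revmap
  mcols(merged)$fdr <- vapply(revmap, function(i) max(mcols(sig)$fdr[i]), numeric(1))
  mcols(merged)$nMembers <- lengths(revmap)
  mcols(merged)$provenance <- vapply(revmap, function(i)
    paste(sort(unique(mcols(sig)$setId[i])), collapse = ","), character(1))
  mcols(merged)$revmap <- NULL
  sort(merged)
}

#' Associate genes with TRI loci and derive the cTSS set
#'
#' A gene is associated with a locus when its TSS lies within +/- flank
#' (default 1.5 kb) of the locus center; a locus may list several genes
#' (nearby annotated genes on both strands).
#'
#' @param triLoci \code{GRanges} from \code{\link{combineAndMerge}}.
#' @param genes gene annotation \code{GRanges} with \code{geneId}.
#' @param flank association radius around locus centers (bp).
#' @return \code{triLoci} with added metadata column \code{genes}
#'   (comma-separated gene ids, "" when none).
#' @export
assignGenes <- function(triLoci, genes, flank = 1500L) {
  centers <- (start(triLoci) + end(triLoci)) %/% 2L
  tssPos <- anchorPositions(genes)
  geneChrom <- as.character(seqnames(genes))
  mcols(triLoci)$genes <- vapply(seq_along(triLoci), function(i) {
    hit <- geneChrom == as.character(seqnames(triLoci)[i]) &
      abs(tssPos - centers[i]) <= flank
    paste(mcols(genes)$geneId[hit], collapse = ",")
  }, character(1))
  triLoci
}

#' Control TSSs: active but not TRI-associated
#'
#' Active TSSs are those whose TSS +/- windowHalf window holds more than
#' \code{activityFloor} pooled fragments; TSSs associated with a TRI locus
#' (within the association flank of a locus center) are removed.
#'
#' @param genes gene annotation \code{GRanges}.
#' @param fragmentSets list of \code{\linkS4class{FragmentSet}}s (pooled for
#'   the occupancy check).
#' @param triLoci called TRI loci.
#' @param windowHalf half-width of the occupancy window (bp).
#' @param activityFloor minimum pooled fragment count (exclusive) for an
#'   active TSS.
#' @param flank TRI association radius (bp), as in \code{\link{assignGenes}}.
#' @return \code{GRanges} of cTSS positions (width 1, stranded) with
#'   \code{geneId}.
#' @export
ctssSet <- function(genes, fragmentSets, triLoci, windowHalf = 1000L,
                    activityFloor = 0, flank = 1500L) {
  tssPos <- anchorPositions(genes)
  tssGr <- GRanges(seqnames(genes), IRanges(tssPos, tssPos), strand = strand(genes),
                   geneId = mcols(genes)$geneId)
  winGr <- GRanges(seqnames(genes), IRanges(pmax(1L, tssPos - windowHalf), tssPos + windowHalf))
  pooled <- poolFragments(fragmentSets)
  occ <- countOverlaps(winGr, pooled, ignore.strand = TRUE)
  active <- occ > activityFloor
  if (length(triLoci)) {
    centers <- (start(triLoci) + end(triLoci)) %/% 2L
    centerGr <- GRanges(seqnames(triLoci), IRanges(centers, centers))
    nearTri <- overlapsAny(tssGr, centerGr + flank, ignore.strand = TRUE)
  } else {
    nearTri <- rep(FALSE, length(tssGr))
  }
  tssGr[active & !nearTri]
}
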