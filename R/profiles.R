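#' Build a point-anchored profile matrix
#'
#' One row per region, one column per bin from -flankUp to +flankDown
#' around the anchor; each cell is the mean track value over the bin.
#' Regions overlapping the genome blacklist are excluded before
#' aggregation; regions whose profile span leaves the genome are dropped
#' with a recorded count. With \code{strandFlip}, minus-strand rows are
#' reversed so columns read in transcription direction.
#'
#' @param regions \code{GRanges}; the anchor is the region start, its 5'
#'   end for stranded regions, or the midpoint with
#'   \code{anchor = "center"}.
#' @param track a \code{\linkS4class{BinnedTrack}}.
#' @param flankUp,flankDown profile extent (bp).
#' @param bin column width (bp); must divide both flanks.
#' @param strandFlip reverse minus-strand rows.
#' @param anchor \code{"start"} (5' end) or \code{"center"}.
#' @param genome optional \code{GenomeModel} whose blacklist excludes
#'   regions.
#' @return A \code{\linkS4class{ProfileMatrix}}; attribute \code{dropped}
#'   counts regions excluded for leaving the genome.
#' @export
buildProfileMatrix <- function(regions, track, flankUp = 1500L, flankDown = 1500L,
                               bin = 10L, strandFlip = FALSE,
                               anchor = c("start", "center"), genome = NULL) {
  anchor <- match.arg(anchor)
  if (flankUp %% bin != 0L || flankDown %% bin != 0L) {
    stop("bin must divide both flanks")
  }
  if (!is.null(genome) && length(blacklist(genome))) {
    keep <- !overlapsAny(granges(regions), blacklist(genome), ignore.strand = TRUE)
    regions <- regions[keep]
  }
  pos <- if (anchor == "center") (start(regions) + end(regions)) %/% 2L
         else anchorPositions(regions)
  chr <- as.character(seqnames(regions))
  offsets <- seq(-flankUp, flankDown - bin, by = bin)
  nCol <- length(offsets)
  inGenome <- pos - flankUp >= 1L &
    pos + flankDown <= track@seqlengths[chr] * 1.0
  dropped <- sum(!inGenome)
  if (dropped) warning(dropped, " region(s) anchored off-genome excluded")
  regions <- regions[inGenome]; pos <- pos[inGenome]; chr <- chr[inGenome]
  mat <- matrix(NA_real_, nrow = length(regions), ncol = nCol)
  tb <- track@binSize
  for (i in seq_along(regions)) {
    v <- track@values[[chr[i]]]
    cellStart <- pos[i] + offsets
    mat[i, ] <- vapply(seq_len(nCol), function(j) {
      from <- (cellStart[j] - 1L) %/% tb + 1L
      to <- (cellStart[j] + bin - 2L) %/% tb + 1L
      mean(v[from:to], na.rm = TRUE)
    }, numeric(1))
  }
  mat[is.nan(mat)] <- NA_real_
  if (strandFlip) {
    neg <- as.character(strand(regions)) == "-"
    mat[neg, ] <- mat[neg, nCol:1, drop = FALSE]
  }
  rownames(mat) <- if (!is.null(mcols(regions)$geneId)) mcols(regions)$geneId else NULL
  pm <- new("ProfileMatrix", values = mat, offsets = as.numeric(offsets),
            binSize = as.integer(bin), anchorMode = "point")
  attr(pm, "dropped") <- dropped
  pm
}

#' Aggregate a profile matrix to median and standard error per bin
#'
#' Per column: the median over non-missing rows and SE = sd / sqrt(n) with
#' n the non-missing count. Invariant to row order.
#'
#' @param pm a \code{\linkS4class{ProfileMatrix}}.
#' @return \code{data.frame} with \code{offset}, \code{median}, \code{se},
#'   \code{n} (median and se are NA for empty columns).
#' @export
aggregateProfile <- function(pm) {
  stopifnot(is(pm, "ProfileMatrix"))
  m <- pm@values
  n <- colSums(!is.na(m))
  med <- suppressWarnings(apply(m, 2, median, na.rm = TRUE))
  se <- suppressWarnings(apply(m, 2, sd, na.rm = TRUE)) / sqrt(pmax(n, 1))
  se[n == 1L] <- 0
  med[n == 0L] <- NA_real_
  se[n == 0L] <- NA_real_
  data.frame(offset = pm@offsets, median = med, se = se, n = n)
}

#' Scaled gene-body profile matrix
#'
#' The gene body is resampled to exactly \code{bodyBins} columns by
#' length-proportional averaging, flanks are binned natively, and rows are
#' strand-flipped into transcription direction (the default for body
#' profiles). Genes shorter than \code{bodyBins} bp are excluded.
#'
#' @param genes stranded \code{GRanges} of gene bodies.
#' @param track a \code{\linkS4class{BinnedTrack}}.
#' @param bodyBins number of body columns.
#' @param flank flank extent (bp) on each side.
#' @param bin flank column width (bp).
#' @param strandFlip flip minus-strand rows (default TRUE).
#' @return A \code{\linkS4class{ProfileMatrix}} with \code{anchorMode
#'   "scaled_body"}; flank columns carry bp offsets (upstream negative,
#'   downstream past 1e6 marker-free: see \code{offsets}), body columns
#'   carry fractional positions in (0, 1).
#' @export
scaledBodyMatrix <- function(genes, track, bodyBins = 100L, flank = 10000L,
                             bin = 1000L, strandFlip = TRUE) {
  if (flank %% bin != 0L) stop("bin must divide flank")
  keep <- width(genes) >= bodyBins
  genes <- genes[keep]
  nFlank <- flank %/% bin
  nCol <- 2L * nFlank + bodyBins
  offsets <- c(seq(-flank, -bin, by = bin),
               (seq_len(bodyBins) - 0.5) / bodyBins,
               seq(1, flank, by = bin))
  tb <- track@binSize
  mat <- matrix(NA_real_, nrow = length(genes), ncol = nCol)
  cellMean <- function(v, from, to) {
    if (to < from || from < 1L || to > length(v) * tb) return(NA_real_)
    i1 <- (from - 1L) %/% tb + 1L
    i2 <- (to - 1L) %/% tb + 1L
    m <- mean(v[i1:i2], na.rm = TRUE)
    if (is.nan(m)) NA_real_ else m
  }
  for (i in seq_along(genes)) {
    chr <- as.character(seqnames(genes)[i])
    v <- track@values[[chr]]
    gs <- start(genes)[i]; ge <- end(genes)[i]
    row <- numeric(nCol)
    # upstream flank (reference orientation: left of gene start)
    for (j in seq_len(nFlank)) {
      from <- gs - flank + (j - 1L) * bin
      row[j] <- cellMean(v, from, from + bin - 1L)
    }
    # body, length-proportional
    bw <- (ge - gs + 1) / bodyBins
    for (j in seq_len(bodyBins)) {
      from <- gs + as.integer(floor((j - 1L) * bw))
      to <- gs + as.integer(ceiling(j * bw)) - 1L
      row[nFlank + j] <- cellMean(v, max(gs, from), min(ge, to))
    }
    for (j in seq_len(nFlank)) {
      from <- ge + 1L + (j - 1L) * bin
      row[nFlank + bodyBins + j] <- cellMean(v, from, from + bin - 1L)
    }
    if (strandFlip && as.character(strand(genes)[i]) == "-") row <- rev(row)
    mat[i, ] <- row
  }
  rownames(mat) <- if (!is.null(mcols(genes)$geneId)) mcols(genes)$geneId else NULL
  new("ProfileMatrix", values = mat, offsets = offsets,
      binSize = as.integer(bin), anchorMode = "scaled_body")
}

setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix (%s): %d region(s) x %d bin(s) of %d bp\n",
              object@anchorMode, nrow(object@values), ncol(object@values),
              object@binSize))
})

#' Matrix values of a ProfileMatrix
#' @param x a \code{ProfileMatrix}
#' @export
profileValues <- function(x) {
  stopifnot(is(x, "ProfileMatrix"))
  x@values
}

#' Subsample regions to match a group size
#'
#' Uniform sample without replacement, deterministic given the seed; used
#' to plot/compare equal numbers of control and TRI regions.
#'
#' @param regions \code{GRanges}.
#' @param n sample size (<= number of regions).
#' @param seed integer RNG seed.
#' @return \code{GRanges} subset of size n.
#' @export
matchSample <- function(regions, n, seed = 1L) {
  if (n > length(regions)) stop("n exceeds the number of regions")
  idx <- withSeed(seed, sample.int(length(regions), n))
  regions[idx]
}

#' Compare signal summaries between two region groups
#'
#' Each region (optionally resized to a fixed length about its center) is
#' summarized by the median track value per sub-window averaged across the
#' region (\code{\link{mapSignalSummary}}); groups are compared with the
#' rank-sum test.
#'
#' @param groupA,groupB \code{GRanges}.
#' @param track \code{\linkS4class{BinnedTrack}} or scored \code{GRanges}.
#' @param roiLength optional fixed region-of-interest length (bp) centered
#'   on each region's midpoint.
#' @param subWindow sub-window size (bp).
#' @param stat sub-window statistic.
#' @return list with \code{summaryA}, \code{summaryB} (per-region values),
#'   \code{medianA}, \code{medianB}, \code{p} (two-sided rank-sum), and
#'   \code{statistic}.
#' @export
compareRegionGroups <- function(groupA, groupB, track, roiLength = NULL,
                                subWindow = 10L, stat = "median") {
  if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
  fix <- function(gr) {
    if (is.null(roiLength)) return(gr)
    mid <- (start(gr) + end(gr)) %/% 2L
    half <- roiLength %/% 2L
    GRanges(seqnames(gr), IRanges(pmax(1L, mid - half), mid - half + roiLength - 1L))
  }
  sa <- mapSignalSummary(fix(groupA), track, subWindow, stat = stat)
  sb <- mapSignalSummary(fix(groupB), track, subWindow, stat = stat)
  if (all(is.na(sa)) || all(is.na(sb))) stop("a group has all-missing summaries")
  rt <- ranksumTest(sa[!is.na(sa)], sb[!is.na(sb)])
  list(summaryA = sa, summaryB = sb,
       medianA = median(sa, na.rm = TRUE), medianB = median(sb, na.rm = TRUE),
       p = rt$p, statistic = rt$statistic)
}
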