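#' Merge intervals within a gap
#'
#' Produces a sorted, disjoint set covering the same bases. With
#' \code{maxGap = 0}, overlapping and bookended (touching) intervals merge,
#' matching the common merge default of BED tooling. Idempotent and
#' order-independent.
#'
#' @param gr \code{GRanges}.
#' @param maxGap maximum gap (bp) across which intervals still merge.
#' @return sorted disjoint \code{GRanges}.
#' @export
mergeIntervals <- function(gr, maxGap = 0L) {
  if (maxGap < 0) stop("maxGap must be >= 0")
  reduce(sort(granges(gr), ignore.strand = TRUE),
         min.gapwidth = maxGap + 1L, ignore.strand = TRUE)
}

#' Per-query overlap counts and base-pair overlap
#'
#' For each query interval, the number of subject intervals it overlaps
#' (>= 1 bp) and the total overlapped base pairs (summed over all
#' overlapping subject intervals). The summed bp overlap is symmetric in
#' query and subject.
#'
#' @param query,subject \code{GRanges}.
#' @return \code{data.frame} with columns \code{hits} and \code{bp}, one row
#'   per query interval.
#' @export
intersectCount <- function(query, subject) {
  ov <- findOverlaps(query, subject, ignore.strand = TRUE)
  hits <- countOverlaps(query, subject, ignore.strand = TRUE)
  bp <- integer(length(query))
  if (length(ov)) {
    w <- width(pintersect(granges(query)[queryHits(ov)],
                          granges(subject)[subjectHits(ov)]))
    agg <- tapply(w, queryHits(ov), sum)
    bp[as.integer(names(agg))] <- as.integer(agg)
  }
  data.frame(hits = hits, bp = bp)
}

#' Sliding windows around anchor points
#'
#' Builds the fixed-length sliding windows used for the TSS scan: windows of
#' exactly \code{windowLength} bp starting \code{flankUp} bp before the
#' anchor and advancing by \code{step} until the last window ends
#' \code{flankDown} bp after it. For minus-strand anchors the construction
#' is mirrored so that \code{flankUp} is upstream in the transcription
#' sense. Windows that would be clipped below full length by a chromosome
#' edge are dropped, keeping all windows in a set length-matched.
#'
#' @param anchors \code{GRanges} of anchor points (width-1 positions; wider
#'   ranges anchor at their 5' end respecting strand, or their start when
#'   unstranded).
#' @param flankUp,flankDown flank sizes in bp.
#' @param windowLength window length in bp, \code{<= flankUp + flankDown}.
#' @param step step size in bp.
#' @param genome optional \code{GenomeModel} for edge clipping.
#' @return \code{GRanges} of windows with metadata columns \code{anchor}
#'   (index into \code{anchors}) and \code{offset} (offset-set index k,
#'   0-based).
#' @export
makeWindows <- function(anchors, flankUp = 1000L, flankDown = 1000L,
                        windowLength = 1000L, step = 100L, genome = NULL) {
  if (step < 1) stop("step must be >= 1")
  if (windowLength > flankUp + flankDown) stop("windowLength must be <= flankUp + flankDown")
  if (!is.null(genome)) {
    pos0 <- anchorPositions(anchors)
    sl <- seqlengths(genome)
    chr0 <- as.character(seqnames(anchors))
    if (any(!chr0 %in% names(sl)) || any(pos0 < 1L) || any(pos0 > sl[chr0])) {
      stop("anchor off chromosome")
    }
  }
  K <- (flankUp + flankDown - windowLength) %/% step
  pos <- anchorPositions(anchors)
  chr <- as.character(seqnames(anchors))
  neg <- as.character(strand(anchors)) == "-"
  n <- length(anchors)
  offs <- rep(0:K, each = n)
  anchorIdx <- rep(seq_len(n), K + 1L)
  # plus strand / unstranded: window k = [pos - flankUp + k*step, + windowLength)
  startPos <- ifelse(rep(neg, K + 1L),
                     pos[anchorIdx] + flankUp - offs * step - windowLength + 1L,
                     pos[anchorIdx] - flankUp + offs * step)
  gr <- GRanges(chr[anchorIdx], IRanges(start = startPos, width = windowLength),
                anchor = anchorIdx, offset = offs)
  keep <- start(gr) >= 1L
  if (!is.null(genome)) {
    sl <- seqlengths(genome)
    keep <- keep & end(gr) <= sl[as.character(seqnames(gr))]
  }
  gr <- gr[keep]
  gr[order(mcols(gr)$offset, mcols(gr)$anchor)]
}

# 5'-respecting anchor position of each range (start for +/* , end for -)
anchorPositions <- function(gr) {
  ifelse(as.character(strand(gr)) == "-", end(gr), start(gr))
}

#' Region summary by sub-window statistic then mean
#'
#' The region-summary procedure used for group comparisons: each region is
#' partitioned into sub-windows, the chosen statistic (default median) of
#' the track values overlapping each sub-window is taken, and the summaries
#' are averaged across the region. Empty sub-windows are missing and are
#' excluded from the mean; a region with no covered sub-window yields
#' \code{NA}.
#'
#' @param regions \code{GRanges}.
#' @param track a \code{\linkS4class{BinnedTrack}} or a scored \code{GRanges}
#'   (e.g. read from bedGraph).
#' @param subWindow sub-window size in bp.
#' @param stat \code{"median"} or \code{"mean"}.
#' @return numeric vector, one summary per region (NA where uncovered).
#' @export
mapSignalSummary <- function(regions, track, subWindow, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  statFun <- if (stat == "median") median else mean
  scored <- if (is(track, "BinnedTrack")) trackToGRanges(track) else track
  if (is.null(score(scored))) stop("track must carry scores")
  vapply(seq_along(regions), function(i) {
    r <- regions[i]
    ends <- seq(start(r) - 1L, end(r), by = subWindow)
    if (ends[length(ends)] < end(r)) ends <- c(ends, end(r))
    subs <- GRanges(seqnames(r), IRanges(start = head(ends, -1L) + 1L, end = ends[-1L]))
    ov <- findOverlaps(subs, scored, ignore.strand = TRUE)
    if (!length(ov)) return(NA_real_)
    vals <- tapply(score(scored)[subjectHits(ov)], queryHits(ov), statFun)
    mean(vals)
  }, numeric(1))
}
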