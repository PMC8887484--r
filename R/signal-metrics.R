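#' Replication fork directionality from strand-split Okazaki counts
#'
#' RFD = (R - F) / (R + F) per bin, where F and R are forward- and
#' reverse-strand Okazaki fragment counts. +1 means purely rightward-moving
#' forks, -1 purely leftward. Bins with no coverage (R + F = 0) are missing
#' rather than 0: zero is a meaningful balanced-fork value and must not be
#' conflated with no data.
#'
#' @param fwd,rev \code{\linkS4class{BinnedTrack}}s of forward / reverse
#'   strand counts on the same binning.
#' @return \code{BinnedTrack} of RFD values in [-1, 1] with NA at uncovered
#'   bins.
#' @export
computeRfd <- function(fwd, rev) {
  checkSameBinning(fwd, rev)
  vals <- lapply(names(fwd@values), function(chr) {
    f <- fwd@values[[chr]]; r <- rev@values[[chr]]
    if (any(f < 0, na.rm = TRUE) || any(r < 0, na.rm = TRUE)) {
      stop("strand counts must be non-negative")
    }
    tot <- f + r
    out <- (r - f) / tot
    out[!is.na(tot) & tot == 0] <- NA_real_
    out
  })
  names(vals) <- names(fwd@values)
  BinnedTrack(vals, fwd@binSize, fwd@seqlengths, "raw")
}

checkSameBinning <- function(a, b) {
  stopifnot(is(a, "BinnedTrack"), is(b, "BinnedTrack"))
  if (a@binSize != b@binSize ||
      !identical(names(a@values), names(b@values)) ||
      !identical(lengths(a@values), lengths(b@values))) {
    stop("tracks are not on the same binning")
  }
  invisible(TRUE)
}

#' Replication-timing log2 ratio (TimEX)
#'
#' Per-bin log2((S + c) / (G0 + c)) between an S-phase (activated) and a
#' G0 (resting) coverage track, followed by a centered running mean over
#' \code{smooth} bp. Higher values mean earlier replication. The pseudocount
#' \code{c} guards empty bins.
#'
#' @param sTrack,g0Track RPM-normalized \code{BinnedTrack}s on the same
#'   binning (default bin 100 bp).
#' @param smooth smoothing span in bp (default 500).
#' @param pseudocount added to both tracks before the ratio (default 0.1).
#' @return \code{BinnedTrack} of smoothed log2 ratios (NA at missing bins
#'   and at chromosome edges shorter than half the smoothing span).
#' @export
timexLog2 <- function(sTrack, g0Track, smooth = 500L, pseudocount = 0.1) {
  checkSameBinning(sTrack, g0Track)
  bs <- sTrack@binSize
  nSmooth <- max(1L, round(smooth / bs))
  if (nSmooth %% 2L == 0L) nSmooth <- nSmooth + 1L
  vals <- lapply(names(sTrack@values), function(chr) {
    s <- sTrack@values[[chr]]; g <- g0Track@values[[chr]]
    lr <- log2((s + pseudocount) / (g + pseudocount))
    if (nSmooth > 1L) {
      frollmean(lr, nSmooth, align = "center", na.rm = TRUE, hasNA = TRUE)
    } else lr
  })
  names(vals) <- names(sTrack@values)
  BinnedTrack(vals, bs, sTrack@seqlengths, "raw")
}

asDnaCharVector <- function(x) {
  s <- toupper(as.character(x))
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' GC skew along a sequence
#'
#' (G - C) / (G + C) in sliding windows (default 200 bp, step 1 bp), the
#' value assigned to the window center. Windows without any G or C are
#' missing. Reverse-complementing the sequence negates the (reversed)
#' profile.
#'
#' @param sequence a \code{DNAString} or single character string (uppercase
#'   A/C/G/T/N).
#' @param window window size in bp.
#' @param step step in bp.
#' @return \code{data.frame} with 0-based \code{center} positions
#'   (\code{start + floor(window/2)} of each window) and \code{skew} values;
#'   zero rows when the window exceeds the sequence.
#' @export
gcSkew <- function(sequence, window = 200L, step = 1L) {
  ch <- asDnaCharVector(sequence)
  L <- length(ch)
  if (window > L) {
    return(data.frame(center = integer(0), skew = numeric(0)))
  }
  g <- cumsum(c(0L, ch == "G"))
  c_ <- cumsum(c(0L, ch == "C"))
  starts <- seq(1L, L - window + 1L, by = step)
  G <- g[starts + window] - g[starts]
  C <- c_[starts + window] - c_[starts]
  skew <- ifelse(G + C == 0, NA_real_, (G - C) / (G + C))
  data.frame(center = starts - 1L + window %/% 2L, skew = skew)
}

#' GC content along a sequence
#'
#' (G + C) / (A + C + G + T) in sliding windows; N bases are excluded from
#' the denominator and an all-N window is missing.
#'
#' @inheritParams gcSkew
#' @return \code{data.frame} with 0-based \code{center} and \code{gc} in
#'   [0, 1].
#' @export
gcPercent <- function(sequence, window = 200L, step = 1L) {
  ch <- asDnaCharVector(sequence)
  L <- length(ch)
  if (window > L) {
    return(data.frame(center = integer(0), gc = numeric(0)))
  }
  gc <- cumsum(c(0L, ch %in% c("G", "C")))
  acgt <- cumsum(c(0L, ch %in% c("A", "C", "G", "T")))
  starts <- seq(1L, L - window + 1L, by = step)
  GC <- gc[starts + window] - gc[starts]
  D <- acgt[starts + window] - acgt[starts]
  data.frame(center = starts - 1L + window %/% 2L,
             gc = ifelse(D == 0, NA_real_, GC / D))
}

#' G4Hunter per-base scores
#'
#' A G inside a maximal run of L consecutive Gs scores +min(L, 4); a C
#' inside a maximal C-run scores -min(L, 4); A/T/N score 0. Complementing
#' the sequence negates the scores.
#'
#' @param sequence a \code{DNAString} or single character string.
#' @return numeric vector of per-base scores in [-4, 4].
#' @export
g4BaseScores <- function(sequence) {
  ch <- asDnaCharVector(sequence)
  r <- rle(ch)
  runScore <- ifelse(r$values == "G", pmin(r$lengths, 4L),
              ifelse(r$values == "C", -pmin(r$lengths, 4L), 0L))
  rep(runScore, r$lengths)
}

#' G4Hunter windowed propensity score
#'
#' Arithmetic mean of the per-base G4Hunter scores over every
#' \code{window}-length substring. Scores are bounded in [-4, 4]; positive
#' values indicate G-rich (forward-strand) G4 propensity, negative C-rich.
#'
#' @inheritParams g4BaseScores
#' @param window window length in nt (default 25, the published tool's
#'   \code{-w} default used here).
#' @return numeric vector of window mean scores, one per window start
#'   (length \code{nchar - window + 1}).
#' @export
g4hunterScore <- function(sequence, window = 25L) {
  if (window < 1L) stop("window must be >= 1")
  base <- g4BaseScores(sequence)
  L <- length(base)
  if (window > L) return(numeric(0))
  cs <- cumsum(c(0, base))
  starts <- seq_len(L - window + 1L)
  (cs[starts + window] - cs[starts]) / window
}

#' Predict G4-forming hits in regions
#'
#' Scans each region's forward-strand reference sequence with the windowed
#' G4Hunter score and calls a hit wherever |score| >= threshold. Qualifying
#' window spans are merged into maximal non-overlapping hits whose score is
#' the extremal window mean; the sign of the score implies the strand
#' (positive = G-run on the forward strand). With \code{rawCount = TRUE}
#' the per-region count is the number of qualifying windows without
#' merging.
#'
#' @param regions \code{GRanges} (the characterization uses 400 bp windows
#'   over loci).
#' @param genome \code{GenomeModel} with sequence.
#' @param window G4Hunter window (nt).
#' @param threshold absolute score threshold (default 1.4, the published
#'   tool's \code{-s} flag value).
#' @param rawCount count qualifying windows instead of merged hits.
#' @return list with \code{hits} (\code{GRanges} of merged hits with
#'   \code{score} and strand) and \code{summary} (\code{data.frame} with
#'   per-region \code{nHits} and \code{density} = hits per bp).
#' @export
findG4 <- function(regions, genome, window = 25L, threshold = 1.4,
                   rawCount = FALSE) {
  stopifnot(is(genome, "GenomeModel"))
  refRegions <- granges(regions)
  strand(refRegions) <- "*"   # scan the reference strand; sign carries strand
  seqs <- genomeSequence(genome, refRegions)
  acc <- list(chrom = character(0), start = integer(0), end = integer(0),
              score = numeric(0))
  nHits <- integer(length(regions))
  for (i in seq_along(regions)) {
    sc <- g4hunterScore(seqs[[i]], window)
    qual <- which(abs(sc) >= threshold)
    if (!length(qual)) next
    if (rawCount) {
      nHits[i] <- length(qual)
      next
    }
    winStart <- start(refRegions)[i] + qual - 1L
    spans <- IRanges::reduce(IRanges(start = winStart, width = window))
    hitScore <- vapply(seq_along(spans), function(j) {
      inSpan <- winStart >= start(spans)[j] & winStart <= end(spans)[j]
      sc[qual[inSpan]][which.max(abs(sc[qual[inSpan]]))]
    }, numeric(1))
    nHits[i] <- length(spans)
    acc$chrom <- c(acc$chrom, rep(as.character(seqnames(refRegions)[i]), length(spans)))
    acc$start <- c(acc$start, start(spans))
    acc$end <- c(acc$end, end(spans))
    acc$score <- c(acc$score, hitScore)
  }
  hits <- if (length(acc$start)) {
    GRanges(acc$chrom, IRanges(acc$start, acc$end),
            strand = ifelse(acc$score > 0, "+", "-"), score = acc$score)
  } else GRanges()
  list(hits = hits,
       summary = data.frame(nHits = nHits,
                            density = nHits / width(regions)))
}
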