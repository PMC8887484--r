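#' Classify TRI TSSs by transcription orientation
#'
#' For each focal TSS: (1) divergent_pair when an opposite-strand annotated
#' TSS lies within \code{radius} on the focal TSS's upstream side and both
#' TSSs intersect transcription signal on their own strands; (2)
#' convergent_pair when the opposite-strand TSS lies within \code{radius}
#' downstream, same signal requirement; (3) single_bidirectional when no
#' other annotated TSS lies within \code{radius} but signal intersects both
#' strands at the locus; (4) unclassified otherwise. Upstream/downstream
#' are relative to the focal TSS's own strand, distances are TSS-to-TSS,
#' and divergent is evaluated before convergent when both qualify (all
#' qualifying labels are retained in the evidence). Signal intersection
#' means >= 1 bp overlap between the TSS +/- signalHalf window and a
#' strand-matched peak.
#'
#' @param tritss \code{GRanges} of focal TSS positions (stranded, width 1;
#'   a \code{geneId} column is carried through if present).
#' @param tss \code{GRanges} of all annotated TSS positions (stranded).
#' @param plusPeaks,minusPeaks strand-specific transcription peak sets.
#' @param radius partner search radius in bp (default 3000).
#' @param signalHalf half-width of the signal window around a TSS (bp).
#' @return \code{data.frame} with one row per focal TSS: \code{class},
#'   \code{partner} (partner TSS index in \code{tss} or NA),
#'   \code{evidence}.
#' @export
classifyOrientation <- function(tritss, tss, plusPeaks, minusPeaks,
                                radius = 3000L, signalHalf = 500L) {
  if (any(!as.character(strand(tritss)) %in% c("+", "-"))) {
    stop("focal TSSs must be stranded")
  }
  tssPos <- anchorPositions(tss)
  tssStrand <- as.character(strand(tss))
  tssChrom <- as.character(seqnames(tss))
  focPos <- anchorPositions(tritss)
  focStrand <- as.character(strand(tritss))
  focChrom <- as.character(seqnames(tritss))
  focId <- if (!is.null(mcols(tritss)$geneId)) mcols(tritss)$geneId else
    as.character(seq_along(tritss))

  hasSignal <- function(chrom, pos, strandChar) {
    win <- GRanges(chrom, IRanges(max(1L, pos - signalHalf), pos + signalHalf))
    pk <- if (strandChar == "+") plusPeaks else minusPeaks
    length(pk) > 0 && overlapsAny(win, pk, ignore.strand = TRUE)
  }

  out <- data.frame(tritss = focId, class = "unclassified",
                    partner = NA_character_, evidence = "",
                    stringsAsFactors = FALSE)
  for (i in seq_along(tritss)) {
    p <- focPos[i]; sgn <- if (focStrand[i] == "+") 1L else -1L
    same <- tssChrom == focChrom[i]
    d <- (tssPos - p) * sgn            # >0 downstream of focal, <0 upstream
    near <- same & abs(d) <= radius & !(tssPos == p & tssStrand == focStrand[i])
    nearOpp <- near & tssStrand != focStrand[i]
    focalSig <- hasSignal(focChrom[i], p, focStrand[i])
    labels <- character(0)
    upPartner <- which(nearOpp & d < 0)
    downPartner <- which(nearOpp & d > 0)
    partnerOk <- function(j) hasSignal(tssChrom[j], tssPos[j], tssStrand[j])
    upOk <- upPartner[vapply(upPartner, partnerOk, logical(1))]
    downOk <- downPartner[vapply(downPartner, partnerOk, logical(1))]
    if (focalSig && length(upOk)) labels <- c(labels, "divergent_pair")
    if (focalSig && length(downOk)) labels <- c(labels, "convergent_pair")
    if (length(labels)) {
      out$class[i] <- labels[1L]   # divergent takes precedence
      chosen <- if (labels[1L] == "divergent_pair") {
        upOk[which.min(abs(d[upOk]))]
      } else downOk[which.min(abs(d[downOk]))]
      out$partner[i] <- if (!is.null(mcols(tss)$geneId))
        mcols(tss)$geneId[chosen] else as.character(chosen)
      out$evidence[i] <- paste(labels, collapse = ",")
    } else if (!any(near)) {
      plusSig <- hasSignal(focChrom[i], p, "+")
      minusSig <- hasSignal(focChrom[i], p, "-")
      if (plusSig && minusSig) {
        out$class[i] <- "single_bidirectional"
        out$evidence[i] <- "signal:+,-"
      }
    }
  }
  out
}

#' Fraction of TRI loci overlapping TSS windows
#'
#' Overlap is judged against TSS +/- window/2 intervals; the summary
#' reports loci overlapping at least one TSS, total loci, and the fraction.
#'
#' @param triLoci \code{GRanges}.
#' @param tss \code{GRanges} of TSS positions.
#' @param window total TSS window width (bp, default 1000).
#' @return list with \code{overlapping}, \code{total}, \code{fraction}
#'   (NA with a warning when there are no loci).
#' @export
tssOverlapSummary <- function(triLoci, tss, window = 1000L) {
  if (!length(triLoci)) {
    warning("empty locus list: overlap fraction undefined")
    return(list(overlapping = 0L, total = 0L, fraction = NA_real_))
  }
  if (!length(tss)) {
    return(list(overlapping = 0L, total = length(triLoci), fraction = 0))
  }
  pos <- anchorPositions(tss)
  half <- window %/% 2L
  tssWin <- GRanges(seqnames(tss), IRanges(pmax(1L, pos - half), pos + half))
  hit <- overlapsAny(granges(triLoci), tssWin, ignore.strand = TRUE)
  list(overlapping = sum(hit), total = length(triLoci),
       fraction = mean(hit))
}
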