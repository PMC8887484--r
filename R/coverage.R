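#' Construct a BinnedTrack
#'
#' @param values named list of per-chromosome numeric vectors (NA = no data).
#' @param binSize bin width in bp.
#' @param seqlengths named chromosome lengths (defaults to
#'   \code{length(values[[chr]]) * binSize}).
#' @param normalization \code{"raw"} or \code{"RPM"}.
#' @return A \code{\linkS4class{BinnedTrack}}.
#' @export
BinnedTrack <- function(values, binSize, seqlengths = NULL, normalization = "raw") {
  if (is.null(seqlengths)) {
    seqlengths <- vapply(values, function(v) length(v) * as.double(binSize), numeric(1))
  }
  new("BinnedTrack", binSize = as.integer(binSize), values = values,
      normalization = normalization, seqlengths = seqlengths)
}

#' Bin size of a track
#' @param x a \code{BinnedTrack}
#' @export
binSize <- function(x) {
  stopifnot(is(x, "BinnedTrack"))
  x@binSize
}

#' Per-chromosome values of a track
#' @param x a \code{BinnedTrack}
#' @param chrom optional single chromosome name.
#' @return the named list of vectors, or one vector when \code{chrom} given.
#' @export
trackValues <- function(x, chrom = NULL) {
  stopifnot(is(x, "BinnedTrack"))
  if (is.null(chrom)) x@values else x@values[[chrom]]
}

setMethod("show", "BinnedTrack", function(object) {
  nbin <- sum(vapply(object@values, length, integer(1)))
  cat("BinnedTrack:", length(object@values), "chromosome(s),",
      format(nbin, big.mark = ","), "bins of", object@binSize, "bp,",
      object@normalization, "\n")
})

#' Binned fragment coverage of a FragmentSet
#'
#' Counts, per fixed-size bin, the fragments overlapping the bin by at least
#' 1 bp. With \code{normalization = "RPM"} values are scaled by
#' \code{1e6 / librarySize}.
#'
#' @param x a \code{FragmentSet} or \code{GRanges} of fragments.
#' @param genome a \code{GenomeModel}.
#' @param binSize bin width in bp.
#' @param normalization \code{"raw"} or \code{"RPM"}.
#' @return A \code{\linkS4class{BinnedTrack}}.
#' @export
fragmentCoverage <- function(x, genome, binSize = 100L, normalization = c("raw", "RPM")) {
  normalization <- match.arg(normalization)
  frags <- if (is(x, "FragmentSet")) fragments(x) else x
  lib <- length(frags)
  sl <- seqlengths(genome)
  bins <- genomeBins(genome, binSize)
  counts <- countOverlaps(bins, frags, ignore.strand = TRUE)
  scale <- if (normalization == "RPM") 1e6 / lib else 1
  vals <- lapply(names(sl), function(chr) {
    as.numeric(counts[as.character(seqnames(bins)) == chr]) * scale
  })
  names(vals) <- names(sl)
  BinnedTrack(vals, binSize, sl, normalization)
}

#' Fixed-size bins tiling a genome
#'
#' @param genome a \code{GenomeModel}.
#' @param binSize bin width in bp; the last bin of each chromosome may be
#'   shorter.
#' @return \code{GRanges} of bins ordered by (chrom, start).
#' @export
genomeBins <- function(genome, binSize) {
  sl <- seqlengths(genome)
  starts <- lapply(names(sl), function(chr) seq(1L, sl[[chr]], by = binSize))
  chrom <- rep(names(sl), lengths(starts))
  starts <- unlist(starts, use.names = FALSE)
  GRanges(factor(chrom, levels = names(sl)),
          IRanges(start = starts,
                  end = pmin(starts + binSize - 1L, sl[chrom])),
          seqinfo = seqinfo(genome))
}

#' Convert a BinnedTrack to scored intervals
#'
#' Bins with missing values are dropped; the result is bedGraph-ready.
#'
#' @param x a \code{BinnedTrack}.
#' @return \code{GRanges} with a \code{score} column.
#' @export
trackToGRanges <- function(x) {
  stopifnot(is(x, "BinnedTrack"))
  bs <- x@binSize
  chroms <- names(x@values)
  keep <- lapply(chroms, function(chr) which(!is.na(x@values[[chr]])))
  chrom <- rep(chroms, lengths(keep))
  idx <- unlist(keep, use.names = FALSE)
  if (!length(idx)) return(GRanges())
  starts <- (idx - 1L) * bs + 1L
  vals <- unlist(lapply(chroms, function(chr)
    x@values[[chr]][!is.na(x@values[[chr]])]), use.names = FALSE)
  GRanges(factor(chrom, levels = chroms),
          IRanges(start = starts, end = pmin(starts + bs - 1L, x@seqlengths[chrom])),
          score = vals)
}

#' Build a BinnedTrack from scored intervals on a fixed grid
#'
#' Intervals must align to the bin grid (as bedGraph written from a binned
#' track does); each covered bin takes the interval's score, uncovered bins
#' are missing.
#'
#' @param gr scored \code{GRanges}.
#' @param genome a \code{GenomeModel}.
#' @param binSize bin width in bp.
#' @param normalization normalization tag to record.
#' @return A \code{\linkS4class{BinnedTrack}}.
#' @export
trackFromGRanges <- function(gr, genome, binSize, normalization = "raw") {
  sl <- seqlengths(genome)
  vals <- lapply(names(sl), function(chr) rep(NA_real_, ceiling(sl[[chr]] / binSize)))
  names(vals) <- names(sl)
  chr <- as.character(seqnames(gr))
  from <- (start(gr) - 1L) %/% binSize + 1L
  to <- (end(gr) - 1L) %/% binSize + 1L
  for (i in seq_along(gr)) {
    vals[[chr[i]]][from[i]:to[i]] <- score(gr)[i]
  }
  BinnedTrack(vals, binSize, sl, normalization)
}

#' Mask blacklist bins of a track
#'
#' Bins overlapping the model's blacklist are set to missing.
#'
#' @param x a \code{BinnedTrack}.
#' @param genome a \code{GenomeModel} with a blacklist.
#' @return the masked \code{BinnedTrack}.
#' @export
maskBlacklist <- function(x, genome) {
  bl <- blacklist(genome)
  if (!length(bl)) return(x)
  bs <- x@binSize
  vals <- x@values
  for (i in seq_along(bl)) {
    chr <- as.character(seqnames(bl)[i])
    if (!chr %in% names(vals)) next
    from <- (start(bl)[i] - 1L) %/% bs + 1L
    to <- min((end(bl)[i] - 1L) %/% bs + 1L, length(vals[[chr]]))
    vals[[chr]][from:to] <- NA_real_
  }
  BinnedTrack(vals, bs, x@seqlengths, x@normalization)
}
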