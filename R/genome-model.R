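#' Construct a GenomeModel
#'
#' @param seqlengths named numeric vector of chromosome lengths, or a
#'   \code{Seqinfo} object.
#' @param sequences optional \code{DNAStringSet} named by chromosome.
#' @param blacklist optional \code{GRanges} of intervals excluded from
#'   profile and statistical aggregation.
#'
#' @return A \code{\linkS4class{GenomeModel}}.
#'
#' @examples
#' gm <- GenomeModel(c(chr1 = 1e6, chr2 = 5e5))
#' seqlengths(gm)
#'
#' @export
GenomeModel <- function(seqlengths, sequences = NULL, blacklist = NULL) {
  si <- if (is(seqlengths, "Seqinfo")) seqlengths
  else Seqinfo(seqnames = names(seqlengths), seqlengths = as.integer(seqlengths))
  if (is.null(blacklist)) blacklist <- GRanges()
  new("GenomeModel", seqinfo = si, sequences = sequences, blacklist = blacklist)
}

#' @describeIn GenomeModel-class chromosome lengths
#' @param x a \code{GenomeModel}
#' @export
setMethod("seqlengths", "GenomeModel", function(x) GenomeInfoDb::seqlengths(x@seqinfo))

#' @describeIn GenomeModel-class chromosome names
#' @export
setMethod("seqlevels", "GenomeModel", function(x) GenomeInfoDb::seqlevels(x@seqinfo))

#' @describeIn GenomeModel-class the \code{Seqinfo}
#' @export
setMethod("seqinfo", "GenomeModel", function(x) x@seqinfo)

#' Blacklist intervals of a GenomeModel
#' @param x a \code{GenomeModel}
#' @return \code{GRanges}
#' @export
blacklist <- function(x) {
  stopifnot(is(x, "GenomeModel"))
  x@blacklist
}

#' Does the model carry sequence?
#' @param x a \code{GenomeModel}
#' @return logical
#' @export
hasSequence <- function(x) {
  stopifnot(is(x, "GenomeModel"))
  !is.null(x@sequences)
}

#' Extract uppercase sequence for intervals
#'
#' Returns the uppercase A/C/G/T/N sequence of each interval; minus-strand
#' intervals are reverse-complemented.
#'
#' @param genome a \code{GenomeModel} with sequences.
#' @param gr \code{GRanges} of intervals to extract.
#' @return \code{DNAStringSet}, one element per interval, each of the
#'   interval's width.
#' @export
genomeSequence <- function(genome, gr) {
  stopifnot(is(genome, "GenomeModel"))
  if (!hasSequence(genome)) stop("GenomeModel carries no sequence")
  validateIntervals(gr, genome)
  seqs <- DNAStringSet(vapply(seq_along(gr), function(i) {
    chr <- as.character(seqnames(gr)[i])
    as.character(subseq(genome@sequences[[chr]], start(gr)[i], end(gr)[i]))
  }, character(1)))
  neg <- as.character(strand(gr)) == "-"
  if (any(neg)) seqs[neg] <- reverseComplement(seqs[neg])
  seqs
}

setMethod("show", "GenomeModel", function(object) {
  sl <- seqlengths(object)
  cat("GenomeModel:", length(sl), "chromosome(s),",
      format(sum(as.double(sl)), big.mark = ","), "bp total\n")
  cat("  sequence:", if (hasSequence(object)) "attached" else "none",
      "| blacklist:", length(object@blacklist), "interval(s)\n")
})

#' Validate intervals against a GenomeModel
#'
#' Checks that every interval lies on a known chromosome within its bounds.
#' Called by every operation that pairs intervals with a genome.
#'
#' @param gr \code{GRanges}
#' @param genome a \code{GenomeModel} (or \code{NULL} to skip bounds checks).
#' @return invisibly \code{TRUE}; stops with a validation error otherwise.
#' @export
validateIntervals <- function(gr, genome = NULL) {
  if (any(start(gr) < 1L)) stop("interval start below chromosome start")
  if (is.null(genome)) return(invisible(TRUE))
  sl <- seqlengths(genome)
  chr <- as.character(seqnames(gr))
  bad <- !chr %in% names(sl)
  if (any(bad)) stop("intervals on unknown chromosome(s): ",
                     paste(unique(chr[bad]), collapse = ", "))
  over <- end(gr) > sl[chr]
  if (any(over)) stop(sum(over), " interval(s) exceed chromosome length")
  invisible(TRUE)
}

#' Construct a FragmentSet
#'
#' @param fragments \code{GRanges} of fragment intervals.
#' @param sampleId sample label.
#' @param condition \code{"BrdU+"} or \code{"BrdU-"}.
#' @param replicate replicate index.
#' @return A \code{\linkS4class{FragmentSet}}.
#' @export
FragmentSet <- function(fragments, sampleId, condition, replicate = 1L) {
  new("FragmentSet", fragments = fragments, sampleId = as.character(sampleId),
      condition = condition, replicate = as.integer(replicate))
}

#' Fragments of a FragmentSet
#' @param x a \code{FragmentSet}
#' @return \code{GRanges}
#' @export
fragments <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@fragments
}

#' Library size (number of fragments) of a FragmentSet
#' @param x a \code{FragmentSet}
#' @return integer
#' @export
librarySize <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  length(x@fragments)
}

#' Sample identifier
#' @param x a \code{FragmentSet}
#' @export
sampleId <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@sampleId
}

#' Condition tag ("BrdU+" or "BrdU-")
#' @param x a \code{FragmentSet}
#' @export
condition <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@condition
}

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet", object@sampleId, sprintf("(%s, replicate %d):", object@condition,
      object@replicate), format(librarySize(object), big.mark = ","), "fragments\n")
})
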