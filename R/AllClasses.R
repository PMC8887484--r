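#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- queryHits subjectHits
#' @importFrom GenomicRanges GRanges granges countOverlaps findOverlaps
#'   pintersect reduce seqnames strand strand<- start end width start<- end<-
#'   resize shift score score<- mcols mcols<- sort tile
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo
#' @importFrom Biostrings DNAStringSet DNAString subseq reverseComplement
#'   letterFrequency
#' @importFrom stats median sd runif rnorm rpois rgamma rmultinom rbinom
#'   pbinom ppois lbeta p.adjust phyper pnorm setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom data.table frollmean
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom GenomeInfoDb Seqinfo
NULL

setClassUnion("DNAStringSetOrNULL", c("DNAStringSet", "NULL"))

#' GenomeModel: chromosome sizes, optional sequence, optional blacklist
#'
#' Container for the reference frame every other object is validated against:
#' an ordered set of chromosome names with lengths, optionally the genome
#' sequence itself (as a \code{DNAStringSet}), and optionally a blacklist of
#' intervals that are excluded from profile and statistical aggregation.
#'
#' @slot seqinfo \code{Seqinfo} with chromosome names and lengths.
#' @slot sequences \code{DNAStringSet} named by chromosome, or \code{NULL}.
#' @slot blacklist \code{GRanges} of excluded intervals (may be empty).
#'
#' @name GenomeModel-class
#' @rdname GenomeModel-class
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(
    seqinfo = "Seqinfo",
    sequences = "DNAStringSetOrNULL",
    blacklist = "GRanges"
  )
)

setValidity("GenomeModel", function(object) {
  msgs <- character()
  sl <- GenomeInfoDb::seqlengths(object@seqinfo)
  if (length(sl) == 0L) msgs <- c(msgs, "GenomeModel must name at least one chromosome")
  if (any(is.na(sl)) || any(sl <= 0L)) msgs <- c(msgs, "chromosome lengths must be positive")
  if (!is.null(object@sequences)) {
    if (!all(names(object@sequences) %in% names(sl))) {
      msgs <- c(msgs, "sequence names must match chromosome names")
    } else {
      w <- Biostrings::width(object@sequences)
      if (any(w != sl[names(object@sequences)])) {
        msgs <- c(msgs, "sequence lengths must equal chromosome lengths")
      }
    }
  }
  if (length(object@blacklist) > 0L) {
    bl <- object@blacklist
    on <- as.character(GenomicRanges::seqnames(bl)) %in% names(sl)
    if (!all(on)) msgs <- c(msgs, "blacklist intervals on unknown chromosomes")
    else if (any(GenomicRanges::end(bl) > sl[as.character(GenomicRanges::seqnames(bl))])) {
      msgs <- c(msgs, "blacklist intervals exceed chromosome lengths")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' FragmentSet: one sample's sequenced fragments
#'
#' Fragments (not reads) are the unit of the assay: each paired-end fragment
#' is a genomic interval. The library size of a sample is by definition the
#' number of fragments it contains.
#'
#' @slot fragments \code{GRanges} of fragment intervals.
#' @slot sampleId sample label.
#' @slot condition \code{"BrdU+"} (experimental) or \code{"BrdU-"} (control).
#' @slot replicate replicate index (1-based).
#'
#' @name FragmentSet-class
#' @rdname FragmentSet-class
#' @exportClass FragmentSet
setClass("FragmentSet",
  representation(
    fragments = "GRanges",
    sampleId = "character",
    condition = "character",
    replicate = "integer"
  )
)

setValidity("FragmentSet", function(object) {
  msgs <- character()
  if (length(object@sampleId) != 1L) msgs <- c(msgs, "sampleId must be a single string")
  if (!object@condition %in% c("BrdU+", "BrdU-")) {
    msgs <- c(msgs, "condition must be 'BrdU+' or 'BrdU-'")
  }
  if (length(object@replicate) != 1L || is.na(object@replicate) || object@replicate < 1L) {
    msgs <- c(msgs, "replicate must be a positive integer")
  }
  if (length(msgs)) msgs else TRUE
})

#' BinnedTrack: fixed-bin genome-wide signal
#'
#' Per-chromosome numeric vectors on a fixed bin grid. \code{NA} marks
#' zero-information bins (data gaps, blacklist) and is distinct from the
#' value 0, which is a measured signal level.
#'
#' @slot binSize bin width in bp.
#' @slot values named list of per-chromosome numeric vectors; element
#'   \code{i} covers bases \code{[(i-1)*binSize, i*binSize)} (0-based).
#' @slot normalization \code{"raw"} or \code{"RPM"}.
#' @slot seqlengths named integer vector of chromosome lengths.
#'
#' @name BinnedTrack-class
#' @rdname BinnedTrack-class
#' @exportClass BinnedTrack
setClass("BinnedTrack",
  representation(
    binSize = "integer",
    values = "list",
    normalization = "character",
    seqlengths = "numeric"
  )
)

setValidity("BinnedTrack", function(object) {
  msgs <- character()
  if (object@binSize < 1L) msgs <- c(msgs, "binSize must be >= 1")
  if (!object@normalization %in% c("raw", "RPM")) {
    msgs <- c(msgs, "normalization must be 'raw' or 'RPM'")
  }
  if (!identical(sort(names(object@values)), sort(names(object@seqlengths)))) {
    msgs <- c(msgs, "values and seqlengths must cover the same chromosomes")
  } else {
    for (chr in names(object@values)) {
      expected <- ceiling(object@seqlengths[[chr]] / object@binSize)
      if (length(object@values[[chr]]) != expected) {
        msgs <- c(msgs, sprintf(
          "chromosome %s: %d bins, expected ceil(%d / %d) = %d",
          chr, length(object@values[[chr]]), object@seqlengths[[chr]],
          object@binSize, expected))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ResamplingResult: observed statistic versus a resampling null
#'
#' Holds an observed statistic, its null draws, and the empirical p-value
#' P = (r + 1) / (n + 1), where r is the number of null draws at least as
#' extreme as the observed value and n the number of draws. Fold enrichment
#' is observed / mean(null) (NA when the null mean is zero).
#'
#' @slot observed observed statistic.
#' @slot null numeric vector of null draws.
#' @slot r number of draws at least as extreme as observed.
#' @slot n number of draws.
#' @slot pValue empirical p-value (r + 1)/(n + 1).
#' @slot fold observed / mean(null).
#' @slot direction \code{"greater"} or \code{"less"}.
#'
#' @name ResamplingResult-class
#' @rdname ResamplingResult-class
#' @exportClass ResamplingResult
setClass("ResamplingResult",
  representation(
    observed = "numeric",
    null = "numeric",
    r = "integer",
    n = "integer",
    pValue = "numeric",
    fold = "numeric",
    direction = "character"
  )
)

setValidity("ResamplingResult", function(object) {
  msgs <- character()
  if (object@n < 1L) msgs <- c(msgs, "n must be >= 1")
  if (length(object@null) != object@n) msgs <- c(msgs, "null must hold n draws")
  if (object@r < 0L || object@r > object@n) msgs <- c(msgs, "r must lie in [0, n]")
  expectP <- (object@r + 1) / (object@n + 1)
  if (abs(object@pValue - expectP) > 1e-12) {
    msgs <- c(msgs, "pValue must equal (r + 1)/(n + 1)")
  }
  if (!object@direction %in% c("greater", "less")) {
    msgs <- c(msgs, "direction must be 'greater' or 'less'")
  }
  if (length(msgs)) msgs else TRUE
})

#' ProfileMatrix: per-region binned signal around an anchor
#'
#' Rows are regions, columns are bins at fixed offsets relative to the anchor
#' (a point, or a scaled gene body with flanks). \code{NA} cells are missing
#' data and are excluded from aggregation.
#'
#' @slot values numeric matrix (regions x bins), possibly with NA.
#' @slot offsets numeric vector of bin start offsets relative to the anchor
#'   (bp for point anchors; for scaled-body matrices, flank bins carry bp
#'   offsets and body bins carry fractional indices).
#' @slot binSize bin width in bp (flank bins for scaled-body matrices).
#' @slot anchorMode \code{"point"} or \code{"scaled_body"}.
#'
#' @name ProfileMatrix-class
#' @rdname ProfileMatrix-class
#' @exportClass ProfileMatrix
setClass("ProfileMatrix",
  representation(
    values = "matrix",
    offsets = "numeric",
    binSize = "integer",
    anchorMode = "character"
  )
)

setValidity("ProfileMatrix", function(object) {
  msgs <- character()
  if (ncol(object@values) != length(object@offsets)) {
    msgs <- c(msgs, "offsets must label every column")
  }
  if (!object@anchorMode %in% c("point", "scaled_body")) {
    msgs <- c(msgs, "anchorMode must be 'point' or 'scaled_body'")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the synthetic TRIPn-Seq experiment
#'
#' Defines the study conditions the generator emulates: a small multi-
#' chromosome genome, annotated genes split into TRI-class, control-TSS-class
#' and inactive genes, replicate fragment libraries with negative-binomial
#' noise and planted BrdU+ enrichment at TRI loci, strand-specific
#' transcription peaks realizing the orientation classes, an origin-based
#' replication fork model, and per-class variant rates.
#'
#' @slot seed integer RNG seed; all generator output is a deterministic
#'   function of the config including this seed.
#' @slot nChrom number of chromosomes.
#' @slot chromLength length of each chromosome (bp).
#' @slot nTri,nCtss,nInactive gene counts per class.
#' @slot enrichmentFold BrdU+ / BrdU- expectation ratio at planted TRIs.
#' @slot nRepExp,nRepCtl replicate counts per condition.
#' @slot fragmentsPerReplicate fragments per library.
#' @slot fragLenRange fragment length range in bp (uniform).
#' @slot dispersion negative-binomial dispersion of per-bin fragment counts.
#' @slot orientationProps named proportions of TRI genes per orientation
#'   class (divergent_pair, convergent_pair, single_bidirectional,
#'   unclassified).
#' @slot originsPerChrom replication origins per chromosome.
#' @slot originEfficiency origin firing efficiency in (0, 1].
#' @slot variantRates named per-kb Poisson rates: sbs, insertion, deletion
#'   (background / control regions); TRI gene bodies use
#'   \code{deletionFoldTri} times the deletion rate.
#' @slot deletionFoldTri deletion-rate multiplier in TRI gene bodies.
#'
#' @name SimulationConfig-class
#' @rdname SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nChrom = "integer",
    chromLength = "integer",
    nTri = "integer",
    nCtss = "integer",
    nInactive = "integer",
    enrichmentFold = "numeric",
    nRepExp = "integer",
    nRepCtl = "integer",
    fragmentsPerReplicate = "integer",
    fragLenRange = "integer",
    dispersion = "numeric",
    orientationProps = "numeric",
    originsPerChrom = "integer",
    originEfficiency = "numeric",
    variantRates = "numeric",
    deletionFoldTri = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  pos <- c(
    nChrom = object@nChrom, chromLength = object@chromLength,
    nTri = object@nTri, nCtss = object@nCtss,
    nRepExp = object@nRepExp, nRepCtl = object@nRepCtl,
    fragmentsPerReplicate = object@fragmentsPerReplicate,
    originsPerChrom = object@originsPerChrom
  )
  if (any(pos < 1L)) msgs <- c(msgs, "counts must be positive")
  if (object@nInactive < 0L) msgs <- c(msgs, "nInactive must be >= 0")
  if (object@enrichmentFold < 1) msgs <- c(msgs, "enrichmentFold must be >= 1")
  if (object@dispersion < 0) msgs <- c(msgs, "dispersion must be >= 0")
  if (length(object@fragLenRange) != 2L || object@fragLenRange[1] > object@fragLenRange[2] ||
      object@fragLenRange[1] < 1L) {
    msgs <- c(msgs, "fragLenRange must be an increasing positive pair")
  }
  cls <- c("divergent_pair", "convergent_pair", "single_bidirectional", "unclassified")
  if (!identical(sort(names(object@orientationProps)), sort(cls)) ||
      abs(sum(object@orientationProps) - 1) > 1e-8 || any(object@orientationProps < 0)) {
    msgs <- c(msgs, "orientationProps must be non-negative proportions over the four classes summing to 1")
  }
  if (object@originEfficiency <= 0 || object@originEfficiency > 1) {
    msgs <- c(msgs, "originEfficiency must lie in (0, 1]")
  }
  if (!all(c("sbs", "insertion", "deletion") %in% names(object@variantRates)) ||
      any(object@variantRates < 0)) {
    msgs <- c(msgs, "variantRates must be non-negative and name sbs, insertion, deletion")
  }
  if (object@deletionFoldTri < 0) msgs <- c(msgs, "deletionFoldTri must be >= 0")
  # gene slots of 10 kb must fit
  nGenes <- object@nTri + object@nCtss + object@nInactive
  if (nGenes * 10000 > object@nChrom * as.double(object@chromLength)) {
    msgs <- c(msgs, "gene count too large for genome size (10 kb per gene slot required)")
  }
  if (length(msgs)) msgs else TRUE
})
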