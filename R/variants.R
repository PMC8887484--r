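#' Classify variants from their alleles
#'
#' |ref| = |alt| = 1 is an SBS; |alt| > |ref| with a shared anchor base is
#' an insertion; |ref| > |alt| a deletion; anything else (MNVs, complex
#' substitutions) is "other". Vectorized and total.
#'
#' @param ref,alt character vectors of alleles.
#' @return character vector in {sbs, insertion, deletion, other}.
#' @export
classifyVariant <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele")
  nr <- nchar(ref); na <- nchar(alt)
  out <- rep("other", length(ref))
  out[nr == 1L & na == 1L & ref != alt] <- "sbs"
  ins <- na > nr & substr(alt, 1L, nr) == ref
  out[ins] <- "insertion"
  out[nr > na] <- "deletion"
  out[ref == alt] <- "other"
  out
}

#' Read variants from a VCF file
#'
#' Minimal-field VCF (CHROM/POS/REF/ALT) read through \pkg{vcfR};
#' multi-allelic records are split into one record per alternate allele
#' before classification. With \code{deduplicate = TRUE} (the default,
#' matching how merged call sets are counted) identical
#' (chrom, pos, ref, alt) records are collapsed to one.
#'
#' @param path VCF path (plain text).
#' @param deduplicate drop duplicate records.
#' @return \code{data.frame} with \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{class}.
#' @export
readVariantsVcf <- function(path, deduplicate = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  df <- data.frame(chrom = fx[, "CHROM"], pos = as.integer(fx[, "POS"]),
                   ref = fx[, "REF"], alt = fx[, "ALT"], stringsAsFactors = FALSE)
  # split multi-allelic records
  alts <- strsplit(df$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  df <- data.frame(chrom = rep(df$chrom, n), pos = rep(df$pos, n),
                   ref = rep(df$ref, n), alt = unlist(alts),
                   stringsAsFactors = FALSE)
  if (deduplicate) {
    df <- df[!duplicated(df[, c("chrom", "pos", "ref", "alt")]), , drop = FALSE]
  }
  df$class <- classifyVariant(df$ref, df$alt)
  rownames(df) <- NULL
  df
}

#' Write variants as a minimal VCF
#'
#' Writes CHROM/POS/REF/ALT records with a VCFv4.2 header carrying contig
#' lines when a genome is supplied.
#'
#' @param variants \code{data.frame} with \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}.
#' @param path output path.
#' @param genome optional \code{GenomeModel} for contig header lines.
#' @return the path, invisibly.
#' @export
writeVariantsVcf <- function(variants, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(genome)) {
    sl <- seqlengths(genome)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(sl), sl), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(variants)) {
    ord <- order(variants$chrom, variants$pos)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       variants$chrom[ord], variants$pos[ord],
                       variants$ref[ord], variants$alt[ord]), con)
  }
  invisible(path)
}

#' Count variants within regions
#'
#' Regions are merged before counting so a variant shared by two
#' overlapping regions counts once. A variant counts in a region when its
#' (1-based) position lies inside the interval. In per-kb mode each region
#' is split into 1 kb windows and the mean per-window count is reported,
#' normalizing for region length.
#'
#' @param variants \code{data.frame} from \code{\link{readVariantsVcf}} or
#'   \code{\link{simulateVariants}}.
#' @param regions \code{GRanges}.
#' @param perKb report mean count per 1 kb window instead of totals.
#' @return list with \code{total} counts per class (named numeric, plus
#'   \code{all}), and \code{perRegion} \code{data.frame} of per-merged-region
#'   counts.
#' @export
countVariantsInRegions <- function(variants, regions, perKb = FALSE) {
  merged <- mergeIntervals(regions)
  vg <- GRanges(variants$chrom, IRanges(variants$pos, variants$pos))
  classes <- c("sbs", "insertion", "deletion", "other")
  ov <- findOverlaps(vg, merged, ignore.strand = TRUE)
  hitClass <- variants$class[queryHits(ov)]
  region <- subjectHits(ov)
  perRegion <- data.frame(region = seq_along(merged))
  for (cl in classes) {
    cnt <- integer(length(merged))
    tab <- table(region[hitClass == cl])
    cnt[as.integer(names(tab))] <- as.integer(tab)
    perRegion[[cl]] <- cnt
  }
  perRegion$all <- rowSums(perRegion[, classes])
  if (perKb) {
    nWin <- pmax(1L, ceiling(width(merged) / 1000))
    for (cl in c(classes, "all")) perRegion[[cl]] <- perRegion[[cl]] / nWin
  }
  totals <- vapply(c(classes, "all"), function(cl) {
    if (perKb) mean(perRegion[[cl]]) else sum(perRegion[[cl]])
  }, numeric(1))
  list(total = totals, perRegion = perRegion)
}

#' Region-level variant enrichment by control resampling
#'
#' The observed statistic is the per-class variant count (or per-kb rate)
#' over the query regions; each null draw samples |query| regions from the
#' control pool without replacement and recounts under the same merging
#' rule. Empirical P = (r + 1)/(n + 1) and fold = observed / mean(null),
#' per class.
#'
#' @param queryRegions \code{GRanges} (e.g. TRI TSS windows or gene bodies).
#' @param controlPool \code{GRanges} pool sampled for the null (e.g. cTSS
#'   windows).
#' @param variants variant \code{data.frame}.
#' @param nIter number of null draws (default 999).
#' @param seed integer RNG seed.
#' @param perKb compare per-kb rates (gene mode) instead of totals.
#' @param direction tail for the empirical P.
#' @return named list of \code{\linkS4class{ResamplingResult}} per class
#'   (sbs, insertion, deletion, all); classes with zero variants genome-wide
#'   yield NULL entries.
#' @export
variantEnrichment <- function(queryRegions, controlPool, variants,
                              nIter = 999L, seed = 1L, perKb = FALSE,
                              direction = c("greater", "less")) {
  direction <- match.arg(direction)
  nq <- length(queryRegions)
  if (nq > length(controlPool)) stop("query set larger than control pool")
  obs <- countVariantsInRegions(variants, queryRegions, perKb = perKb)$total
  draws <- withSeed(seed, {
    t(vapply(seq_len(nIter), function(i) {
      idx <- sample.int(length(controlPool), nq)
      countVariantsInRegions(variants, controlPool[idx], perKb = perKb)$total
    }, numeric(5)))
  })
  # a class with zero variants genome-wide yields observed 0 against an
  # all-zero null: P = 1 and fold NA (undefined), the flagged degenerate case
  out <- lapply(c(sbs = "sbs", insertion = "insertion",
                  deletion = "deletion", all = "all"),
                function(cl) empiricalPvalue(obs[[cl]], draws[, cl], direction))
  out
}
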