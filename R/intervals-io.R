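#' Read intervals from BED or bedGraph
#'
#' BED (3 or 6 column) and bedGraph (4 column) are read through
#' \pkg{rtracklayer}; file coordinates are 0-based half-open and become
#' 1-based closed \code{GRanges} internally. A lightweight pre-scan reports
#' malformed lines by line number before handing the file to the importer.
#'
#' @param path file path.
#' @param format \code{"BED"} or \code{"bedGraph"}.
#' @return \code{GRanges} in file order; bedGraph intervals carry a
#'   \code{score} column, BED6 intervals carry \code{name}, \code{score},
#'   and strand.
#' @export
readIntervals <- function(path, format = c("BED", "bedGraph")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  checkIntervalLines(path, format)
  gr <- rtracklayer::import(path, format = if (format == "BED") "bed" else "bedGraph")
  unname(gr)
}

# Pre-scan for field count and coordinate sanity so parse errors carry the
# offending line number (the importer's own errors do not).
checkIntervalLines <- function(path, format) {
  lines <- readLines(path)
  minFields <- if (format == "BED") 3L else 4L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track") ||
        startsWith(ln, "browser")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < minFields) {
      stop(sprintf("parse error at line %d of %s: expected >= %d tab-separated fields",
                   i, path, minFields))
    }
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("parse error at line %d of %s: non-numeric coordinates", i, path))
    }
    if (s >= e) {
      stop(sprintf("validation error at line %d of %s: start (%s) >= end (%s)",
                   i, path, f[2], f[3]))
    }
    if (format == "bedGraph" && is.na(suppressWarnings(as.numeric(f[4])))) {
      stop(sprintf("parse error at line %d of %s: non-numeric bedGraph value", i, path))
    }
  }
  invisible(TRUE)
}

#' Write intervals to BED, bedGraph, or a TSV report
#'
#' Round-trip property: \code{readIntervals(writeIntervals(x))} reproduces
#' coordinates, names and scores. bedGraph output requires a \code{score}
#' column.
#'
#' @param gr \code{GRanges} to write.
#' @param path output path.
#' @param format \code{"BED"}, \code{"bedGraph"}, or \code{"TSV"}.
#' @return the path, invisibly.
#' @export
writeIntervals <- function(gr, path, format = c("BED", "bedGraph", "TSV")) {
  format <- match.arg(format)
  if (format == "bedGraph") {
    if (length(gr) > 0 && (is.null(score(gr)) || anyNA(score(gr)))) {
      stop("bedGraph output requires a score on every interval")
    }
    rtracklayer::export(gr, path, format = "bedGraph")
  } else if (format == "BED") {
    rtracklayer::export(gr, path, format = "bed")
  } else {
    df <- data.frame(
      chrom = as.character(seqnames(gr)),
      start = start(gr) - 1L,
      end = end(gr),
      stringsAsFactors = FALSE
    )
    if (length(gr)) df <- cbind(df, as.data.frame(mcols(gr)))
    writeReportTable(df, path)
  }
  invisible(path)
}

#' Write a tab-separated report table
#'
#' Header line plus optional '#' comment lines; the standard tabular output
#' format of the pipeline.
#'
#' @param df data.frame.
#' @param path output path.
#' @param comments character vector written as leading '#' lines.
#' @return the path, invisibly.
#' @export
writeReportTable <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated report table written by writeReportTable
#' @param path file path.
#' @return data.frame.
#' @export
readReportTable <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
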