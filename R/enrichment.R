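#' Empirical resampling p-value
#'
#' P = (r + 1) / (n + 1), where r is the number of null draws at least as
#' extreme as the observed statistic (ties count as extreme, so P is never
#' zero) and n the number of draws.
#'
#' @param observed observed statistic.
#' @param nullDraws numeric vector of null draws.
#' @param direction \code{"greater"} (r = draws >= observed) or
#'   \code{"less"}.
#' @return A \code{\linkS4class{ResamplingResult}}.
#' @export
empiricalPvalue <- function(observed, nullDraws, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(nullDraws) < 1L) stop("null draw set must be non-empty")
  n <- length(nullDraws)
  r <- if (direction == "greater") sum(nullDraws >= observed) else sum(nullDraws <= observed)
  nullMean <- mean(nullDraws)
  new("ResamplingResult", observed = as.numeric(observed),
      null = as.numeric(nullDraws), r = as.integer(r), n = as.integer(n),
      pValue = (r + 1) / (n + 1),
      fold = if (nullMean > 0) observed / nullMean else NA_real_,
      direction = direction)
}

#' @describeIn ResamplingResult-class accessors
#' @param x a \code{ResamplingResult}
#' @export
pValue <- function(x) {
  stopifnot(is(x, "ResamplingResult"))
  x@pValue
}

#' Fold enrichment (observed over null mean) of a ResamplingResult
#'
#' @param x a \code{ResamplingResult}
#' @param central \code{"mean"} (default) or \code{"median"} of the null.
#' @export
foldEnrichment <- function(x, central = c("mean", "median")) {
  stopifnot(is(x, "ResamplingResult"))
  central <- match.arg(central)
  m <- if (central == "mean") mean(x@null) else median(x@null)
  if (m > 0) x@observed / m else NA_real_
}

#' Observed statistic of a ResamplingResult
#' @param x a \code{ResamplingResult}
#' @export
observedStat <- function(x) {
  stopifnot(is(x, "ResamplingResult"))
  x@observed
}

#' Null draws of a ResamplingResult
#' @param x a \code{ResamplingResult}
#' @export
nullDraws <- function(x) {
  stopifnot(is(x, "ResamplingResult"))
  x@null
}

setMethod("show", "ResamplingResult", function(object) {
  cat(sprintf("ResamplingResult: observed %.4g vs %d null draws (%s)\n",
              object@observed, object@n, object@direction))
  cat(sprintf("  null mean %.4g +/- sd %.4g | fold %.3g | empirical P = %.4g\n",
              mean(object@null), sd(object@null), object@fold, object@pValue))
})

#' Gene-list overlap against a resampling null
#'
#' Observed statistic is |query intersect target|. Each of \code{nIter} null
#' draws samples |query| genes from the universe without replacement and
#' counts the intersection with the target set; empirical P and fold follow
#' the resampling conventions (the characterization default is 999 draws).
#'
#' @param queryGenes character vector (subset of \code{universe}).
#' @param universe character vector of all eligible genes.
#' @param targetGenes character vector.
#' @param nIter number of null draws.
#' @param seed integer RNG seed.
#' @param direction tail for the empirical P.
#' @return A \code{\linkS4class{ResamplingResult}}.
#' @export
resampleGeneOverlap <- function(queryGenes, universe, targetGenes,
                                nIter = 999L, seed = 1L,
                                direction = c("greater", "less")) {
  direction <- match.arg(direction)
  queryGenes <- unique(queryGenes); universe <- unique(universe)
  targetGenes <- unique(targetGenes)
  if (!all(queryGenes %in% universe)) stop("query genes must lie in the universe")
  if (length(queryGenes) > length(universe)) stop("query larger than universe")
  if (nIter < 1L) stop("nIter must be >= 1")
  observed <- length(intersect(queryGenes, targetGenes))
  inTarget <- universe %in% targetGenes
  nq <- length(queryGenes)
  draws <- withSeed(seed, {
    vapply(seq_len(nIter), function(i) {
      sum(inTarget[sample.int(length(universe), nq)])
    }, numeric(1))
  })
  empiricalPvalue(observed, draws, direction)
}

#' Workspace-restricted interval overlap randomization test
#'
#' Tests the association between query segments and annotation segments
#' within a workspace (the genomic subset where placements are allowed).
#' The observed statistic is the overlap of the query with the annotations,
#' both clipped to the workspace. Each null sample re-places every query
#' segment, length preserved, uniformly at random within the flattened
#' workspace without splitting across workspace segments (placed segments
#' may overlap one another), and the statistic is recomputed.
#'
#' @param query,annotations,workspace \code{GRanges}.
#' @param statistic \code{"segment_count"} (query segments overlapping >= 1
#'   annotation) or \code{"bp"} (total overlapped base pairs).
#' @param nSamples number of null placements.
#' @param seed integer RNG seed.
#' @param direction tail for the empirical P.
#' @return A \code{\linkS4class{ResamplingResult}}.
#' @export
workspaceOverlapTest <- function(query, annotations, workspace,
                                 statistic = c("segment_count", "bp"),
                                 nSamples = 999L, seed = 1L,
                                 direction = c("greater", "less")) {
  statistic <- match.arg(statistic)
  direction <- match.arg(direction)
  ws <- mergeIntervals(workspace)
  # query segments keep their original lengths for placement; the statistic
  # itself is evaluated on workspace-clipped overlap
  qKeep <- granges(query)[suppressWarnings(
    overlapsAny(granges(query), ws, ignore.strand = TRUE))]
  if (!length(qKeep)) stop("query does not intersect the workspace")
  aClip <- clipToWorkspace(annotations, ws)
  # concatenated workspace coordinates
  wsWidth <- width(ws)
  wsOffset <- cumsum(c(0L, head(wsWidth, -1L)))  # concatenated start of each segment
  annC <- IRanges::reduce(mapToConcat(aClip, ws, wsOffset))
  qC <- mapToConcat(clipToWorkspace(qKeep, ws), ws, wsOffset)
  obs <- overlapStatConcat(qC, annC, statistic)
  qLen <- width(qKeep)
  tooLong <- qLen > max(wsWidth)
  if (any(tooLong)) {
    i <- which(tooLong)[1]
    stop("query segment ", as.character(seqnames(qKeep))[i], ":",
         start(qKeep)[i] - 1L, "-", end(qKeep)[i], " (", qLen[i],
         " bp) fits in no workspace segment")
  }
  # valid (non-splitting) placements per query length
  draws <- withSeed(seed, {
    placements <- lapply(qLen, function(len) {
      nValid <- pmax(0L, wsWidth - len + 1L)
      if (sum(nValid) == 0L) {
        stop("query segment of ", len, " bp fits in no workspace segment")
      }
      seg <- sample.int(length(ws), nSamples, replace = TRUE, prob = nValid)
      offs <- floor(runif(nSamples) * nValid[seg])  # 0-based within segment
      IRanges(start = wsOffset[seg] + offs + 1L, width = len)
    })
    starts <- do.call(cbind, lapply(placements, start))  # nSamples x nQuery
    vapply(seq_len(nSamples), function(s) {
      placed <- IRanges(start = starts[s, ], width = qLen)
      overlapStatConcat(placed, annC, statistic)
    }, numeric(1))
  })
  empiricalPvalue(obs, draws, direction)
}

clipToWorkspace <- function(gr, ws) {
  ov <- suppressWarnings(findOverlaps(granges(gr), ws, ignore.strand = TRUE))
  if (!length(ov)) return(GRanges())
  pintersect(granges(gr)[queryHits(ov)], ws[subjectHits(ov)], ignore.strand = TRUE)
}

# map workspace-clipped ranges into concatenated workspace coordinates
mapToConcat <- function(gr, ws, wsOffset) {
  ov <- suppressWarnings(findOverlaps(granges(gr), ws, ignore.strand = TRUE))
  pieces <- pintersect(granges(gr)[queryHits(ov)], ws[subjectHits(ov)],
                       ignore.strand = TRUE)
  segIdx <- subjectHits(ov)
  IRanges(start = wsOffset[segIdx] + (start(pieces) - start(ws)[segIdx]) + 1L,
          width = width(pieces))
}

overlapStatConcat <- function(q, ann, statistic) {
  if (statistic == "segment_count") {
    sum(IRanges::overlapsAny(q, ann))
  } else {
    ov <- IRanges::findOverlaps(q, ann)
    if (!length(ov)) return(0)
    sum(width(IRanges::pintersect(q[S4Vectors::queryHits(ov)],
                                  ann[S4Vectors::subjectHits(ov)])))
  }
}

#' Hypergeometric over-representation p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least \code{k} successes in a sample of \code{n} from a population of
#' \code{N} containing \code{K} successes. \code{lower = TRUE} gives the
#' depletion tail P(X <= k).
#'
#' @param k successes in the sample.
#' @param n sample size.
#' @param K successes in the population.
#' @param N population size.
#' @param lower sum the lower (depletion) tail instead.
#' @return p-value.
#' @export
hypergeometricEnrichment <- function(k, n, K, N, lower = FALSE) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop("inconsistent hypergeometric counts")
  }
  if (lower) phyper(k, K, N - K, n, lower.tail = TRUE)
  else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Rank-sum statistic with midranks for ties. For a combined sample size of
#' at most 16 the two-sided p-value is computed by enumerating all
#' C(nx + ny, nx) group labelings of the pooled values (valid under ties);
#' larger samples use the normal approximation with tie-corrected variance
#' and continuity correction.
#'
#' @param x,y numeric vectors.
#' @param exactLimit combined size at or below which enumeration is used.
#' @return list with \code{statistic} (rank sum of \code{x}), \code{p}
#'   (two-sided), and \code{method}.
#' @export
ranksumTest <- function(x, y, exactLimit = 16L) {
  nx <- length(x); ny <- length(y)
  if (nx < 1L || ny < 1L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  rk <- rank(pooled)            # midranks for ties
  W <- sum(rk[seq_len(nx)])
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = W, p = 1, method = "degenerate"))
  }
  if (nx + ny <= exactLimit) {
    combos <- utils::combn(nx + ny, nx)
    sums <- colSums(matrix(rk[combos], nrow = nx))
    eW <- nx * (nx + ny + 1) / 2
    eps <- 1e-9
    p <- mean(abs(sums - eW) >= abs(W - eW) - eps)
    list(statistic = W, p = p, method = "exact")
  } else {
    nTot <- nx + ny
    eW <- nx * (nTot + 1) / 2
    tieTab <- table(rk)
    tieCorr <- sum(tieTab^3 - tieTab) / (nTot * (nTot - 1))
    vW <- nx * ny / 12 * ((nTot + 1) - tieCorr)
    z <- (abs(W - eW) - 0.5) / sqrt(vW)
    list(statistic = W, p = min(1, 2 * pnorm(-max(z, 0))), method = "normal")
  }
}

# run expr under a fixed, named RNG without disturbing the caller's stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}
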