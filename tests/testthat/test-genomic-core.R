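test_that("BED and bedGraph parsing maps fields and flags malformed lines", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tpk1\t0\t+", bed)
  gr <- readIntervals(bed, "BED")
  expect_equal(as.character(seqnames(gr)), "chr1")
  expect_equal(start(gr), 1L)   # 0-based file start -> 1-based internal
  expect_equal(end(gr), 100L)
  expect_equal(mcols(gr)$name, "pk1")
  expect_equal(as.character(strand(gr)), "+")

  bg <- tempfile(fileext = ".bedGraph")
  writeLines("chr1\t0\t50\t2.5", bg)
  gb <- readIntervals(bg, "bedGraph")
  expect_equal(start(gb), 1L)
  expect_equal(end(gb), 50L)
  expect_equal(score(gb), 2.5)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t100\t50"), bad)
  expect_error(readIntervals(bad, "BED"), "line 2")

  short <- tempfile(fileext = ".bed")
  writeLines("chr1\t100", short)
  expect_error(readIntervals(short, "BED"), "line 1")
})

test_that("interval writing round-trips coordinates, names and scores", {
  gr <- GRanges(c("chr1", "chr1", "chr2"),
                IRanges(c(11, 201, 51), c(110, 300, 70)),
                strand = c("+", "-", "*"),
                name = c("a", "b", "c"), score = c(1, 2, 3))
  path <- tempfile(fileext = ".bed")
  writeIntervals(gr, path, "BED")
  back <- readIntervals(path, "BED")
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  expect_equal(mcols(back)$name, mcols(gr)$name)
  expect_equal(mcols(back)$score, mcols(gr)$score)
  expect_equal(as.character(strand(back)), as.character(strand(gr)))

  # empty set writes an empty file that reads back empty
  empty <- tempfile(fileext = ".bed")
  writeIntervals(GRanges(), empty, "BED")
  expect_length(readIntervals(empty, "BED"), 0)

  # bedGraph requires scores
  noScore <- GRanges("chr1", IRanges(1, 10))
  expect_error(writeIntervals(noScore, tempfile(), "bedGraph"), "score")

  bgPath <- tempfile(fileext = ".bedGraph")
  writeIntervals(GRanges("chr1", IRanges(c(1, 51), c(50, 80)), score = c(2.5, -1)),
                 bgPath, "bedGraph")
  bgBack <- readIntervals(bgPath, "bedGraph")
  expect_equal(score(bgBack), c(2.5, -1))
})

test_that("merge handles overlap, bookended touch, and disjoint intervals", {
  # file-space [10,20) + [15,30) -> [10,30): 1-based (11,20) + (16,30)
  m <- mergeIntervals(GRanges("chr1", IRanges(c(11, 16), c(20, 30))))
  expect_equal(c(start(m), end(m)), c(11, 30))
  # bookended [10,20) + [20,30) merge at gap 0
  m2 <- mergeIntervals(GRanges("chr1", IRanges(c(11, 21), c(20, 30))))
  expect_equal(c(start(m2), end(m2)), c(11, 30))
  # disjoint [10,20) + [25,30) unchanged
  m3 <- mergeIntervals(GRanges("chr1", IRanges(c(11, 26), c(20, 30))))
  expect_length(m3, 2)
  expect_error(mergeIntervals(m3, maxGap = -1), "maxGap")
})

test_that("merge equals the O(n^2) union oracle and is idempotent", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(20:200, 1)
    starts <- sample.int(5000, n, replace = TRUE)
    ends <- starts + sample.int(80, n, replace = TRUE)
    gap <- sample(c(0L, 5L, 50L), 1)
    gr <- GRanges("chrX", IRanges(starts, ends))
    got <- mergeIntervals(gr[sample(n)], maxGap = gap)  # order-independent
    oracle <- bruteMerge(starts, ends, maxGap = gap)
    expect_equal(start(got), oracle$starts)
    expect_equal(end(got), oracle$ends)
    again <- mergeIntervals(got, maxGap = gap)
    expect_identical(granges(again), granges(got))
  }
})

test_that("intersect counts match arithmetic examples and are bp-symmetric", {
  # [0,10) vs [5,15): 1 hit, 5 bp
  r <- intersectCount(GRanges("c", IRanges(1, 10)), GRanges("c", IRanges(6, 15)))
  expect_equal(r$hits, 1L)
  expect_equal(r$bp, 5L)
  r2 <- intersectCount(GRanges("c", IRanges(1, 10)), GRanges("c", IRanges(50, 60)))
  expect_equal(r2$hits, 0L); expect_equal(r2$bp, 0L)
  r3 <- intersectCount(GRanges("c", IRanges(1, 100)), GRanges("c", IRanges(41, 60)))
  expect_equal(r3$bp, 20L)

  set.seed(7)
  for (rep in 1:5) {
    n1 <- sample(5:60, 1); n2 <- sample(5:60, 1)
    s1 <- sample.int(2000, n1, TRUE); e1 <- s1 + sample.int(50, n1, TRUE)
    s2 <- sample.int(2000, n2, TRUE); e2 <- s2 + sample.int(50, n2, TRUE)
    a <- GRanges("c", IRanges(s1, e1)); b <- GRanges("c", IRanges(s2, e2))
    bpAB <- sum(intersectCount(a, b)$bp)
    bpBA <- sum(intersectCount(b, a)$bp)
    expect_equal(bpAB, bpBA)
    expect_equal(bpAB, brutePairBp(s1, e1, s2, e2))
  }
})

test_that("sliding window sets have the configured geometry and clip at edges", {
  gm <- GenomeModel(c(chr1 = 100000))
  # 0-based anchor 5000 -> 1-based 5001
  anchor <- GRanges("chr1", IRanges(5001, 5001))
  w <- makeWindows(anchor, 1000, 1000, windowLength = 1000, step = 100, genome = gm)
  expect_length(w, 11)
  expect_equal(start(w), seq(4001, 5001, by = 100))
  expect_equal(unique(width(w)), 1000L)
  # window length filling the whole span -> single window
  w1 <- makeWindows(anchor, 1000, 1000, windowLength = 2000, step = 100, genome = gm)
  expect_length(w1, 1)
  expect_equal(c(start(w1), end(w1)), c(4001, 6000))
  # anchor near chromosome start: leading windows dropped, not truncated
  nearStart <- GRanges("chr1", IRanges(401, 401))
  wEdge <- makeWindows(nearStart, 1000, 1000, windowLength = 1000, step = 100,
                       genome = gm)
  expect_true(all(start(wEdge) >= 1))
  expect_true(all(width(wEdge) == 1000))
  expect_lt(length(wEdge), 11)
  expect_error(makeWindows(GRanges("chr1", IRanges(200001, 200001)),
                           1000, 1000, genome = gm), "off chromosome")
  # minus-strand anchors mirror the construction
  minus <- GRanges("chr1", IRanges(5001, 5001), strand = "-")
  wm <- makeWindows(minus, 1000, 500, windowLength = 500, step = 250, genome = gm)
  wp <- makeWindows(GRanges("chr1", IRanges(5001, 5001), strand = "+"),
                    1000, 500, windowLength = 500, step = 250, genome = gm)
  expect_equal(sort(start(wm)), sort(5001 + 5001 - rev(end(wp))))
})

test_that("region summaries take the sub-window statistic then the mean", {
  track <- GRanges("chr1", IRanges(seq(1, 91, 10), seq(10, 100, 10)),
                   score = rep(3, 10))
  reg <- GRanges("chr1", IRanges(1, 100))
  expect_equal(mapSignalSummary(reg, track, 20), 3)
  # two sub-windows with medians 1 and 3 -> mean 2
  tr2 <- GRanges("chr1", IRanges(c(1, 11), c(10, 20)), score = c(1, 3))
  expect_equal(mapSignalSummary(GRanges("chr1", IRanges(1, 20)), tr2, 10), 2)
  # region entirely in a data gap is missing
  expect_true(is.na(mapSignalSummary(GRanges("chr1", IRanges(500, 600)), tr2, 50)))
})

test_that("RPM normalization preserves total signal", {
  gm <- GenomeModel(c(chr1 = 10000, chr2 = 8000))
  set.seed(3)
  frags <- GRanges(sample(c("chr1", "chr2"), 500, TRUE),
                   IRanges(sample.int(7000, 500, TRUE), width = 150))
  fs <- FragmentSet(frags, "s1", "BrdU+", 1)
  raw <- fragmentCoverage(fs, gm, binSize = 100, normalization = "raw")
  rpm <- fragmentCoverage(fs, gm, binSize = 100, normalization = "RPM")
  totRaw <- sum(unlist(trackValues(raw)))
  totRpm <- sum(unlist(trackValues(rpm)))
  expect_equal(totRpm * librarySize(fs) / 1e6, totRaw, tolerance = 1e-6)
})

test_that("interval validation and blacklist masking enforce the genome model", {
  gm <- GenomeModel(c(chr1 = 1000), blacklist = GRanges("chr1", IRanges(101, 200)))
  expect_error(validateIntervals(GRanges("chr9", IRanges(1, 10)), gm), "unknown")
  expect_error(validateIntervals(GRanges("chr1", IRanges(900, 2000)), gm), "exceed")
  expect_silent(validateIntervals(GRanges("chr1", IRanges(1, 1000)), gm))
  tr <- BinnedTrack(list(chr1 = rep(1, 10)), 100, c(chr1 = 1000))
  masked <- maskBlacklist(tr, gm)
  expect_true(all(is.na(trackValues(masked, "chr1")[2])))
  expect_equal(sum(is.na(trackValues(masked, "chr1"))), 1)
})

test_that("invalid container states are rejected by class validity", {
  expect_error(GenomeModel(c(chr1 = -5)), "negative|positive")
  expect_error(FragmentSet(GRanges(), "s", "BrdU?", 1), "condition")
  expect_error(BinnedTrack(list(chr1 = rep(0, 3)), 100, c(chr1 = 1000)),
               "expected")
})
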