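test_that("fragment counting follows the overlap and midpoint rules", {
  # fragment [100,400) 0-based = (101,400) 1-based vs windows [0,200),[200,500)
  frag <- FragmentSet(GRanges("chr1", IRanges(101, 400)), "s", "BrdU+", 1)
  win <- GRanges("chr1", IRanges(c(1, 201), c(200, 500)))
  cOv <- countFragments(frag, win, mode = "overlap")
  expect_equal(as.integer(cOv), c(1L, 1L))
  cMid <- countFragments(frag, win, mode = "midpoint")  # midpoint 250
  expect_equal(as.integer(cMid), c(0L, 1L))
  empty <- FragmentSet(GRanges(), "e", "BrdU-", 1)
  expect_equal(as.integer(countFragments(empty, win)), c(0L, 0L))
  expect_equal(attr(countFragments(list(frag, empty), win), "librarySizes"),
               c(1L, 0L))
})

test_that("counting equals an all-pairs brute-force overlap scan", {
  set.seed(55)
  n <- 3000
  starts <- sample.int(100000, n, replace = TRUE)
  frags <- GRanges("chr1", IRanges(starts, starts + sample(200:500, n, TRUE)))
  fs <- FragmentSet(frags, "s", "BrdU+", 1)
  win <- GRanges("chr1", IRanges(seq(1, 99001, 1000), width = 900))
  got <- as.integer(countFragments(fs, win))
  brute <- vapply(seq_along(win), function(i) {
    sum(start(frags) <= end(win)[i] & end(frags) >= start(win)[i])
  }, integer(1))
  expect_equal(got, brute)
})

test_that("one-sided pooled test matches exact binomial oracles", {
  # equal libraries, k = 10 of t = 20, rho = 0
  counts <- matrix(c(10L, 10L), nrow = 1)
  attr(counts, "librarySizes") <- c(1e6L, 1e6L)
  attr(counts, "conditions") <- c("BrdU+", "BrdU-")
  r <- differentialWindowTest(counts, rho = 0)
  expect_equal(r$p, sum(dbinom(10:20, 20, 0.5)), tolerance = 1e-12)
  expect_equal(r$p, 0.5881, tolerance = 1e-4)
  # all 20 in the experiment: p = 0.5^20
  c2 <- matrix(c(20L, 0L), nrow = 1)
  attr(c2, "librarySizes") <- c(1e6L, 1e6L)
  attr(c2, "conditions") <- c("BrdU+", "BrdU-")
  expect_equal(differentialWindowTest(c2, rho = 0)$p, 0.5^20, tolerance = 1e-12)
  # empty window: p = 1, log2FC = 0, flagged
  c3 <- matrix(c(0L, 0L), nrow = 1)
  attr(c3, "librarySizes") <- c(1e6L, 1e6L)
  attr(c3, "conditions") <- c("BrdU+", "BrdU-")
  r3 <- differentialWindowTest(c3, rho = 0)
  expect_equal(r3$p, 1)
  expect_equal(r3$log2FC, 0)
  expect_true(r3$flag)
  # beta-binomial tail reduces to the binomial at vanishing overdispersion
  r4 <- differentialWindowTest(counts, rho = 1e-6)
  expect_equal(r4$p, r$p, tolerance = 1e-4)
  # overdispersion widens the tail
  r5 <- differentialWindowTest(counts, rho = 0.1)
  expect_gt(r5$p, 0)
  expect_lt(abs(r5$p - 0.5), abs(r$p - 0.5) + 1)
})

test_that("beta-binomial tail is a valid decreasing tail in k", {
  counts <- matrix(cbind(0:30, 30:0), ncol = 2)
  attr(counts, "librarySizes") <- c(1e6L, 1e6L)
  attr(counts, "conditions") <- c("BrdU+", "BrdU-")
  p <- differentialWindowTest(counts, rho = 0.05)$p
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) <= 1e-12))  # more enrichment -> smaller p
  expect_equal(p[1], 1, tolerance = 1e-9)  # P(X >= 0) = 1
})

test_that("method-of-moments dispersion responds to replicate noise", {
  set.seed(77)
  n <- 2000
  lam <- 50
  mkCounts <- function(disp) {
    draw <- function() {
      if (disp == 0) rpois(n, lam) else
        rpois(n, lam * rgamma(n, 1 / disp, 1 / disp))
    }
    m <- cbind(draw(), draw(), draw(), draw(), draw(), draw())
    attr(m, "librarySizes") <- rep(1e6L, 6)
    attr(m, "conditions") <- rep(c("BrdU+", "BrdU-"), each = 3)
    m
  }
  rhoNull <- attr(differentialWindowTest(mkCounts(0)), "rho")
  rhoOver <- attr(differentialWindowTest(mkCounts(0.3)), "rho")
  expect_lt(rhoNull, 0.005)
  expect_gt(rhoOver, rhoNull + 0.01)
})

test_that("BH FDR equals the brute-force step-up definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(1), 1)
  expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
  set.seed(19)
  for (i in 1:60) {
    p <- runif(sample.int(500, 1))
    q <- bhFdr(p)
    expect_equal(q, bruteBH(p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("peak caller recovers a planted enriched region and no null peaks", {
  gm <- GenomeModel(c(chr1 = 2000000))
  set.seed(13)
  nBg <- 40000
  bgPos <- sample.int(1999500, nBg, replace = TRUE)
  bg <- GRanges("chr1", IRanges(bgPos, width = 300))
  # experiment: same background rate plus a 10x region over 1 kb
  exPos <- c(sample.int(1999500, nBg, replace = TRUE),
             sample(1000000:1000999, 200, replace = TRUE))
  ex <- GRanges("chr1", IRanges(exPos, width = 300))
  peaks <- callCandidatePeaks(ex, bg, gm)
  expect_equal(length(peaks), 1L)
  expect_lt(abs(start(peaks) - 1000000), 400)
  expect_lt(abs(end(peaks) - 1001300), 400)
  # exp == bg: no significant peaks expected
  nullPeaks <- callCandidatePeaks(bg, bg, gm)
  expect_lte(length(nullPeaks), 1L)
  # empty background falls back to the experiment-wide rate
  fb <- callCandidatePeaks(ex, NULL, gm)
  expect_true(is(fb, "GRanges"))
  expect_error(callCandidatePeaks(GRanges(), bg, gm), "empty")
})

test_that("TSS scan produces 11 independently corrected offset sets", {
  fx <- smallFixture()
  genes <- fx$gen$genes
  scan <- tssWindowScan(fx$frags, tssPoints(genes), fx$gen$genome)
  sets <- unique(mcols(scan)$setId)
  expect_length(sets, 11)
  expect_true(all(table(mcols(scan)$setId) > 0))
  # FDR is computed within each set: every set's minimum FDR >= its minimum p
  for (s in sets) {
    sub <- mcols(scan)[mcols(scan)$setId == s, ]
    expect_true(all(sub$fdr >= sub$p - 1e-12))
    expect_equal(sub$fdr, bhFdr(sub$p))
  }
  # planted TRI TSSs reach significance in at least one offset set
  sig <- scan[mcols(scan)$fdr <= 0.05]
  expect_true(all(overlapsAny(fx$gen$truth$triLoci, sig)))
})

test_that("combine/merge keeps the highest member FDR over disjoint loci", {
  # peak [100,600) FDR 0.01 + window [500,1500) FDR 0.04 -> [100,1500) FDR 0.04
  pk <- GRanges("chr1", IRanges(101, 600), fdr = 0.01, setId = "denovo")
  win <- GRanges("chr1", IRanges(501, 1500), fdr = 0.04, setId = "tss_k00")
  merged <- combineAndMerge(pk, win)
  expect_length(merged, 1)
  expect_equal(c(start(merged), end(merged)), c(101, 1500))
  expect_equal(mcols(merged)$fdr, 0.04)
  expect_equal(mcols(merged)$provenance, "denovo,tss_k00")
  # two disjoint members stay two loci
  two <- combineAndMerge(pk, GRanges("chr1", IRanges(5001, 6000),
                                     fdr = 0.02, setId = "tss_k01"))
  expect_length(two, 2)
  # FDR 0.06 member is excluded
  excl <- combineAndMerge(pk, GRanges("chr1", IRanges(501, 1500),
                                      fdr = 0.06, setId = "tss_k00"))
  expect_length(excl, 1)
  expect_equal(end(excl), 600)
  # output is disjoint, all FDR <= threshold, and a fixed point
  fx <- smallFixture()
  scan <- tssWindowScan(fx$frags, tssPoints(fx$gen$genes), fx$gen$genome)
  loci <- combineAndMerge(scan)
  expect_true(all(mcols(loci)$fdr <= 0.05))
  expect_true(all(width(GenomicRanges::gaps(loci)) > 0))
  expect_equal(length(GenomicRanges::reduce(loci)), length(loci))
  again <- combineAndMerge(loci[, c("fdr")] |> (\(g) {
    mcols(g)$setId <- "loci"; g })())
  expect_identical(granges(again), granges(loci))
})

test_that("gene association uses the 1.5 kb center rule", {
  # locus center 10000 (0-based) = 10001 (1-based); gene TSSs at 9000 (+)
  # and 10800 (-) associate, 11600 does not
  locus <- GRanges("chr1", IRanges(9501, 10500), fdr = 0.01,
                   setId = "denovo")
  genes <- GRanges("chr1",
                   IRanges(c(9001, 6801, 11601), c(12000, 10801, 14000)),
                   strand = c("+", "-", "+"),
                   geneId = c("gA", "gB", "gC"))
  out <- assignGenes(locus, genes)
  expect_equal(out$genes, "gA,gB")
  far <- assignGenes(GRanges("chr1", IRanges(20001, 21000), fdr = 0.01,
                             setId = "x"), genes)
  expect_equal(far$genes, "")
})

test_that("discovery recovers planted loci and genes on the fixture", {
  fx <- smallFixture()
  res <- runDiscovery(fx$frags, fx$gen$genes, fx$gen$genome,
                      activityFloor = uniformFloor(fx$frags, fx$gen$genome))
  truth <- fx$gen$truth$triLoci
  expect_gte(sum(overlapsAny(truth, res$triLoci)) / length(truth), 0.9)
  expect_lte(sum(!overlapsAny(res$triLoci, truth)) / max(1, length(res$triLoci)), 0.1)
  hit <- overlapsAny(res$triLoci, truth)
  assigned <- sort(unique(unlist(strsplit(mcols(res$triLoci)$genes[hit], ","))))
  expect_equal(assigned, sort(fx$gen$truth$triGenes))
  # cTSS set: active non-TRI TSSs (ctss genes and any unassociated partners)
  ctssIds <- mcols(res$ctss)$geneId
  expect_true(all(!ctssIds %in% assigned))
  inactiveIds <- mcols(fx$gen$genes)$geneId[mcols(fx$gen$genes)$class == "inactive"]
  expect_true(all(!inactiveIds %in% ctssIds))
  ctssClassIds <- mcols(fx$gen$genes)$geneId[mcols(fx$gen$genes)$class == "ctss"]
  expect_true(all(ctssClassIds %in% ctssIds))
})
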