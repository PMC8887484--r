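test_that("generation is fully deterministic given the seed", {
  cfg <- simulationConfig(seed = 9, nChrom = 1, chromLength = 300000L,
                          nTri = 4, nCtss = 16, nInactive = 8,
                          fragmentsPerReplicate = 20000L)
  a <- generateGenome(cfg)
  b <- generateGenome(cfg)
  expect_identical(as.character(a$genome@sequences), as.character(b$genome@sequences))
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth$triLoci, b$truth$triLoci)
  fa <- simulateTripnFragments(cfg, a$genome, a$genes, a$truth)
  fb <- simulateTripnFragments(cfg, b$genome, b$genes, b$truth)
  expect_identical(fragments(fa[[1]]), fragments(fb[[1]]))
  expect_identical(fragments(fa[[4]]), fragments(fb[[4]]))
  va <- simulateVariants(cfg, a$genome, a$truth)
  vb <- simulateVariants(cfg, b$genome, b$truth)
  expect_identical(va, vb)
})

test_that("TRI promoters are more GC-rich than background with planted G-runs", {
  fx <- smallFixture()
  gen <- fx$gen
  genes <- gen$genes
  tri <- genes[mcols(genes)$class == "tri"]
  pos <- tssPoints(tri)
  prom <- GRanges(seqnames(pos), IRanges(start(pos) - 499, start(pos) + 500),
                  strand = strand(pos))
  seqs <- genomeSequence(gen$genome, prom)
  gcTri <- mean(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
  # background windows away from genes
  bg <- GRanges("chr1", IRanges(seq(1000, 99000, by = 10000), width = 1000))
  gcBg <- mean(Biostrings::letterFrequency(genomeSequence(gen$genome, bg),
                                           "GC", as.prob = TRUE))
  expect_gt(gcTri, gcBg + 0.1)
  # planted G-run tract downstream of each TRI TSS
  expect_true(all(vapply(seq_along(seqs), function(i)
    grepl("GGG", as.character(seqs[[i]])), logical(1))))
})

test_that("library sizes equal the configured totals exactly", {
  fx <- smallFixture()
  expect_true(all(vapply(fx$frags, librarySize, integer(1)) ==
                    fx$cfg@fragmentsPerReplicate))
  conds <- vapply(fx$frags, condition, character(1))
  expect_equal(sum(conds == "BrdU+"), 3L)
  expect_equal(sum(conds == "BrdU-"), 3L)
})

test_that("planted enrichment fold is recovered in expectation", {
  fx <- smallFixture()
  loci <- fx$gen$truth$triLoci
  counts <- countFragments(fx$frags, loci)
  conds <- attr(counts, "conditions")
  ratioTri <- mean(rowSums(counts[, conds == "BrdU+", drop = FALSE])) /
    mean(rowSums(counts[, conds == "BrdU-", drop = FALSE]))
  # fixed library sizes create a composition effect (extra TRI signal in
  # BrdU+ depresses everything else), so the fold is recovered relative to
  # unenriched promoters rather than as a raw ratio
  ctssTss <- tssPoints(fx$gen$genes[mcols(fx$gen$genes)$class == "ctss"])
  ctssWin <- GRanges(seqnames(ctssTss), IRanges(start(ctssTss) - 600,
                                                start(ctssTss) + 599))
  cc <- countFragments(fx$frags, ctssWin)
  ratioCtss <- mean(rowSums(cc[, conds == "BrdU+", drop = FALSE])) /
    mean(rowSums(cc[, conds == "BrdU-", drop = FALSE]))
  fold <- ratioTri / ratioCtss
  expect_gt(fold, 0.85 * fx$cfg@enrichmentFold)
  expect_lt(fold, 1.15 * fx$cfg@enrichmentFold)
})

test_that("fold-1 null gives exchangeable BrdU+/BrdU- window counts", {
  cfg <- simulationConfig(seed = 21, nChrom = 1, chromLength = 1000000L,
                          nTri = 2, nCtss = 40, nInactive = 10,
                          enrichmentFold = 1, fragmentsPerReplicate = 100000L)
  gen <- generateGenome(cfg, withSequence = FALSE)
  frags <- simulateTripnFragments(cfg, gen$genome, gen$genes, gen$truth)
  win <- genomeBins(gen$genome, 1000L)
  counts <- countFragments(frags, win)
  conds <- attr(counts, "conditions")
  ke <- rowSums(counts[, conds == "BrdU+", drop = FALSE])
  kc <- rowSums(counts[, conds == "BrdU-", drop = FALSE])
  expect_gt(wilcox.test(ke, kc)$p.value, 0.01)
})

test_that("orientation geometry is realized and recoverable from the annotation", {
  fx <- smallFixture()
  genes <- fx$gen$genes
  tri <- genes[mcols(genes)$class == "tri"]
  oc <- classifyOrientation(tssPoints(tri), tssPoints(genes),
                            fx$tx$plusPeaks, fx$tx$minusPeaks)
  expect_equal(oc$class, mcols(tri)$orientation)
  # divergent partners sit within 3 kb upstream on the opposite strand
  div <- which(mcols(tri)$orientation == "divergent_pair")
  partnerIds <- oc$partner[div]
  expect_true(all(!is.na(partnerIds)))
  # inactive genes carry no transcription signal on either strand
  inact <- tssPoints(genes[mcols(genes)$class == "inactive"])
  win <- GRanges(seqnames(inact), IRanges(start(inact) - 500, start(inact) + 500))
  expect_equal(sum(countOverlaps(win, fx$tx$plusPeaks)) +
                 sum(countOverlaps(win, fx$tx$minusPeaks)), 0L)
})

test_that("Okazaki simulation realizes the planted fork field", {
  gm <- GenomeModel(c(chr1 = 1000000))
  # single fully efficient origin: RFD -1 left, +1 right
  ok <- simulateOkseq(gm, data.frame(chrom = "chr1", pos = 500000,
                                     efficiency = 1), depth = 30, seed = 2)
  rfd <- trackValues(computeRfd(ok$fwd, ok$rev), "chr1")
  expect_true(all(rfd[1:499] == -1, na.rm = TRUE))
  expect_true(all(rfd[501:1000] == 1, na.rm = TRUE))
  # balanced null: no origins -> f_R = 0.5 everywhere
  okNull <- simulateOkseq(gm, data.frame(chrom = character(0), pos = integer(0),
                                         efficiency = numeric(0)),
                          depth = 400, seed = 3)
  expect_true(all(abs(trackValues(okNull$fR, "chr1") - 0.5) < 1e-12))
  # two flanking origins: termination (down-slope) between them
  ok2 <- simulateOkseq(gm, data.frame(chrom = "chr1", pos = c(250000, 750000),
                                      efficiency = c(0.9, 0.9)), depth = 50, seed = 4)
  fr <- trackValues(ok2$fR, "chr1")
  # hand-computed f_R between the origins, left of the midpoint: rightward
  # unless only the right origin fires (0.09) or neither (0.01 balanced)
  expect_equal(fr[300], 0.81 + 0.09 + 0.01 * 0.5, tolerance = 1e-6)
  expect_equal(fr[700], 0.09 + 0.01 * 0.5, tolerance = 1e-6)
  # termination: f_R (and hence RFD) drops across the inter-origin zone
  expect_gt(fr[400], fr[600])
  expect_true(all(diff(fr[300:700]) <= 1e-12))
  expect_error(simulateOkseq(gm, data.frame(chrom = "chr1", pos = 1,
                                            efficiency = 1), depth = 0), "depth")
})

test_that("variant simulation plants the configured deletion excess", {
  cfg <- simulationConfig(seed = 31, nChrom = 2, chromLength = 3000000L,
                          nTri = 60, nCtss = 200, nInactive = 40,
                          fragmentsPerReplicate = 1000L,
                          variantRates = c(sbs = 1, insertion = 0.3, deletion = 0.5),
                          deletionFoldTri = 2)
  gen <- generateGenome(cfg, withSequence = FALSE)
  vars <- simulateVariants(cfg, gen$genome, gen$truth)
  triBp <- sum(width(gen$truth$triGeneBodies))
  ctlBp <- sum(width(gen$truth$controlGeneBodies))
  delTri <- sum(vars$class == "deletion" &
    overlapsAny(GRanges(vars$chrom, IRanges(vars$pos, vars$pos)),
                gen$truth$triGeneBodies, ignore.strand = TRUE))
  delCtl <- sum(vars$class == "deletion" &
    overlapsAny(GRanges(vars$chrom, IRanges(vars$pos, vars$pos)),
                gen$truth$controlGeneBodies, ignore.strand = TRUE))
  ratio <- (delTri / triBp) / (delCtl / ctlBp)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
  # round-trip through the VCF reader preserves records and classes
  path <- tempfile(fileext = ".vcf")
  writeVariantsVcf(vars, path, gen$genome)
  back <- readVariantsVcf(path)
  expect_equal(nrow(back), nrow(vars))
  expect_equal(sort(table(back$class)), sort(table(vars$class)))
  # zero rates -> empty list
  cfg0 <- simulationConfig(seed = 31, nChrom = 1, chromLength = 500000L,
                           nTri = 2, nCtss = 20, nInactive = 5,
                           fragmentsPerReplicate = 1000L,
                           variantRates = c(sbs = 0, insertion = 0, deletion = 0),
                           deletionFoldTri = 0)
  gen0 <- generateGenome(cfg0, withSequence = FALSE)
  expect_equal(nrow(simulateVariants(cfg0, gen0$genome, gen0$truth)), 0L)
})

test_that("config validity rejects impossible study conditions", {
  expect_error(simulationConfig(nTri = 0), "positive|counts")
  expect_error(simulationConfig(enrichmentFold = 0.5), "enrichmentFold")
  expect_error(simulationConfig(nChrom = 1, chromLength = 100000L,
                                nTri = 50, nCtss = 50, nInactive = 0),
               "too large")
  expect_error(simulationConfig(originEfficiency = 1.5), "ficiency")
})
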