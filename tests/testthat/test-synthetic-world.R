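test_that("world generation is deterministic in the seed", {
  cfg <- worldConfig(nChrom = 2L, chromLength = 2e6, repeatPairCount = 100L,
                     svCounts = c(NAHR = 40, NHEJ = 80),
                     pairSeparation = c(2e4, 3e5), seed = 61)
  w1 <- generateWorld(cfg)
  w2 <- generateWorld(cfg)
  expect_identical(start(w1@svs), start(w2@svs))
  expect_identical(as.character(mcols(w1@svs)$mechanism),
                   as.character(mcols(w2@svs)$mechanism))
  expect_identical(w1@repeatPairs, w2@repeatPairs)
  expect_identical(w1@contacts$chr1@counts, w2@contacts$chr1@counts)
  expect_identical(w1@rtTrack@values$chr1, w2@rtTrack@values$chr1)
})

test_that("NAHR deletions sit exactly on repeat-pair members with the planted meiotic fraction", {
  w <- generateWorld(xRecoveryConfig(62, xTrue = 0.10))
  nahr <- w@svs[mcols(w@svs)$mechanism == "NAHR"]
  tr <- w@truth$nahr
  up <- w@repeatPairs[tr$usedPairIdx, ]
  expect_equal(start(nahr), pmin(up$origin_start, up$target_start))
  expect_equal(end(nahr), pmax(up$origin_start, up$target_start))
  # planted meiotic fraction within binomial error of x_true
  n <- length(nahr)
  expect_lt(abs(mean(tr$meioticFlag) - 0.10), 3 * sqrt(0.1 * 0.9 / n) + 1e-9)
  # flagged deletions have both breakpoints inside meiotic DSB peaks
  fl <- which(tr$meioticFlag)
  bp <- data.frame(chrom = rep(as.character(seqnames(nahr))[fl], 2),
                   pos = c(start(nahr)[fl], end(nahr)[fl]))
  pts <- GRanges(bp$chrom, IRanges(bp$pos, bp$pos))
  expect_true(all(suppressWarnings(overlapsAny(pts, w@peaks$meioticDSB))))
})

test_that("requesting more NAHR deletions than repeat pairs is an explicit error", {
  cfg <- worldConfig(nChrom = 1L, chromLength = 2e6, repeatPairCount = 10L,
                     svCounts = c(NAHR = 50), withContacts = FALSE,
                     withTracks = FALSE, seed = 1)
  expect_error(generateWorld(cfg), "repeat pairs")
})

test_that("unbiased meiotic peaks are uniform across compartments", {
  w <- generateWorld(nullWorldConfig(63))
  mid <- intervalMidpoints(w@peaks$meioticDSB)
  lab <- assignLabel(mid, w@compartments)
  lev <- sort(unique(as.character(mcols(w@compartments)$label)))
  cov <- vapply(lev, function(l)
    sum(as.numeric(width(w@compartments)[mcols(w@compartments)$label == l])),
    numeric(1))
  obs <- table(factor(lab, levels = lev))
  expect_gt(suppressWarnings(chisq.test(as.numeric(obs),
                                        p = cov / sum(cov))$p.value), 1e-3)
})

test_that("contact matrices are symmetric, non-negative, with masked zero rows", {
  w <- generateWorld(hicBoostConfig(64))
  cm <- w@contacts$chr1
  expect_true(all(cm@counts >= 0))
  expect_equal(cm@counts, t(cm@counts))
  expect_true(all(rowSums(cm@counts[cm@mask, , drop = FALSE]) == 0))
  expect_equal(sum(cm@mask),
               round(w@config$unmappableRate * nrow(cm@counts)))
  # noiseless un-boosted regeneration has obs/exp exactly 1 off the mask
  cfg <- worldConfig(nChrom = 1L, chromLength = 1e6, svCounts = c(NHEJ = 5),
                     repeatPairCount = 0L, compartmentBoost = 1, nahrBoost = 1,
                     contactNoise = FALSE, unmappableRate = 0,
                     withTracks = FALSE, seed = 65)
  w0 <- generateWorld(cfg)
  oe <- obsExp(w0@contacts$chr1@counts)
  expect_true(all(abs(oe$oe - 1) < 1e-9))
})

test_that("written worlds read back identically and analysis never needs the truth file", {
  w <- generateWorld(worldConfig(nChrom = 2L, chromLength = 1e6,
                                 repeatPairCount = 60L,
                                 svCounts = c(NAHR = 30, NHEJ = 60),
                                 pairSeparation = c(2e4, 2e5),
                                 meioticCount = 60, spontCount = 120,
                                 contactResolution = 2e4, seed = 66))
  d <- file.path(tempdir(), "world-rt")
  writeWorld(w, d)
  expect_true(file.exists(file.path(d, "truth.txt")))
  file.remove(file.path(d, "truth.txt"))   # analysis inputs must not need it
  inp <- readWorldInputs(d)
  expect_equal(chromLengths(inp$layout), chromLengths(w@layout))
  expect_equal(start(inp$svs), start(w@svs))
  expect_equal(mcols(inp$svs)$mechanism, mcols(w@svs)$mechanism)
  expect_equal(as.character(mcols(inp$compartments)$label),
               as.character(mcols(w@compartments)$label))
  expect_equal(start(inp$peaks$meioticDSB), start(w@peaks$meioticDSB))
  expect_equal(inp$contacts$chr1@counts, w@contacts$chr1@counts)
  expect_equal(inp$rtTrack@values$chr1, w@rtTrack@values$chr1,
               tolerance = 1e-8)
  unlink(d, recursive = TRUE)
})

test_that("planted compartment enrichment is recovered with the correct sign", {
  w <- generateWorld(plantedA1Config(67))
  res <- enrichmentZscores(w@svs, w@compartments, w@layout,
                           nPerm = 300, seed = 68)
  zTDUP <- res$z[res$mechanism == "TDUP" & res$label == "A1"]
  zNHEJ <- res$z[res$mechanism == "NHEJ" & res$label == "A1"]
  expect_gt(zTDUP, 3)
  expect_lt(zNHEJ, 3)
})

test_that("planted DSB/DNase co-localization gives an aggregation peak at offset zero", {
  w <- generateWorld(worldConfig(nChrom = 2L, chromLength = 3e6,
                                 svCounts = c(NHEJ = 10),
                                 repeatPairCount = 0L, tfbsFraction = 0.4,
                                 spontColocRate = 0.8,
                                 withContacts = FALSE, withTracks = FALSE,
                                 seed = 69))
  occupied <- w@peaks$dnase[suppressWarnings(
    overlapsAny(w@peaks$dnase, w@peaks$tfbs))]
  free <- w@peaks$dnase[!suppressWarnings(
    overlapsAny(w@peaks$dnase, w@peaks$tfbs))]
  pOcc <- regulatoryAggregation(occupied, w@peaks$spontDSB, w@layout,
                                window = 1000, bin = 10)
  pFree <- regulatoryAggregation(free, w@peaks$spontDSB, w@layout,
                                 window = 1000, bin = 10)
  expect_gt(offsetZeroValue(pOcc), 2 * offsetZeroValue(pFree))
  # peak at the center exceeds the flanks
  flank <- mean(pOcc@values[abs(profileOffsets(pOcc)) > 700])
  expect_gt(offsetZeroValue(pOcc), 3 * flank)
})
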