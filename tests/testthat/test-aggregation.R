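test_that("peak aggregation handles the degenerate extremes", {
  gl <- GenomeLayout(c(chr1 = 1e5))
  anch <- data.frame(chrom = "chr1", pos = 50000)
  none <- peakAggregation(anch, GRanges(), gl)
  expect_true(all(none@values == 0))
  expect_equal(length(none@values), 50L)
  full <- peakAggregation(anch, GRanges("chr1", IRanges(1, 1e5)), gl)
  expect_true(all(full@values == 1))
  expect_error(peakAggregation(anch[0, ], GRanges(), gl), "empty anchor")
})

test_that("peak aggregation equals the per-base brute-force oracle", {
  set.seed(11)
  gl <- GenomeLayout(c(c1 = 4000, c2 = 3000))
  for (rep in 1:10) {
    np <- sample(1:8, 1)
    pc <- sample(c("c1", "c2"), np, replace = TRUE)
    ps <- sapply(pc, function(ch) sample.int(chromLengths(gl)[[ch]] - 200, 1))
    peaks <- GRanges(pc, IRanges(ps, ps + sample(10:300, np, replace = TRUE)))
    peaks <- GRanges(pc, IRanges(ps, pmin(ps + sample(10:300, np, replace = TRUE),
                                          chromLengths(gl)[pc])))
    na <- sample(1:5, 1)
    ac <- sample(c("c1", "c2"), na, replace = TRUE)
    anch <- data.frame(chrom = ac,
                       pos = sapply(ac, function(ch)
                         sample.int(chromLengths(gl)[[ch]], 1)))
    win <- sample(c(300, 500), 1); bin <- sample(c(20, 50), 1)
    prof <- peakAggregation(anch, peaks, gl, window = win, bin = bin)
    oracle <- bruteAggregation(anch, peaks, gl, win, bin)
    expect_equal(prof@values, oracle$values, tolerance = 1e-12)
    expect_equal(profileOffsets(prof), as.integer(oracle$offsets))
  }
})

test_that("profiles are invariant under anchor reordering", {
  set.seed(12)
  gl <- GenomeLayout(c(c1 = 1e4))
  peaks <- GRanges("c1", IRanges(sample(1:9000, 20), width = 150))
  anch <- data.frame(chrom = "c1", pos = sample(500:9500, 15))
  p1 <- peakAggregation(anch, peaks, gl, window = 500, bin = 50)
  p2 <- peakAggregation(anch[sample(15), ], peaks, gl, window = 500, bin = 50)
  expect_equal(p1@values, p2@values)
})

test_that("regulatory aggregation anchors at interval midpoints", {
  gl <- GenomeLayout(c(chr1 = 1e5))
  sites <- GRanges("chr1", IRanges(1000, 1999))  # even length, midpoint 1500
  prof <- regulatoryAggregation(sites, sites, gl, window = 100, bin = 10)
  expect_equal(offsetZeroValue(prof), 1)   # anchored inside the site itself
  # against direct anchoring at start + floor(len/2)
  direct <- peakAggregation(data.frame(chrom = "chr1", pos = 1500), sites, gl,
                            window = 100, bin = 10)
  expect_equal(prof@values, direct@values)
})

test_that("signal aggregation normalizes a flat track to exactly 1", {
  gl <- GenomeLayout(c(chr1 = 1e5))
  tr <- SignalTrack(list(chr1 = rep(2.5, 1e4)), step = 10L)
  anch <- data.frame(chrom = "chr1", pos = c(30000, 60000))
  prof <- signalAggregation(anch, tr)
  expect_true(all(abs(prof@values - 1) < 1e-12))
  expect_equal(prof@nAnchors, 2L)
})

test_that("signal aggregation excludes missing bases and dips at planted troughs", {
  # missing data: single missing cell does not poison the bin mean
  v <- rep(1, 100); v[50] <- NA
  tr <- SignalTrack(list(c1 = v), step = 10L)
  prof <- signalAggregation(data.frame(chrom = "c1", pos = 500), tr,
                            window = 200, bin = 10)
  expect_true(all(abs(prof@values - 1) < 1e-12))
  # sinusoidal nucleosome track with anchors at troughs dips below 1 at 0
  step <- 10; n <- 2e4
  mids <- (seq_len(n) - 0.5) * step
  nuc <- SignalTrack(list(c1 = 1 + 0.5 * sin(2 * pi * mids / 150)), step = 10L)
  troughs <- data.frame(chrom = "c1",
                        pos = round(150 * (100:160) + 112))  # sin == -1
  dprof <- signalAggregation(troughs, nuc, window = 1000, bin = 10)
  expect_lt(offsetZeroValue(dprof), 0.9)
})

test_that("boundary-anchored profiles keep the interior separate and normalize to 1", {
  gl <- GenomeLayout(c(c1 = 5e4))
  tr <- SignalTrack(list(c1 = rep(3, 5e3)), step = 10L)
  el <- GRanges("c1", IRanges(c(20000, 30000), width = 300))
  bp <- boundarySignalProfile(el, tr, window = 500, bin = 10)
  expect_true(all(abs(bp$profile@values - 1) < 1e-12))
  expect_equal(bp$interiorMean, 1)
  anch <- elementBoundaryAnchors(el)
  expect_equal(anch$start$pos, start(el))
  expect_equal(anch$end$pos, end(el))
  expect_true(all(profileOffsets(bp$profile)[1:50] < 0))
})

test_that("mean replication time averages available bases around the point", {
  gl <- GenomeLayout(c(c1 = 2000))
  flat <- SignalTrack(list(c1 = rep(1.3, 2000)), step = 1L)
  expect_equal(meanReplicationTime(data.frame(chrom = "c1", pos = 1000), flat),
               1.3)
  stepTr <- SignalTrack(list(c1 = c(rep(-1, 1000), rep(1, 1000))), step = 1L)
  expect_equal(meanReplicationTime(data.frame(chrom = "c1", pos = 1001), stepTr),
               0)
  # point 100 bp from the chromosome start: mean over the 600 available bases
  grad <- SignalTrack(list(c1 = as.numeric(1:2000)), step = 1L)
  got <- meanReplicationTime(data.frame(chrom = "c1", pos = 101), grad)
  expect_equal(got, mean(1:600))
  empty <- SignalTrack(list(c1 = rep(NA_real_, 2000)), step = 1L)
  expect_true(is.na(meanReplicationTime(data.frame(chrom = "c1", pos = 500), empty)))
})

test_that("KS statistic matches the exhaustive ECDF oracle", {
  x <- c(1, 2, 3); y <- c(1, 2, 3)
  r <- ksTwoSample(x, y)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  expect_equal(ksTwoSample(1:5, 11:15)$D, 1)
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), mean = runif(1, 0, 2))
    expect_equal(ksTwoSample(a, b)$D, bruteKSD(a, b), tolerance = 1e-12)
  }
  expect_error(ksTwoSample(numeric(), 1:3), "non-empty")
})

test_that("KS clustering separates early- from late-replicating mechanisms", {
  set.seed(14)
  samples <- list(dup = rnorm(200, 1), dup2 = rnorm(200, 1))
  samples$dup2 <- samples$dup          # identical sample: distance 0
  samples$late1 <- rnorm(200, -1.5)
  samples$late2 <- rnorm(200, -1.4)
  cl <- ksCluster(samples)
  expect_equal(cl$height[1], 0)
  k2 <- stats::cutree(cl$hclust, k = 2)
  expect_equal(k2[["dup"]], k2[["dup2"]])
  expect_equal(k2[["late1"]], k2[["late2"]])
  expect_false(k2[["dup"]] == k2[["late1"]])
  expect_error(ksCluster(samples[1]), "two mechanisms")
})

test_that("junction classification rules follow the stated thresholds", {
  expect_equal(classifyNonhomologous(5, 0), "NHrepl")
  expect_equal(classifyNonhomologous(0, 0), "NHEJ")
  expect_equal(classifyNonhomologous(2, 5), "ambiguous")
  expect_equal(classifyNonhomologous(0, 11), "NHrepl")
  expect_error(classifyNonhomologous(-1, 0), "non-negative")
  expect_equal(classifyPseudogenePeriodicity(c(300, 375, 410)),
               c("close", "away", "close"))
  expect_error(classifyPseudogenePeriodicity(0), "positive")
})
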