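library(Biostrings)

# deterministic toy genome with controllable planted copies
plantGenome <- function(len, plants, seed = 1) {
  set.seed(seed)
  x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (p in plants) x[p$at:(p$at + nchar(p$seq) - 1L)] <- strsplit(p$seq, "")[[1]]
  DNAStringSet(setNames(paste(x, collapse = ""), "chr1"))
}

rc <- function(s) as.character(reverseComplement(DNAString(s)))

test_that("homology search recovers a planted same-orientation copy", {
  set.seed(21)
  rep1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  g <- plantGenome(60000, list(list(at = 10000, seq = rep1),
                               list(at = 30000, seq = rep1)))
  seedGR <- GRanges("chr1", IRanges(10050, 10149))  # inside the first copy
  hit <- findHomologousTarget(seedGR, g)
  expect_false(is.null(hit))
  expect_equal(hit$orientation, "same")
  expect_gt(hit$identity, 0.99)
  expect_gt(hit$alignment_length, 50)
  expect_true(hit$target_start >= 30000 && hit$target_end <= 30350)
})

test_that("orientation and separation filters reject planted violations", {
  set.seed(22)
  rep1 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  # inverted copy only -> no same-orientation survivor
  gInv <- plantGenome(60000, list(list(at = 10000, seq = rep1),
                                  list(at = 30000, seq = rc(rep1))))
  expect_null(findHomologousTarget(GRanges("chr1", IRanges(10050, 10149)), gInv))
  # copy beyond the separation window -> none; within -> found
  gFar <- plantGenome(60000, list(list(at = 10000, seq = rep1),
                                  list(at = 40000, seq = rep1)))
  seedGR <- GRanges("chr1", IRanges(10050, 10149))
  expect_null(findHomologousTarget(seedGR, gFar, maxSep = 5000))
  expect_false(is.null(findHomologousTarget(seedGR, gFar, maxSep = 50000)))
  # nearly adjacent copy -> below the minimum separation
  gNear <- plantGenome(60000, list(list(at = 10000, seq = rep1),
                                   list(at = 10310, seq = rep1)))
  seedHead <- GRanges("chr1", IRanges(10280, 10379))
  near <- findHomologousTarget(seedHead, gNear, minSep = 5000)
  expect_null(near)
})

test_that("search recovers planted world pairs above threshold and none below", {
  cfg <- worldConfig(nChrom = 1L, chromLength = 2e5, binSize = 2e4,
                     repeatPairCount = 12L, pairSeparation = c(5e3, 5e4),
                     repeatIdentity = 0.95,
                     svCounts = c(NHEJ = 5), repeatCompartmentWeights =
                       c(A1 = 1, A2 = 1, B1 = 1, B2 = 1, B3 = 1),
                     withContacts = FALSE, withTracks = FALSE, seed = 31)
  w <- generateWorld(cfg)
  g <- worldGenome(w)
  pairs <- w@repeatPairs
  set.seed(99)
  found <- 0L
  for (i in seq_len(nrow(pairs))) {
    seedGR <- GRanges("chr1", IRanges(pairs$origin_start[i] + 100,
                                      pairs$origin_start[i] + 199))
    hit <- findHomologousTarget(seedGR, g)
    if (is.null(hit)) next
    inTarget <- hit$target_start >= pairs$target_start[i] - 10 &
      hit$target_end <= pairs$target_end[i] + 10
    if (inTarget) found <- found + 1L
    expect_gt(hit$identity, 0.85)
    expect_gt(hit$alignment_length, 50)
    expect_equal(hit$orientation, "same")
  }
  expect_gte(found / nrow(pairs), 0.95)
})

test_that("length rejection sampling reproduces the target distribution", {
  set.seed(41)
  # uniform target over attainable lengths: acceptance rate flat
  pairsU <- data.frame(chrom = "chr1", origin_start = 1:4000,
                       origin_end = 1:4000 + 99,
                       target_start = 1:4000 + sample(1000:20000, 4000, TRUE))
  unifPdf <- lengthPDF(runif(5000, 1000, 20000))
  accU <- lengthRejectionSample(pairsU, unifPdf, seed = 1)
  LU <- abs(accU$target_start - accU$origin_start)
  expect_gt(suppressWarnings(ks.test(LU, "punif", 1000, 20000))$p.value, 1e-3)
  # narrow peak at 5 kb: accepted separations concentrate near 5 kb
  target <- rnorm(5000, 5000, 300)
  pdf <- lengthPDF(target)
  acc <- lengthRejectionSample(pairsU, pdf, seed = 2)
  L <- abs(acc$target_start - acc$origin_start)
  expect_gt(length(L), 100)
  expect_lt(abs(median(L) - 5000), 300)
  expect_gt(suppressWarnings(ks.test(L, target))$p.value, 1e-3)
  # zero-density lengths are always rejected
  far <- data.frame(chrom = "chr1", origin_start = 1, origin_end = 100,
                    target_start = 1e6)
  expect_equal(nrow(lengthRejectionSample(far, pdf, seed = 3)), 0L)
})

test_that("compartment matching honors largest-remainder quotas exactly", {
  track <- GRanges("chr1", IRanges(c(1, 100001, 200001),
                                   c(100000, 200000, 300000)))
  mcols(track)$label <- c("A1", "B1", "B3")
  # real NAHR breakpoints: 50% A1, 50% B3
  real <- makeSVSet(GRanges("chr1", IRanges(rep(50000, 10), rep(250000, 10))),
                    "NAHR")
  mkPairs <- function(n, at) data.frame(
    chrom = "chr1", origin_start = round(seq(at[1], at[2], length.out = n)),
    origin_end = round(seq(at[1], at[2], length.out = n)) + 99,
    target_start = round(seq(at[1], at[2], length.out = n)) + 5000)
  pairs <- rbind(mkPairs(200, c(1, 99000)),      # A1 pool
                 mkPairs(200, c(201000, 299000))) # B3 pool
  sel <- matchCompartmentProportions(pairs, real, track, size = 100, seed = 5)
  lab <- assignLabel(data.frame(chrom = sel$chrom, pos = sel$origin_start), track)
  expect_equal(as.numeric(table(lab)[c("A1", "B3")]), c(50, 50))
  # rounding case: proportions 1/3, 1/3, 1/3 at size 100 sum to exactly 100
  real3 <- makeSVSet(GRanges("chr1", IRanges(c(rep(50000, 4), rep(150000, 4),
                                               rep(250000, 4)),
                                             c(rep(51000, 4), rep(151000, 4),
                                               rep(251000, 4)))), "NAHR")
  pairs3 <- rbind(pairs, mkPairs(200, c(101000, 199000)))
  sel3 <- matchCompartmentProportions(pairs3, real3, track, size = 100, seed = 6)
  expect_equal(nrow(sel3), 100L)
  lab3 <- assignLabel(data.frame(chrom = sel3$chrom, pos = sel3$origin_start),
                      track)
  props <- as.numeric(table(factor(lab3, c("A1", "B1", "B3"))))
  expect_equal(sort(props), c(33, 33, 34))
  expect_equal(props, oracleLargestRemainder(rep(1 / 3, 3), 100),
               tolerance = 1e-9)
  # empty pool for a required compartment errors with the deficit
  expect_error(matchCompartmentProportions(mkPairs(200, c(1, 99000)), real,
                                           track, size = 100),
               "insufficient")
})

test_that("repeat enrichment fold and chi-square behave as constructed", {
  gl <- GenomeLayout(c(chr1 = 1e6))
  reps <- GRanges("chr1", IRanges(seq(1, 9.91e5, by = 1e4), width = 1000))
  # 100 repeats of 1 kb cover 10%; all breakpoints inside -> fold 10
  ptsIn <- data.frame(chrom = "chr1", pos = seq(1, 9.91e5, by = 1e4) + 500)
  rIn <- repeatEnrichment(ptsIn, reps, gl)
  expect_equal(rIn$fold, 10, tolerance = 1e-9)
  expect_lt(rIn$p, 1e-6)
  set.seed(8)
  ptsU <- data.frame(chrom = "chr1", pos = sample.int(1e6, 3000))
  rU <- repeatEnrichment(ptsU, reps, gl)
  expect_lt(abs(rU$fold - 1), 0.25)
  expect_error(repeatEnrichment(ptsU, GRanges(), gl), "zero bases")
})
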