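mkSVs <- function(chrom, starts, ends, mech = "NHEJ") {
  makeSVSet(GRanges(chrom, IRanges(starts, ends)), mech)
}

test_that("circular permutation shifts by one shared offset and wraps across chromosomes", {
  gl <- GenomeLayout(c(A = 100, B = 50))
  svs <- mkSVs("A", 90, 95)
  p0 <- circularPermute(svs, gl, 0)
  expect_equal(p0$chrom1, "A"); expect_equal(p0$pos1, 90)
  expect_equal(p0$chrom2, "A"); expect_equal(p0$pos2, 95)
  p20 <- circularPermute(svs, gl, 20)
  expect_equal(p20$lin_bp1, 110)
  expect_equal(c(p20$chrom1, p20$chrom2), c("B", "B"))
  expect_equal(c(p20$pos1, p20$pos2), c(10, 15))
  # wrap of the last base to the first
  pw <- circularPermute(mkSVs("B", 49, 50), gl, 149)
  expect_equal(pw$chrom1, "B"); expect_equal(pw$pos1, 48)
  expect_equal(pw$chrom2, "B"); expect_equal(pw$pos2, 49)
  expect_error(circularPermute(svs, gl, 150), "offset")
})

test_that("permutation preserves count, lengths, and circular gap structure", {
  gl <- GenomeLayout(c(A = 5000, B = 3000, C = 2000))
  set.seed(3)
  st <- sort(sample(1:4000, 25))
  svs <- mkSVs("A", st, st + sample(10:200, 25, replace = TRUE))
  L <- totalLength(gl)
  circGaps <- function(lin) {
    s <- sort(lin)
    sort(c(diff(s), L - (s[length(s)] - s[1])))
  }
  lin0 <- linearCoordinate(gl, "A", start(svs))
  for (off in c(1, 999, 5432, L - 1)) {
    p <- circularPermute(svs, gl, off)
    expect_equal(nrow(p), length(svs))
    expect_equal(p$length, end(svs) - start(svs))
    expect_equal(circGaps(p$lin_bp1), circGaps(lin0))
  }
})

test_that("background ensembles are deterministic in the seed", {
  gl <- GenomeLayout(c(A = 1e6, B = 1e6))
  o1 <- backgroundEnsemble(gl, 100, seed = 11)
  o2 <- backgroundEnsemble(gl, 100, seed = 11)
  o3 <- backgroundEnsemble(gl, 100, seed = 12)
  expect_identical(o1, o2)
  expect_false(identical(o1, o3))
  expect_true(all(o1 >= 1 & o1 <= totalLength(gl) - 1))
  expect_error(backgroundEnsemble(gl, 0), "n must be")
})

test_that("category fractions count gaps in the denominator only", {
  track <- GRanges("chr1", IRanges(c(1, 1001), c(1000, 2000)))
  mcols(track)$label <- c("A1", "B3")
  allA1 <- data.frame(chrom = "chr1", pos = c(5, 500, 1000))
  expect_equal(categoryFractions(allA1, track), c(A1 = 1, B3 = 0))
  gapPts <- data.frame(chrom = "chr1", pos = c(2500, 3000))
  expect_equal(sum(categoryFractions(gapPts, track)), 0)
  mixed <- data.frame(chrom = "chr1", pos = c(10, 1500, 2500, 3000))
  expect_equal(categoryFractions(mixed, track), c(A1 = 0.25, B3 = 0.25))
  expect_error(categoryFractions(allA1[0, ], track), "empty")
})

test_that("fast enrichment path agrees with brute-force relabeling per permutation", {
  set.seed(9)
  gl <- GenomeLayout(c(chr1 = 50000, chr2 = 30000))
  track <- GRanges(rep(c("chr1", "chr2"), c(5, 3)),
                   IRanges(c(seq(1, 41001, by = 10000), seq(1, 20001, by = 10000)),
                           width = 8000))
  mcols(track)$label <- sample(c("A1", "B1"), 8, replace = TRUE)
  st <- sample(1:45000, 30)
  svs <- makeSVSet(GRanges("chr1", IRanges(st, st + 500)),
                   sample(c("NAHR", "NHEJ"), 30, replace = TRUE))
  nPerm <- 25L
  res <- enrichmentZscores(svs, track, gl, nPerm = nPerm, seed = 4)

  offsets <- backgroundEnsemble(gl, nPerm, seed = 4)
  bp <- svBreakpoints(svs)
  lev <- sort(unique(mcols(track)$label))
  brute <- function(points, mech) {
    sapply(sort(unique(mech)), function(m) {
      lab <- assignLabel(points[mech == m, , drop = FALSE], track)
      sapply(lev, function(l) mean(lab == l))
    })
  }
  obs <- brute(bp[, c("chrom", "pos")], bp$mechanism)
  bgArr <- array(NA_real_, c(length(lev), 2, nPerm))
  for (i in seq_len(nPerm)) {
    pp <- circularPermute(svs, gl, offsets[i])
    pts <- data.frame(chrom = c(pp$chrom1, pp$chrom2), pos = c(pp$pos1, pp$pos2))
    bgArr[, , i] <- brute(pts, rep(pp$mechanism, 2))
  }
  for (m in seq_len(2)) for (l in seq_along(lev)) {
    row <- res[res$mechanism == sort(unique(bp$mechanism))[m] &
               res$label == lev[l], ]
    expect_equal(row$observed, obs[l, m], tolerance = 1e-12)
    expect_equal(row$bg_mean, mean(bgArr[l, m, ]), tolerance = 1e-12)
    expect_equal(row$bg_sd, sd(bgArr[l, m, ]), tolerance = 1e-12)
  }
})

test_that("degenerate single-label segmentation yields undefined Z", {
  gl <- GenomeLayout(c(chr1 = 10000))
  track <- GRanges("chr1", IRanges(1, 10000))
  mcols(track)$label <- "A1"
  svs <- mkSVs("chr1", c(100, 5000), c(200, 5100))
  res <- enrichmentZscores(svs, track, gl, nPerm = 20, seed = 1)
  expect_true(all(is.na(res$z)))
  expect_true(all(res$bg_sd == 0))
})

test_that("region-unit enrichment scores deleted bases per label", {
  gl <- GenomeLayout(c(chr1 = 10000))
  track <- GRanges("chr1", IRanges(c(1, 5001), c(5000, 10000)))
  mcols(track)$label <- c("A1", "B1")
  svs <- mkSVs("chr1", c(1000, 2000), c(1499, 2499))  # fully inside A1
  res <- enrichmentZscores(svs, track, gl, nPerm = 30, seed = 2, unit = "region")
  expect_equal(res$observed[res$label == "A1"], 1)
  expect_equal(res$observed[res$label == "B1"], 0)
})

test_that("encompassing statistic counts each SV once and recovers planted spanning", {
  gl <- GenomeLayout(c(chr1 = 1e5))
  pts <- data.frame(chrom = "chr1", pos = c(20000, 20500, 21000, 70000))
  # one SV containing three points counts once; strict containment at ends
  svs <- mkSVs("chr1", c(19999, 30000, 70000), c(21001, 30100, 70100),
               c("NAHR", "NAHR", "NAHR"))
  res <- encompassingZscores(svs, pts, gl, nPerm = 10, seed = 1)
  expect_equal(res$observed, 1)  # third SV starts AT the point: not strict
  # planted recovery: spanning class positive Z, non-spanning class not above it
  set.seed(5)
  bound <- data.frame(chrom = "chr1", pos = seq(5000, 95000, by = 5000))
  spanSt <- bound$pos[1:15] - 400
  spanning <- mkSVs("chr1", spanSt, spanSt + 800, "NAHR")
  tinySt <- bound$pos[1:15] + 1000
  tiny <- mkSVs("chr1", tinySt, tinySt + 50, "NHEJ")
  res2 <- encompassingZscores(suppressWarnings(c(spanning, tiny)), bound, gl,
                              nPerm = 300, seed = 7)
  zN <- res2$z[res2$mechanism == "NAHR"]
  zE <- res2$z[res2$mechanism == "NHEJ"]
  expect_gt(zN, 2)
  expect_lt(zE, zN)
})

test_that("Z-profile clustering merges identical rows first and separates opposed blocks", {
  z <- rbind(a = c(3, -2, 1), b = c(3, -2, 1), c = c(-3, 2, -1),
             d = c(-3.1, 2.2, -1), e = c(2.9, -2.1, 1.2))
  cl <- zscoreCluster(z)
  expect_equal(cl$height[1], 0)
  k2 <- stats::cutree(cl$hclust, k = 2)
  expect_equal(k2[["a"]], k2[["b"]])
  expect_equal(k2[["a"]], k2[["e"]])
  expect_equal(k2[["c"]], k2[["d"]])
  expect_false(k2[["a"]] == k2[["c"]])
  expect_error(zscoreCluster(z[1, , drop = FALSE]), "two mechanisms")
  zNA <- z; zNA["a", 1] <- NA
  expect_warning(cl2 <- zscoreCluster(zNA), "excluding")
  expect_false("a" %in% cl2$order)
})
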