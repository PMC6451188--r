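suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# Brute-force per-base peak aggregation: for each bin around each anchor,
# count covered bases one at a time.
bruteAggregation <- function(anchors, peaks, layout, window, bin) {
  offs <- seq(-window %/% bin, window %/% bin - 1L)
  covered <- lapply(chromNames(layout), function(ch) {
    v <- logical(chromLengths(layout)[[ch]])
    p <- peaks[as.character(seqnames(peaks)) == ch]
    for (i in seq_along(p)) v[start(p)[i]:end(p)[i]] <- TRUE
    v
  })
  names(covered) <- chromNames(layout)
  vals <- numeric(length(offs))
  for (bi in seq_along(offs)) {
    tot <- 0
    for (a in seq_len(nrow(anchors))) {
      bases <- anchors$pos[a] + offs[bi] * bin + 0:(bin - 1L)
      cv <- covered[[anchors$chrom[a]]]
      inb <- bases >= 1 & bases <= length(cv)
      tot <- tot + sum(cv[bases[inb]])
    }
    vals[bi] <- tot / (nrow(anchors) * bin)
  }
  list(offsets = offs * bin, values = vals)
}

# Plain symmetric Sinkhorn iteration to convergence (independent of the
# Newton-CG implementation under test).
sinkhornBalance <- function(A, maxIter = 100000L, tol = 1e-12) {
  x <- rep(1, nrow(A))
  for (i in seq_len(maxIter)) {
    v <- as.numeric(A %*% x) * x
    if (max(abs(v - 1)) < tol) break
    x <- x * sqrt(1 / v)
  }
  list(balanced = A * outer(x, x), scaling = x)
}

# Exhaustive ECDF-difference KS statistic.
bruteKSD <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(g) - stats::ecdf(y)(g)))
}

# Largest-remainder apportionment, written independently (enumerative).
oracleLargestRemainder <- function(props, size) {
  raw <- props * size
  base <- floor(raw)
  rem <- raw - base
  left <- size - sum(base)
  if (left > 0) {
    for (i in order(rem, decreasing = TRUE)[seq_len(left)])
      base[i] <- base[i] + 1
  }
  base
}

# --- shared small-world configurations (study conditions at test scale) ---

# No planted structure anywhere: uniform SV placement, uniform peaks.
nullWorldConfig <- function(seed) {
  worldConfig(nChrom = 2L, chromLength = 3e6,
              svCounts = c(NHEJ = 200, TDUP = 200, `AluL1-del` = 200),
              svEnrichment = list(),
              repeatPairCount = 0L, spontCount = 300, spontColocRate = 0,
              meioticCount = 150, meioticB1Bias = 1, xTrue = 0,
              dnaseDensity = c(A1 = 30, A2 = 30, B1 = 30, B2 = 30, B3 = 30),
              withContacts = FALSE, withTracks = FALSE, seed = seed)
}

# One SV class with a 3x planted A1 density bias.
plantedA1Config <- function(seed) {
  worldConfig(nChrom = 2L, chromLength = 3e6,
              svCounts = c(TDUP = 300, NHEJ = 300),
              svEnrichment = list(TDUP = c(A1 = 3)),
              repeatPairCount = 0L, withContacts = FALSE, withTracks = FALSE,
              seed = seed)
}

# Meiotic-fraction recovery world: NAHR + the two repair control classes.
xRecoveryConfig <- function(seed, xTrue = 0.10) {
  worldConfig(nChrom = 2L, chromLength = 5e6,
              svCounts = c(NAHR = 150, NHEJ = 300, NHrepl = 300),
              repeatPairCount = 400L, meioticCount = 200,
              xTrue = xTrue, withContacts = FALSE, withTracks = FALSE,
              seed = seed)
}

# Only the spontaneous-DSB association planted: everything else uniform.
spontOnlyConfig <- function(seed) {
  worldConfig(nChrom = 2L, chromLength = 5e6,
              svCounts = c(NAHR = 200),
              svEnrichment = list(),
              repeatPairCount = 600L,
              repeatCompartmentWeights = c(A1 = 1, A2 = 1, B1 = 1, B2 = 1, B3 = 1),
              dnaseDensity = c(A1 = 30, A2 = 30, B1 = 30, B2 = 30, B3 = 30),
              spontCount = 600, spontColocRate = 0, spontAtNahrRate = 0.9,
              meioticCount = 200, meioticB1Bias = 1, xTrue = 0,
              withContacts = FALSE, withTracks = FALSE, seed = seed)
}

# Hi-C world with a planted 2x NAHR-pair contact boost.
hicBoostConfig <- function(seed) {
  worldConfig(nChrom = 2L, chromLength = 3e6,
              svCounts = c(NAHR = 120), repeatPairCount = 400L,
              pairSeparation = c(2e4, 5e5), nahrBoost = 2,
              xTrue = 0, withTracks = FALSE, seed = seed)
}

# Structureless Hi-C world: pure distance decay (no boosts).
hicNeutralConfig <- function(seed) {
  worldConfig(nChrom = 2L, chromLength = 3e6,
              svCounts = c(NHEJ = 10), repeatPairCount = 0L,
              compartmentBoost = 1, nahrBoost = 1,
              withTracks = FALSE, seed = seed)
}

worldAnalysisStack <- function(world, krTol = 1e-6) {
  oeList <- lapply(world@contacts, function(cm)
    obsExp(krBalance(cm, tol = krTol)$balanced))
  profile <- compartmentDistanceProfile(oeList, world@compartments,
                                        world@contacts[[1]]@resolution)
  list(oeList = oeList, profile = profile)
}
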