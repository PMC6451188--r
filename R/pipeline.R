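#' Pipeline configuration
#'
#' Assembles the end-to-end run configuration with the conventional
#' defaults: 1000 permutations, 2.5 kb / 100 bp peak aggregation windows,
#' 1 kb / 10 bp signal windows with 2 kb normalization, 5 kb minimum SV
#' length for the Hi-C comparison, and a 3-standard-deviation discordance
#' threshold. A single global seed is expanded into fixed per-stage seeds
#' so any stage can be rerun in isolation.
#'
#' @param seed global integer seed.
#' @param nPerm permutations for the circular-permutation background.
#' @param peakWindow,peakBin peak-aggregation geometry (bp).
#' @param signalWindow,signalBin,normWindow signal-aggregation geometry (bp).
#' @param minSVLength minimum SV length for Hi-C interaction (bp).
#' @param krTol KR balancing tolerance.
#' @param discordanceK discordant-bin threshold in residual SDs.
#' @param f_m,f_s capture fractions for the meiotic-fraction estimate.
#' @param stages character vector of stages to run, a subset of
#'   `c("enrichment", "aggregation", "hic", "regression", "estimate")`.
#' @return named list of class `svcPipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1L, nPerm = 1000L,
                           peakWindow = 2500L, peakBin = 100L,
                           signalWindow = 1000L, signalBin = 10L,
                           normWindow = 2000L, minSVLength = 5000L,
                           krTol = 1e-6, discordanceK = 3,
                           f_m = 1, f_s = 1,
                           stages = c("enrichment", "aggregation", "hic",
                                      "regression", "estimate")) {
  cfg <- as.list(environment())
  known <- c("enrichment", "aggregation", "hic", "regression", "estimate")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "svcPipelineConfig"
  cfg
}

# Fixed per-stage seed derivation from the global seed.
.stageSeed <- function(seed, stage) {
  offs <- c(world = 11L, enrichment = 23L, aggregation = 37L, hic = 41L,
            regression = 43L, estimate = 53L)
  (as.integer(seed) * 1009L + offs[[stage]]) %% .Machine$integer.max
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates all stages over a set of inputs (a [SyntheticWorld-class],
#' or a directory as read by [readWorldInputs()]) and writes stage outputs
#' as TSV plus a run manifest (parameter echo and consumed seeds) to
#' `outDir`. Reruns with the same inputs and configuration are
#' bit-identical. The synthetic truth record is never consumed.
#'
#' @param inputs a `SyntheticWorld`, or a directory path of inputs.
#' @param outDir output directory.
#' @param config a [pipelineConfig()].
#' @return list of stage results, invisibly; files under `outDir`.
#' @export
runPipeline <- function(inputs, outDir, config = pipelineConfig()) {
  if (is.character(inputs)) inputs <- readWorldInputs(inputs)
  if (is(inputs, "SyntheticWorld")) {
    inputs <- list(layout = inputs@layout, compartments = inputs@compartments,
                   peaks = inputs@peaks, svs = inputs@svs,
                   tadBoundaries = inputs@tadBoundaries,
                   loopAnchors = inputs@loopAnchors,
                   rtTrack = inputs@rtTrack, nucTrack = inputs@nucTrack,
                   contacts = inputs@contacts,
                   repeatPairs = inputs@repeatPairs)
  }
  missing <- setdiff(c("layout", "compartments", "svs"), names(inputs))
  if (length(missing))
    stop("missing required input(s): ", paste(missing, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  seeds <- list()
  wtsv <- function(x, f) write.table(x, file.path(outDir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)

  if ("enrichment" %in% config$stages) {
    s <- .stageSeed(config$seed, "enrichment")
    seeds$enrichment <- s
    res$enrichment <- enrichmentZscores(inputs$svs, inputs$compartments,
                                        inputs$layout, nPerm = config$nPerm,
                                        seed = s)
    wtsv(res$enrichment, "enrichment_compartments.tsv")
    if (nrow(inputs$tadBoundaries)) {
      res$tadEncompassing <- encompassingZscores(
        inputs$svs, inputs$tadBoundaries, inputs$layout,
        nPerm = config$nPerm, seed = s)
      wtsv(res$tadEncompassing, "encompassing_tad_boundaries.tsv")
    }
  }

  mech <- as.character(mcols(inputs$svs)$mechanism)
  profFor <- function(m, peaks) {
    bp <- svBreakpoints(inputs$svs[mech == m])
    peakAggregation(bp[, c("chrom", "pos")], peaks, inputs$layout,
                    window = config$peakWindow, bin = config$peakBin)
  }
  if ("aggregation" %in% config$stages &&
      !is.null(inputs$peaks$meioticDSB)) {
    aggOut <- list()
    for (m in intersect(c("NAHR", "NHEJ", "NHrepl"), unique(mech))) {
      pr <- profFor(m, inputs$peaks$meioticDSB)
      aggOut[[m]] <- data.frame(mechanism = m, offset = profileOffsets(pr),
                                value = pr@values, n_anchors = pr@nAnchors)
      res$aggregation[[m]] <- pr
    }
    wtsv(do.call(rbind, aggOut), "aggregation_meiotic_dsb.tsv")
  }

  if ("hic" %in% config$stages && length(inputs$contacts)) {
    oeList <- lapply(inputs$contacts, function(cm)
      obsExp(krBalance(cm, tol = config$krTol)$balanced))
    resn <- inputs$contacts[[1]]@resolution
    profile <- compartmentDistanceProfile(oeList, inputs$compartments, resn)
    res$hic <- svInteractions(inputs$svs, oeList, profile,
                              inputs$compartments,
                              minLength = config$minSVLength)
    wtsv(res$hic, "hic_interactions.tsv")
  }

  if ("regression" %in% config$stages &&
      all(c("spontDSB", "meioticDSB") %in% names(inputs$peaks)) &&
      !is.null(inputs$repeatPairs) && nrow(inputs$repeatPairs) &&
      "NAHR" %in% mech) {
    bins <- inputs$compartments
    Y <- binFractions(svBreakpoints(inputs$svs[mech == "NAHR"]), bins)
    X <- cbind(
      homologous = binFractions(pairBreakpoints(inputs$repeatPairs), bins),
      spontaneous = binFractions(intervalMidpoints(inputs$peaks$spontDSB), bins),
      meiotic = binFractions(intervalMidpoints(inputs$peaks$meioticDSB), bins))
    res$regression <- fitLinear(Y, X)
    res$discordant <- discordantBins(res$regression, k = config$discordanceK)
    wtsv(data.frame(term = names(res$regression$coefficients),
                    estimate = res$regression$coefficients,
                    r_squared = res$regression$r_squared,
                    adj_r_squared = res$regression$adj_r_squared),
         "regression_fit.tsv")
    wtsv(res$discordant, "discordant_bins.tsv")
  }

  if ("estimate" %in% config$stages &&
      !is.null(inputs$peaks$meioticDSB) &&
      all(c("NAHR", "NHEJ", "NHrepl") %in% mech)) {
    nahrProf <- res$aggregation$NAHR
    if (is.null(nahrProf)) nahrProf <- profFor("NAHR", inputs$peaks$meioticDSB)
    ctrl <- lapply(c("NHEJ", "NHrepl"), profFor,
                   peaks = inputs$peaks$meioticDSB)
    res$estimate <- estimateFromProfiles(nahrProf, ctrl,
                                         f_m = config$f_m, f_s = config$f_s)
    wtsv(as.data.frame(res$estimate), "meiotic_fraction.tsv")
  }

  manifest <- c(
    paste0("package_version=", as.character(utils::packageVersion("svchromatin"))),
    paste0("global_seed=", config$seed),
    vapply(names(seeds), function(n) paste0("seed_", n, "=", seeds[[n]]),
           character(1)),
    paste0("stages=", paste(config$stages, collapse = ",")),
    paste0("n_perm=", config$nPerm),
    paste0("peak_window=", config$peakWindow), paste0("peak_bin=", config$peakBin),
    paste0("min_sv_length=", config$minSVLength),
    paste0("kr_tol=", config$krTol), paste0("discordance_k=", config$discordanceK))
  writeLines(manifest, file.path(outDir, "manifest.txt"))
  invisible(res)
}
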