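.demoDefaults <- function() {
  list(minCopies = 7L, maxCopies = 25L, gcMin = 0.40, gcMax = 0.60,
       homopolymer = 5L, alleleThreshold = 0.02, window = 10L,
       tileWidth = 100L, featureFlank = 500L,
       correlationLevel = "replicate", seed = 1L, readsPerSite = 2000L,
       replicates = 3L, depth = 100L, errorRate = 0,
       controlEfficiency = 0.5, repNoiseSd = 0.08)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (7-25 copy band, 40-60\% GC, homopolymer run 5, 2\%
#' allele threshold, quantification window 10 bp, 100-bp methylation
#' tiling, 1-kb feature windows) and reports conflicts.
#'
#' @param config Named list of overrides (may be empty).
#' @return Normalized config list.
#' @export
validateConfig <- function(config = list()) {
  defaults <- .demoDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (cfg$minCopies > cfg$maxCopies)
    stop("copy range invalid: minCopies > maxCopies")
  if (cfg$gcMin > cfg$gcMax) stop("GC bounds invalid: gcMin > gcMax")
  if (cfg$alleleThreshold < 0 || cfg$alleleThreshold > 1)
    stop("alleleThreshold must be in [0, 1]")
  if (!cfg$correlationLevel %in% c("replicate", "site"))
    stop("correlationLevel must be 'replicate' or 'site'")
  for (k in c("minCopies", "maxCopies", "homopolymer", "window",
              "tileWidth", "featureFlank", "readsPerSite", "replicates",
              "depth"))
    if (cfg[[k]] <= 0) stop("config value must be positive: ", k)
  cfg
}

# Deterministic protospacer passing the GC and simple-motif filters, with an
# AluI site (AGCT) across positions 16-19 so the restriction-overlap stage
# keeps it.
.demoProtospacer <- function(seed) {
  set.seed(seed)
  repeat {
    p <- paste(sample(BASES, 15, replace = TRUE), collapse = "")
    proto <- paste0(p, "AGCT", "A")
    if (filterGC(proto) && filterSimpleMotif(proto))
      return(paste0(proto, "TGG"))
  }
}

# 20-bp cassette guaranteeing CG, CHG and CHH cytosines in any window that
# contains it, so window-level methylation is always defined in all three
# contexts at planted loci
CONTEXT_CASSETTE <- "TTACGTTCAGGTTCTTATTT"

.plantCassettes <- function(genome, reg, tileWidth = 100L) {
  cut0 <- cutPosition(reg)
  tile0 <- (cut0 %/% tileWidth) * tileWidth
  for (i in seq_along(reg)) {
    ch <- as.character(seqnames(reg))[i]
    s <- as.character(genome[[ch]])
    a <- tile0[i] + 3L  # 1-based start; sites are planted clear of this span
    substr(s, a, a + nchar(CONTEXT_CASSETTE) - 1L) <- CONTEXT_CASSETTE
    genome[[ch]] <- DNAString(s)
  }
  genome
}

.demoContexts <- function() {
  data.frame(
    context = c("open_unmeth", "open_unmeth", "cg_only", "cg_only",
                "rddm", "rddm", "het", "het"),
    mCG = c(0.02, 0.02, 0.60, 0.60, 0.50, 0.50, 0.80, 0.80),
    mCHG = c(0.01, 0.01, 0.02, 0.02, 0.40, 0.40, 0.70, 0.70),
    mCHH = c(0.005, 0.005, 0.02, 0.02, 0.30, 0.30, 0.05, 0.05),
    open = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    state = c("state1", "state2", "state3", "state3", "state6", "state6",
              "state8", "state9"),
    efficiency = c(0.75, 0.70, 0.30, 0.28, 0.08, 0.07, 0.003, 0.004),
    insShare = c(0.70, 0.68, 0.60, 0.58, 0.35, 0.33, 0.25, 0.27))
}

#' Run the full pipeline end to end on synthetic data
#'
#' Builds a synthetic genome with two planted multicopy families whose
#' copies span four methylation domains and both accessibility states,
#' simulates methylation calls, peaks and feature tracks, simulates edited
#' amplicon reads with planted efficiency monotone in accessibility
#' (heterochromatic, inaccessible copies are planted ~250-fold less edited
#' than open unmethylated ones), then runs discovery, annotation, indel
#' profiling (normalized to a simulated single-copy euchromatic control)
#' and association statistics, and reports whether the qualitative headline
#' - lower recovered editing at heterochromatic planted sites - holds.
#'
#' @param config Named list of overrides, see [validateConfig()].
#' @param dir Optional output directory; when given, genome FASTA, site
#'   registry, methylation calls, peaks, tracks and summary tables are
#'   written there.
#' @return list with elements \code{config}, \code{built}, \code{catalog},
#'   \code{cascade}, \code{annotation}, \code{selectedFamilies},
#'   \code{editingTable}, \code{groups}, \code{correlations},
#'   \code{clusters}, \code{insertionKW}, and \code{headline}.
#' @export
runDemo <- function(config = list(), dir = NULL) {
  cfg <- validateConfig(config)
  ctx <- .demoContexts()
  nPer <- nrow(ctx)
  targets <- c(.demoProtospacer(cfg$seed), .demoProtospacer(cfg$seed + 101L))
  if (targets[1] == targets[2]) targets[2] <- .demoProtospacer(cfg$seed + 202L)

  # evenly spaced loci, alternating chromosome and strand; offsets 34/44
  # within the 100-bp tile keep each site clear of the context cassette
  loci <- lapply(1:2, function(f) {
    i <- seq_len(nPer)
    strand <- ifelse(i %% 3 == 0, "-", "+")
    data.frame(chrom = ifelse(i %% 2 == 1, "chr1", "chr2"),
               start0 = 4000L + (i - 1L) * 6000L + (f - 1L) * 3000L +
                 ifelse(strand == "-", 44L, 34L),
               strand = strand)
  })
  gplan <- genomePlan(
    chromLengths = c(chr1 = 60000L, chr2 = 60000L),
    families = list(list(name = "famA", target = targets[1],
                         loci = loci[[1]]),
                    list(name = "famB", target = targets[2],
                         loci = loci[[2]])),
    organelles = c(chrM = 8000L, chrC = 8000L),
    gc = 0.36, seed = cfg$seed)
  built <- buildGenome(gplan)
  built$genome <- .plantCassettes(built$genome, built$registry,
                                  cfg$tileWidth)
  reg <- built$registry
  regCtx <- ctx[rep(seq_len(nPer), 2), ]
  regCtx$family <- mcols(reg)$family
  regCtx$site <- paste0(sub("fam", "MC", mcols(reg)$family), ".",
                        rep(seq_len(nPer), 2))
  names(reg) <- regCtx$site

  # chromatin plan: planned methylation in the 100-bp tile holding each cut
  cut0 <- cutPosition(reg)
  tile0 <- (cut0 %/% cfg$tileWidth) * cfg$tileWidth
  wins <- data.frame(chrom = as.character(seqnames(reg)), start0 = tile0,
                     end0 = tile0 + cfg$tileWidth,
                     mCG = regCtx$mCG, mCHG = regCtx$mCHG,
                     mCHH = regCtx$mCHH)
  peakDf <- data.frame(chrom = as.character(seqnames(reg))[regCtx$open],
                       start0 = pmax(0L, start(reg)[regCtx$open] - 201L),
                       end0 = end(reg)[regCtx$open] + 200L)
  center0 <- (start(reg) - 1L) + 11L
  featReg <- function(mean) data.frame(
    chrom = as.character(seqnames(reg)),
    start0 = pmax(0L, center0 - 600L), end0 = center0 + 600L, mean = mean)
  features <- list(
    ATAC = featReg(ifelse(regCtx$open, 8, 0.5)),
    H3K56ac = featReg(regCtx$efficiency * 10),
    H3K9me2 = featReg(ifelse(regCtx$context %in% c("het", "rddm"), 6, 0.3)),
    H3_1 = featReg((0.8 - regCtx$insShare) * 10))
  cplan <- chromatinPlan(wins, depth = cfg$depth, peaks = peakDf,
                         features = features, noiseSd = 0,
                         seed = cfg$seed + 1L)
  calls <- simulateMethylation(built$genome, cplan)
  tracks <- simulateTracks(built$genome, cplan)

  # discovery
  catalog <- scanPamSites(built$genome)
  cascade <- filterCascade(catalog, lo = cfg$minCopies, hi = cfg$maxCopies,
                           maxRun = cfg$homopolymer, gcLo = cfg$gcMin,
                           gcHi = cfg$gcMax, organelles = built$organelles,
                           enzymes = loadEnzymes())

  # annotation of the planted occurrences (discovery recovers exactly these)
  windows <- windowMethylation(calls, seqlengths = seqlengths(built$genome),
                               windowSize = cfg$tileWidth)
  states <- GRanges(as.character(seqnames(reg)),
                    IRanges(pmax(1L, start(reg) - 500L), end(reg) + 500L),
                    state = regCtx$state)
  ann <- annotateSites(reg, windows, tracks$peaks, tracks$tracks,
                       states = states, windowSize = cfg$tileWidth)
  subcat <- subsetCatalog(catalog, targets)
  occ <- occurrences(subcat)
  regIdx <- match(paste(seqnames(occ), start(occ)),
                  paste(seqnames(reg), start(reg)))
  selected <- selectMCsiteFamilies(
    subcat,
    data.frame(accessibility = ann$accessibility, domain = ann$domain,
               state = ann$state)[regIdx, , drop = FALSE])

  # editing simulation + profiling, with a shared-control normalization
  ampl <- .extractAmplicons(built$genome, reg)
  protoOnStrand <- substr(mcols(reg)$target, 1, 20)
  editTab <- list()
  controlRef <- .controlAmplicon(cfg$seed + 7L)
  for (r in seq_len(cfg$replicates)) {
    set.seed(cfg$seed + 1000L * r)
    repMult <- exp(stats::rnorm(1, 0, cfg$repNoiseSd))
    ctrlPlan <- editingPlan(cfg$readsPerSite,
                            1 - cfg$controlEfficiency * repMult,
                            cfg$controlEfficiency * repMult * 0.6,
                            c(del_1_5 = cfg$controlEfficiency * repMult * 0.3,
                              del_6_10 = cfg$controlEfficiency * repMult * 0.07,
                              del_gt10 = cfg$controlEfficiency * repMult * 0.03),
                            errorRate = cfg$errorRate,
                            seed = cfg$seed + 900L + r)
    ctrlSim <- simulateAmpliconReads(controlRef$reference,
                                     controlRef$cutIndex, ctrlPlan)
    ctrlProf <- profileAmplicon(ctrlSim$reads, controlRef$spec,
                                threshold = cfg$alleleThreshold,
                                window = cfg$window)
    for (i in seq_along(reg)) {
      eff <- min(0.95, regCtx$efficiency[i] * repMult)
      plan <- editingPlan(cfg$readsPerSite, 1 - eff,
                          eff * regCtx$insShare[i],
                          c(del_1_5 = eff * (1 - regCtx$insShare[i]) * 0.7,
                            del_6_10 = eff * (1 - regCtx$insShare[i]) * 0.2,
                            del_gt10 = eff * (1 - regCtx$insShare[i]) * 0.1),
                          insRule = "templated",
                          delSizes = list(del_1_5 = 2L, del_6_10 = 7L,
                                          del_gt10 = 12L),
                          errorRate = cfg$errorRate,
                          seed = cfg$seed + 10000L * r + i)
      sim <- simulateAmpliconReads(ampl$seq[i], ampl$cut[i], plan)
      spec <- ampliconSpec(ampl$seq[i], protoOnStrand[i],
                           siteId = regCtx$site[i])
      prof <- profileAmplicon(sim$reads, spec,
                              threshold = cfg$alleleThreshold,
                              window = cfg$window)
      prof <- normalizeFrequency(prof, ctrlProf)
      editTab[[length(editTab) + 1L]] <- data.frame(
        site = regCtx$site[i], family = regCtx$family[i], replicate = r,
        indel_freq = indelFrequency(prof),
        normalized_freq = prof@normalizedFrequency,
        insertion_rate = insertionRate(prof))
    }
  }
  editTab <- do.call(rbind, editTab)

  groups <- lapply(split(editTab, editTab$family), function(d)
    assignGroups(data.frame(site = d$site, value = d$normalized_freq)))

  raw <- attr(ann, "normalized")
  siteMeans <- tapply(editTab$normalized_freq, editTab$site, mean)
  insMeans <- tapply(editTab$insertion_rate, editTab$site, mean)
  repFeat <- raw[match(editTab$site, ann$site), , drop = FALSE]
  corEff <- correlate(repFeat, editTab$normalized_freq, "efficiency")
  corIns <- correlate(raw[match(names(insMeans), ann$site), , drop = FALSE],
                      as.numeric(insMeans), "insertion_rate")
  clusters <- clusterFeatures(`rownames<-`(raw, ann$site))
  kwKeep <- !is.na(editTab$insertion_rate)
  kw <- kruskalWallis(editTab$insertion_rate[kwKeep],
                      editTab$family[kwKeep])

  hetSites <- ann$site[!is.na(ann$domain) & ann$domain == "heterochromatin"]
  unmSites <- ann$site[!is.na(ann$domain) & ann$domain == "unmethylated"]
  minPos <- min(siteMeans[siteMeans > 0])  # sites with detected editing
  headline <- list(
    heterochromatin_mean = mean(siteMeans[hetSites]),
    unmethylated_mean = mean(siteMeans[unmSites]),
    lower_at_heterochromatin =
      mean(siteMeans[hetSites]) < mean(siteMeans[unmSites]),
    fold_change_extremes = foldChange(max(siteMeans), minPos))

  out <- list(config = cfg, built = built, catalog = catalog,
              cascade = cascade, annotation = ann,
              selectedFamilies = selected, editingTable = editTab,
              groups = groups,
              correlations = rbind(corEff, corIns), clusters = clusters,
              insertionKW = kw, headline = headline)
  if (!is.null(dir)) .writeDemo(out, calls, tracks, dir)
  out
}

.extractAmplicons <- function(genome, reg, flank = 110L) {
  n <- length(reg)
  seqs <- character(n)
  cuts <- integer(n)
  for (i in seq_len(n)) {
    ch <- as.character(seqnames(reg))[i]
    s0 <- start(reg)[i] - 1L
    a0 <- max(0L, s0 - flank)
    b0 <- min(nchar(as.character(genome[[ch]])), s0 + 23L + flank)
    seqs[i] <- substring(as.character(genome[[ch]]), a0 + 1L, b0)
    cuts[i] <- cutPosition(reg[i]) - a0
  }
  list(seq = seqs, cut = cuts)
}

.controlAmplicon <- function(seed) {
  set.seed(seed)
  proto <- .demoProtospacer(seed + 1L)
  left <- .randomSeq(110L, 0.4)
  right <- .randomSeq(110L, 0.4)
  ref <- paste0(left, proto, right)
  spec <- ampliconSpec(ref, substr(proto, 1, 20), siteId = "CHLI2_control")
  list(reference = ref, cutIndex = spec$cutIndex, spec = spec)
}

.writeDemo <- function(out, calls, tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenome(out$built, file.path(dir, "genome"))
  writeSiteRegistry(out$built$registry, file.path(dir, "site_registry"))
  writeCytosineCalls(calls, file.path(dir, "cytosine_calls.tsv"))
  writeBed(tracks$peaks, file.path(dir, "peaks.bed"))
  for (nm in names(tracks$tracks))
    writeBedGraph(tracks$tracks[[nm]],
                  file.path(dir, paste0("track_", nm, ".bedGraph")))
  utils::write.table(out$editingTable, file.path(dir, "editing_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$correlations, file.path(dir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$annotation, file.path(dir, "site_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeTruthLog(out$headline, file.path(dir, "headline.json"))
  invisible(dir)
}
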