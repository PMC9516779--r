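testTarget <- "ACGTTGCATCAGGATCAGCTTGG"

# build a TargetCatalog by hand: k dummy occurrences per target at spaced loci
manualCatalog <- function(copies) {
  occ <- list()
  at <- 1L
  for (i in seq_along(copies)) {
    tg <- copies[[i]]$target
    k <- copies[[i]]$n
    occ[[i]] <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(seq(at, by = 100L, length.out = k),
                               width = 23L),
      strand = "+", target = tg)
    at <- at + 100L * k
  }
  TargetCatalog(suppressWarnings(do.call(c, occ)))
}

test_that("PAM scanning finds no targets where no PAM can exist", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 500)))
  expect_equal(length(scanPamSites(g)), 0L)
  expect_equal(length(scanPamSites(Biostrings::DNAStringSet())), 0L)
})

test_that("scanner recovers planted copies with correct strand convention", {
  gp <- genomePlan(c(chr1 = 10000L),
                   families = list(list(target = testTarget, copies = 7)),
                   seed = 3)
  b <- buildGenome(gp)
  cat <- scanPamSites(b$genome)
  expect_equal(unname(copyNumber(cat)[testTarget]), 7L)
  # a minus-strand planted copy is reported with strand '-' and the
  # forward-strand interval covering the same 23 bases
  minus <- b$registry[as.character(GenomicRanges::strand(b$registry)) == "-"]
  occ <- occurrences(cat)
  occMinus <- occ[S4Vectors::mcols(occ)$target == testTarget &
                    as.character(GenomicRanges::strand(occ)) == "-"]
  expect_setequal(GenomicRanges::start(occMinus),
                  GenomicRanges::start(minus))
})

test_that("scanner equals the naive both-strand window oracle", {
  set.seed(21)
  for (rep in 1:20) {
    seqs <- list(chrA = randomGenomeChar(sample(500:2500, 1), gc = runif(1, 0.3, 0.6)))
    g <- Biostrings::DNAStringSet(unlist(seqs))
    expect_same_occurrences(scanPamSites(g), oracleScan(seqs))
  }
  # N-containing windows are excluded
  s <- paste0(randomGenomeChar(100), "N", randomGenomeChar(100))
  g <- Biostrings::DNAStringSet(c(chrN = s))
  expect_same_occurrences(scanPamSites(g), oracleScan(list(chrN = s)))
})

test_that("every reported occurrence slices back to its catalog key", {
  set.seed(22)
  g <- Biostrings::DNAStringSet(c(c1 = randomGenomeChar(3000)))
  cat <- scanPamSites(g)
  occ <- occurrences(cat)
  s <- as.character(g[[1]])
  kmer <- substring(s, GenomicRanges::start(occ), GenomicRanges::end(occ))
  minus <- as.character(GenomicRanges::strand(occ)) == "-"
  kmer[minus] <- oracleRC(kmer[minus])
  expect_identical(kmer, S4Vectors::mcols(occ)$target)
})

test_that("copy-range filter keeps the inclusive 7-25 band", {
  mk <- function(base, n) list(target = base, n = n)
  cat <- manualCatalog(list(
    mk("AAATTTCCCGGGATATATATAGG", 1L),
    mk("CAATTTCCCGGGATATATATAGG", 6L),
    mk("GAATTTCCCGGGATATATATAGG", 7L),
    mk("TAATTTCCCGGGATATATATAGG", 25L),
    mk("ACATTTCCCGGGATATATATAGG", 26L)))
  kept <- filterCopyRange(cat, 7, 25)
  expect_setequal(targetSequences(kept),
                  c("GAATTTCCCGGGATATATATAGG", "TAATTTCCCGGGATATATATAGG"))
  expect_error(filterCopyRange(cat, 25, 7), "lo")
  empty <- TargetCatalog(GenomicRanges::GRanges(target = character()))
  expect_equal(length(filterCopyRange(empty)), 0L)
})

test_that("simple-motif and GC filters follow the printed rules", {
  expect_true(filterSimpleMotif("ACGTACGTACGTACGTACGT"))
  expect_false(filterSimpleMotif("AAAAACGTACGTACGTACGT"))
  expect_true(filterSimpleMotif("AAAACGTACGTACGTACGTA"))  # run of 4 passes
  gc8 <- paste0(strrep("GC", 4), strrep("AT", 6))   # 8/20 = 40%
  gc12 <- paste0(strrep("GC", 6), strrep("AT", 4))  # 12/20 = 60%
  gc13 <- paste0(strrep("GC", 6), "G", strrep("AT", 3), "A")
  expect_true(filterGC(gc8))
  expect_true(filterGC(gc12))
  expect_false(filterGC(gc13))
  expect_false(filterGC(strrep("AT", 10)))
})

test_that("organellar filter matches either strand of the organelles", {
  org <- Biostrings::DNAStringSet(c(
    chrC = paste0(randomGenomeChar(200), testTarget, randomGenomeChar(200))))
  expect_false(filterOrganellar(testTarget, org))
  expect_false(filterOrganellar(oracleRC(testTarget), org))
  other <- "TTTTGGGGCCCCAAAATTTTAGG"
  expect_true(filterOrganellar(other, org))
  expect_true(filterOrganellar(other, Biostrings::DNAStringSet()))
})

test_that("restriction overlap is called at protospacer bases 17-18", {
  enzAlu <- restrictionEnzyme("AluI", "AGCT")
  enzHinf <- restrictionEnzyme("HinfI", "GANTC")
  # AGCT planted at protospacer positions 16-19 covers 17 and 18
  tgHit <- paste0("CCATTACATTCGATA", "AGCT", "ATGG")
  expect_identical(substr(tgHit, 16, 19), "AGCT")
  hits <- annotateRestrictionOverlap(tgHit, list(enzAlu))[[1]]
  expect_true("AluI" %in% hits)
  # motif only at positions 1-4 does not qualify
  tgMiss <- paste0("AGCT", "ATTACATCGATATAT", "ATGG")
  expect_equal(nchar(tgMiss), 23L)
  expect_length(annotateRestrictionOverlap(tgMiss, list(enzAlu))[[1]], 0L)
  # degenerate motif GANTC matching across 15-19 (IUPAC-expansion oracle)
  tgDeg <- paste0("CCATTACATTCGAT", "GACTC", "ATGG")
  expect_equal(nchar(tgDeg), 23L)
  expect_true(oracleIUPACOverlap(tgDeg, "GANTC"))
  expect_true("HinfI" %in%
                annotateRestrictionOverlap(tgDeg, list(enzHinf))[[1]])
  expect_error(restrictionEnzyme("bad", "AGXT"), "malformed IUPAC")
})

test_that("restriction-overlap calls agree with the IUPAC oracle on random targets", {
  set.seed(30)
  enz <- list(restrictionEnzyme("HinfI", "GANTC"),
              restrictionEnzyme("HincII", "GTYRAC"),
              restrictionEnzyme("AluI", "AGCT"))
  tg <- vapply(1:60, function(i)
    paste0(randomGenomeChar(20), "AGG"), "")
  got <- annotateRestrictionOverlap(tg, enz)
  for (i in seq_along(tg)) {
    for (e in enz) {
      expect_equal(e$name %in% got[[i]], oracleIUPACOverlap(tg[i], e$motif),
                   info = paste(tg[i], e$name))
    }
  }
})

test_that("cascade counts are monotone and survivors are order-invariant", {
  gp <- genomePlan(c(chr1 = 20000L),
                   families = list(list(target = testTarget, copies = 8)),
                   organelles = c(chrM = 2000L), seed = 13)
  b <- buildGenome(gp)
  cat <- scanPamSites(b$genome)
  enz <- loadEnzymes()
  cs <- filterCascade(cat, organelles = b$organelles, enzymes = enz)
  expect_true(all(diff(cs$stageCounts) <= 0))
  # lazy and eager evaluation give the same survivors and first-fail labels
  eager <- filterCascade(cat, organelles = b$organelles, enzymes = enz,
                         lazy = FALSE)
  expect_identical(targetSequences(cs$catalog),
                   targetSequences(eager$catalog))
  expect_identical(cs$report$first_fail, eager$report$first_fail)
  # eager flags are independent predicates: survivors equal the
  # intersection of all per-filter passes, regardless of filter order
  fl <- eager$report
  keepOracle <- fl$copy_range & fl$simple_motif & fl$gc & fl$organellar &
    fl$restriction_overlap
  expect_setequal(targetSequences(cs$catalog), fl$target[keepOracle])
  # oracle predicates agree
  expect_equal(fl$gc, unname(oracleGCPass(fl$target)))
  expect_equal(fl$simple_motif, unname(oracleMotifPass(fl$target)))
})

test_that("family selection applies the chromatin-diversity criteria", {
  occ <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 101, 201, 301, 401, 501), width = 23L),
    strand = "+",
    target = rep(c(testTarget, "TTTTGGGGCCCCAAAATTTTAGG"), each = 3))
  cat <- TargetCatalog(occ)
  ann <- data.frame(
    accessibility = c("open", "closed", "closed", "open", "open", "open"),
    domain = c("unmethylated", "RdDM", "heterochromatin",
               "unmethylated", "unmethylated", "RdDM"),
    state = c("4", "8", "8", "1", "1", "1"))
  sel <- selectMCsiteFamilies(cat, ann)
  expect_identical(sel, testTarget)  # second family is all-open, 1 state
  annTwoDomains <- ann
  annTwoDomains$domain[1:3] <- c("unmethylated", "RdDM", "RdDM")
  expect_length(selectMCsiteFamilies(cat, annTwoDomains), 0L)
  annNA <- ann
  annNA$domain[2] <- NA
  expect_error(selectMCsiteFamilies(cat, annNA), "unannotated")
})
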