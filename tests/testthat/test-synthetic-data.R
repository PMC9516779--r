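testTarget <- "ACGTTGCATCAGGATCAGCTTGG"

test_that("built genomes contain planted families exactly as registered", {
  gp <- genomePlan(c(chr1 = 10000L),
                   families = list(list(target = testTarget, copies = 7)),
                   seed = 3)
  b <- buildGenome(gp)
  expect_equal(length(b$registry), 7L)
  # naive string-search oracle: exactly 7 occurrences, fwd + rc combined
  s <- as.character(b$genome[[1]])
  hits <- oracleScan(list(chr1 = s))
  expect_equal(sum(hits$target == testTarget), 7L)
  # every registered locus reproduces the 23-mer on its strand
  for (i in seq_len(7)) {
    s0 <- GenomicRanges::start(b$registry)[i] - 1L
    kmer <- substr(s, s0 + 1L, s0 + 23L)
    if (as.character(GenomicRanges::strand(b$registry))[i] == "-")
      kmer <- oracleRC(kmer)
    expect_identical(kmer, testTarget)
  }
})

test_that("empty plans give empty registries and seeded runs are identical", {
  gp0 <- genomePlan(c(chr1 = 2000L), families = list(), seed = 11)
  expect_equal(length(buildGenome(gp0)$registry), 0L)
  gp <- genomePlan(c(chr1 = 5000L, chr2 = 3000L),
                   families = list(list(target = testTarget, copies = 3)),
                   organelles = c(chrM = 1500L), seed = 42)
  b1 <- buildGenome(gp)
  b2 <- buildGenome(gp)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(as.character(b1$organelles), as.character(b2$organelles))
})

test_that("plan validation rejects bad targets and colliding loci", {
  expect_error(genomePlan(c(chr1 = 1000L),
                          families = list(list(target = "ACGTACGTACGTACGTACGTTAA",
                                               copies = 2))),
               "end in GG")
  loci <- data.frame(chrom = "chr1", start0 = c(100L, 110L),
                     strand = c("+", "+"))
  expect_error(genomePlan(c(chr1 = 1000L),
                          families = list(list(target = testTarget,
                                               loci = loci))),
               "collision")
  lociOut <- data.frame(chrom = "chr1", start0 = 995L, strand = "+")
  expect_error(genomePlan(c(chr1 = 1000L),
                          families = list(list(target = testTarget,
                                               loci = lociOut))),
               "overflow")
})

test_that("cytosine context labeling follows the plant CG/CHG/CHH rules", {
  #        123456789012
  seq <- "ACGACAGCCTAG"
  # pos0 1: C followed by G -> CG; pos0 4: C,A,G -> CHG; pos0 7: C,C,T -> CHH
  expect_equal(cytosineContext(seq, 1L, "+"), "CG")
  expect_equal(cytosineContext(seq, 4L, "+"), "CHG")
  expect_equal(cytosineContext(seq, 7L, "+"), "CHH")
  # minus strand: G at pos0 2, 5'-neighbor on minus is comp of pos0 1 (C)
  expect_equal(cytosineContext(seq, 2L, "-"), "CG")
  # G at pos0 6: forward pos0 5 = A -> comp T (not G); pos0 4 = C -> comp G
  expect_equal(cytosineContext(seq, 6L, "-"), "CHG")
  expect_equal(cytosineContext(seq, 11L, "-"), "CHH")
})

test_that("simulated methylation realizes planned window levels", {
  gp <- genomePlan(c(chr1 = 4000L),
                   families = list(list(target = testTarget, copies = 2)),
                   seed = 5)
  b <- buildGenome(gp)
  win <- data.frame(chrom = "chr1", start0 = 1000L, end0 = 1100L,
                    mCG = 0.6, mCHG = 0.5, mCHH = 0.05)
  cp <- chromatinPlan(win, depth = 200L, seed = 6)
  calls <- simulateMethylation(b$genome, cp)
  expect_true(all(calls$total_count == 200L))
  # weighted recomputation within the binomial bound at depth 200
  expect_lt(abs(oracleWindowMeth(calls, "chr1", 1000, 1100, "CG") - 0.6), 0.05)
  expect_lt(abs(oracleWindowMeth(calls, "chr1", 1000, 1100, "CHG") - 0.5), 0.05)
  expect_lt(abs(oracleWindowMeth(calls, "chr1", 1000, 1100, "CHH") - 0.05), 0.05)
  # degenerate binomial: level 0 gives all-zero methylated counts
  cp0 <- chromatinPlan(data.frame(chrom = "chr1", start0 = 0L, end0 = 300L,
                                  mCG = 0, mCHG = 0, mCHH = 0),
                       depth = 50L, seed = 7)
  calls0 <- simulateMethylation(b$genome, cp0)
  expect_true(all(calls0$mc_count == 0L))
  # emitted records agree with the genome: every '+' record sits on a C
  s <- as.character(b$genome[[1]])
  plus <- calls$strand == "+"
  expect_true(all(substring(s, calls$pos0[plus] + 1L,
                            calls$pos0[plus] + 1L) == "C"))
  expect_true(all(substring(s, calls$pos0[!plus] + 1L,
                            calls$pos0[!plus] + 1L) == "G"))
})

test_that("track simulation realizes planned signal and peaks", {
  gp <- genomePlan(c(chr1 = 5000L), families = list(), seed = 8)
  b <- buildGenome(gp)
  cp <- chromatinPlan(data.frame(chrom = "chr1", start0 = 0L, end0 = 100L,
                                 mCG = 0, mCHG = 0, mCHH = 0),
                      peaks = data.frame(chrom = "chr1", start0 = 1000L,
                                         end0 = 1400L),
                      features = list(
                        sig = data.frame(chrom = "chr1", start0 = 1500L,
                                         end0 = 3000L, mean = 1.0)),
                      noiseSd = 0, seed = 9)
  tr <- simulateTracks(b$genome, cp)
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2240, 2262),
                                 strand = "+")
  expect_equal(unname(featureWindowMeans(site, tr$tracks)[1, 1]), 1.0)
  expect_equal(callAccessibility(site, tr$peaks), "closed")
  siteIn <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1101, 1123))
  expect_equal(callAccessibility(siteIn, tr$peaks), "open")
  expect_error(chromatinPlan(data.frame(chrom = "chr1", start0 = 0L,
                                        end0 = 100L, mCG = 0, mCHG = 0,
                                        mCHH = 0),
                             features = list(bad = data.frame(
                               chrom = "chr1", start0 = 0L, end0 = 10L,
                               mean = -1))),
               "negative planned signal")
})

test_that("amplicon read simulation honors plan classes and rules", {
  set.seed(1)
  ref <- randomGenomeChar(200)
  cut <- 100L
  # null case: all unmodified, no error
  p0 <- editingPlan(500L, 1, 0, seed = 2)
  sim0 <- simulateAmpliconReads(ref, cut, p0)
  expect_true(all(sim0$reads == ref))
  expect_true(all(sim0$truth$class == "unmodified"))
  # templated insertion duplicates the base 5' of the cut
  refT <- paste0(substr(ref, 1, 99), "T", substr(ref, 101, 200))
  pI <- editingPlan(200L, 0, 1, insRule = "templated", seed = 3)
  simI <- simulateAmpliconReads(refT, cut, pI)
  expect_true(all(simI$truth$ins_base == "T"))
  expect_true(all(substr(simI$reads, 101, 101) == "T"))
  # class mix recovered within the multinomial bound
  pM <- editingPlan(10000L, 0, 0.70,
                    c(del_1_5 = 0.20, del_6_10 = 0, del_gt10 = 0.10),
                    seed = 4)
  simM <- simulateAmpliconReads(ref, cut, pM)
  frac <- table(simM$truth$class) / 10000
  expect_lt(abs(frac[["ins1"]] - 0.70), 0.02)
  expect_lt(abs(frac[["del_1_5"]] - 0.20), 0.02)
  expect_lt(abs(frac[["del_gt10"]] - 0.10), 0.02)
  # deletions straddle the cut
  dels <- simM$truth[!is.na(simM$truth$del_len), ]
  expect_true(all(dels$del_start0 < cut & dels$del_start0 + dels$del_len >= cut))
  # guard rails
  expect_error(simulateAmpliconReads(substr(ref, 1, 40), 20L, p0), "short")
  expect_error(simulateAmpliconReads(ref, 10L, p0), "17 bases")
  expect_error(editingPlan(10L, 0.5, 0.4), "sum to 1")
  expect_error(editingPlan(10L, 0.5, 0.5, errorRate = 0.2), "errorRate")
})

test_that("emitted files round-trip through the package readers", {
  gp <- genomePlan(c(chr1 = 3000L),
                   families = list(list(target = testTarget, copies = 2)),
                   seed = 10)
  b <- buildGenome(gp)
  td <- withr::local_tempdir()
  writeGenome(b, file.path(td, "g"))
  back <- Biostrings::readDNAStringSet(file.path(td, "g_nuclear.fa"))
  expect_identical(as.character(back[[1]]), as.character(b$genome[[1]]))
  cp <- chromatinPlan(data.frame(chrom = "chr1", start0 = 500L, end0 = 700L,
                                 mCG = 0.3, mCHG = 0.2, mCHH = 0.1),
                      depth = 30L, seed = 11)
  calls <- simulateMethylation(b$genome, cp)
  writeCytosineCalls(calls, file.path(td, "calls.tsv"))
  expect_equal(readCytosineCalls(file.path(td, "calls.tsv")), calls)
  reads <- c("ACGT", "GGCCTA")
  writeFastq(reads, file.path(td, "r.fastq"))
  expect_equal(readFastq(file.path(td, "r.fastq"))$seq, reads)
  writeSiteRegistry(b$registry, file.path(td, "reg"))
  bed <- readBed(file.path(td, "reg.bed"))
  expect_equal(GenomicRanges::start(bed), GenomicRanges::start(b$registry))
})
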