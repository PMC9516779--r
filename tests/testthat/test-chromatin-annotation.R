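test_that("window methylation is the read-count-weighted mean", {
  calls <- data.frame(chrom = "chr1", pos0 = c(10L, 20L),
                      strand = c("+", "-"), context = "CG",
                      mc_count = c(5L, 5L), total_count = c(10L, 10L))
  w <- windowMethylation(calls)
  expect_equal(w$mCG, 0.5)
  expect_equal(w$nCG, 2L)
  expect_true(is.na(w$mCHH))
  expect_false(w$complete)
  # weighting, not mean-of-fractions: 9/10 and 0/90 -> 9/100
  calls2 <- data.frame(chrom = "chr1", pos0 = c(1L, 2L), strand = "+",
                       context = "CHH", mc_count = c(9L, 0L),
                       total_count = c(10L, 90L))
  expect_equal(windowMethylation(calls2)$mCHH, 0.09)
  expect_error(windowMethylation(data.frame(
    chrom = "chr1", pos0 = 5L, strand = "+", context = "CXX",
    mc_count = 1L, total_count = 2L)), "context")
  expect_error(windowMethylation(calls, seqlengths = c(chr1 = 15L)),
               "outside genome")
})

test_that("window methylation matches the brute-force oracle on synthetic data", {
  gp <- genomePlan(c(chr1 = 2000L), families = list(), seed = 31)
  b <- buildGenome(gp)
  cp <- chromatinPlan(data.frame(chrom = "chr1",
                                 start0 = c(0L, 300L), end0 = c(300L, 700L),
                                 mCG = c(0.6, 0.2), mCHG = c(0.5, 0.1),
                                 mCHH = c(0.05, 0.3)),
                      depth = 40L, seed = 32)
  calls <- simulateMethylation(b$genome, cp)
  w <- windowMethylation(calls)
  for (i in seq_len(nrow(w))) {
    for (ctx in c("CG", "CHG", "CHH")) {
      expect_equal(w[[paste0("m", ctx)]][i],
                   oracleWindowMeth(calls, w$chrom[i], w$start0[i],
                                    w$end0[i], ctx))
    }
  }
})

test_that("domain classification honors the printed threshold rules", {
  expect_equal(classifyDomain(0.05, 0.02, 0.01), "unmethylated")
  expect_equal(classifyDomain(0.60, 0.50, 0.05), "heterochromatin")
  expect_equal(classifyDomain(0.50, 0.30, 0.20), "RdDM")
  expect_equal(classifyDomain(0.15, 0.05, 0.05), "intermediate")
  expect_equal(classifyDomain(0.50, 0.05, 0.05), "CG-only")
  # RdDM precedence over heterochromatin when both rules fire
  expect_equal(classifyDomain(0.60, 0.60, 0.20), "RdDM")
  expect_error(classifyDomain(NA, 0.1, 0.1), "undefined")
  expect_error(classifyDomain(1.2, 0.1, 0.1), "\\[0, 1\\]")
})

test_that("domain labels partition the level cube", {
  g <- seq(0, 1, by = 0.05)
  grid <- expand.grid(mCG = g, mCHG = g, mCHH = g)
  lab <- classifyDomain(grid$mCG, grid$mCHG, grid$mCHH)
  expect_false(anyNA(lab))
  expect_setequal(unique(lab), c("unmethylated", "RdDM", "heterochromatin",
                                 "CG-only", "intermediate"))
  # rule implications hold everywhere
  un <- grid$mCG < 0.10 & grid$mCHG < 0.10 & grid$mCHH < 0.10
  expect_true(all(lab[un] == "unmethylated"))
  expect_true(all(lab[!un & grid$mCHH >= 0.15] == "RdDM"))
  expect_true(all(lab[!un & grid$mCHH < 0.15 &
                        grid$mCG > 0.40 & grid$mCHG > 0.40] ==
                    "heterochromatin"))
})

test_that("accessibility calls use >= 1 bp overlap on half-open intervals", {
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 173))  # [150,173)
  peak <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))  # [100,200)
  expect_equal(callAccessibility(site, peak), "open")
  abut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150))  # [100,150)
  expect_equal(callAccessibility(site, abut), "closed")
  expect_equal(callAccessibility(site, GenomicRanges::GRanges()), "closed")
})

test_that("feature window means weight partial overlaps pro rata", {
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(990, 1012))
  # center0 = 1000, window [500, 1500)
  const <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2000),
                                  score = 1.0)
  expect_equal(unname(featureWindowMeans(site, list(f = const))[1, 1]), 1.0)
  half <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 1000),
                                 score = 2.0)  # [500,1000) = half the window
  expect_equal(unname(featureWindowMeans(site, list(f = half))[1, 1]), 1.0)
  # random piecewise track equals the per-base expansion oracle
  set.seed(41)
  pieces <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(400, 700, 1100, 1400),
                             end = c(650, 1050, 1250, 1600)),
    score = runif(4, 0, 5))
  got <- unname(featureWindowMeans(site, list(f = pieces))[1, 1])
  expect_equal(got, oracleWindowMean(pieces, "chr1", 500, 1500))
  # splitting an interval at an interior point changes nothing
  split1 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(400, 501, 700, 1100, 1400),
                             end = c(500, 650, 1050, 1250, 1600)),
    score = pieces$score[c(1, 1, 2, 3, 4)])
  expect_equal(unname(featureWindowMeans(site, list(f = split1))[1, 1]), got)
})

test_that("feature windows truncate at chromosome bounds with a warning", {
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, 32))
  GenomeInfoDb::seqlengths(site) <- c(chr1 = 5000L)
  tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5000), score = 2)
  expect_warning(m <- featureWindowMeans(site, list(f = tr)), "truncated")
  expect_equal(unname(m[1, 1]), 2)  # constant signal, truncated denominator
})

test_that("per-base methylation reports a 0-100 scale on the target strand", {
  gp <- genomePlan(c(chr1 = 1000L),
                   families = list(list(
                     target = "ACGTTGCATCAGGATCAGCTTGG",
                     loci = data.frame(chrom = "chr1", start0 = 500L,
                                       strand = "+"))),
                   seed = 51)
  b <- buildGenome(gp)
  calls <- data.frame(chrom = "chr1", pos0 = c(501L, 501L, 510L),
                      strand = c("+", "-", "+"), context = "CG",
                      mc_count = c(8L, 4L, 0L), total_count = c(10L, 10L, 5L))
  site <- b$registry[1]
  lv <- perBaseMethylation(site, calls)
  expect_length(lv, 23L)
  expect_equal(lv[2], 60)   # (8+4)/20 both strands combined
  expect_equal(lv[11], 0)
  expect_true(all(is.na(lv[-c(2, 11)])))
  # minus-strand site reads 5'->3' on the target strand (reversed)
  siteMinus <- site
  GenomicRanges::strand(siteMinus) <- "-"
  expect_equal(perBaseMethylation(siteMinus, calls)[22], 60)
})

test_that("min-max normalization maps each feature to [0, 1]", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 1, 2))
  norm <- normalizeFeatures(m)
  expect_equal(unname(norm[, "a"]), c(0, 0.5, 1))
  expect_equal(max(norm[, "b"]), 1)
  expect_equal(min(norm[, "b"]), 0)
  expect_warning(n2 <- normalizeFeatures(cbind(c = c(3, 3, 3))), "constant")
  expect_equal(unname(n2[, 1]), c(0, 0, 0))
  expect_error(normalizeFeatures(matrix(numeric(), 0, 0)), "empty")
})

test_that("site annotation joins domain at the cut-site window", {
  # site on chr1 [100,123) '+': cut0 = 116 -> window [100,200)
  site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 123),
                                 strand = "+")
  names(site) <- "s1"
  windows <- data.frame(chrom = "chr1", start0 = c(0L, 100L),
                        end0 = c(100L, 200L),
                        mCG = c(0, 0.6), mCHG = c(0, 0.5),
                        mCHH = c(0, 0.05),
                        nCG = 1L, nCHG = 1L, nCHH = 1L, complete = TRUE)
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 105))
  st <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500),
                               state = "state7")
  ann <- annotateSites(site, windows, peaks, states = st)
  expect_equal(ann$domain, "heterochromatin")
  expect_equal(ann$accessibility, "open")
  expect_equal(ann$state, "state7")
})
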