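#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern vmatchPattern
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

BASES <- c("A", "C", "G", "T")

rc <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

#' Plan a synthetic genome with planted multicopy CRISPR target families
#'
#' Describes a genome of i.i.d.-background chromosomes with configurable GC
#' content into which identical 23-mer CRISPR targets (20-nt protospacer +
#' NGG PAM) are planted at chosen loci. Optional organellar contigs
#' (chloroplast/mitochondria stand-ins) are flagged by name so downstream
#' filters can treat them separately from nuclear copy counting.
#'
#' Families may specify explicit loci (data.frame with \code{chrom},
#' \code{start0} (0-based), \code{strand}) or just a \code{copies} count, in
#' which case non-overlapping loci are drawn uniformly at plan time using the
#' plan seed.
#'
#' @param chromLengths Named integer vector of chromosome lengths (bp).
#' @param families List of families; each a list with \code{target} (23-mer
#'   ending in GG) and either \code{loci} or \code{copies} (plus optional
#'   \code{chroms} restricting placement).
#' @param organelles Named integer vector of organellar contig lengths
#'   (may be empty).
#' @param gc Background GC fraction in (0, 1).
#' @param seed Integer random seed.
#' @return A validated list of class \code{GenomePlan}.
#' @export
genomePlan <- function(chromLengths, families = list(),
                       organelles = integer(), gc = 0.36, seed = 1L) {
  if (is.null(names(chromLengths)) || any(names(chromLengths) == ""))
    stop("chromLengths must be named")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  set.seed(as.integer(seed))
  taken <- GRanges()
  families <- lapply(seq_along(families), function(i) {
    fam <- families[[i]]
    if (is.null(fam$name)) fam$name <- paste0("fam", i)
    tg <- toupper(fam$target)
    if (nchar(tg) != 23 || grepl("[^ACGT]", tg))
      stop("family target must be a 23-mer over ACGT: ", fam$name)
    if (substr(tg, 22, 23) != "GG")
      stop("family target must end in GG on the stated strand: ", fam$name)
    fam$target <- tg
    if (is.null(fam$loci)) {
      if (is.null(fam$copies)) stop("family needs loci or copies: ", fam$name)
      chroms <- fam$chroms %||% names(chromLengths)
      loci <- .drawLoci(fam$copies, chromLengths[chroms], taken)
      fam$loci <- loci
    }
    fam$loci$strand <- as.character(fam$loci$strand)
    if (!all(fam$loci$strand %in% c("+", "-")))
      stop("locus strand must be '+' or '-': ", fam$name)
    gr <- GRanges(fam$loci$chrom,
                  IRanges(fam$loci$start0 + 1L, width = 23L))
    over <- fam$loci$start0 < 0 |
      fam$loci$start0 + 23L > chromLengths[as.character(fam$loci$chrom)]
    if (any(over))
      stop("locus overflows chromosome in family ", fam$name, ": locus ",
           which(over)[1])
    if (suppressWarnings(
          length(GenomicRanges::findOverlaps(gr, taken)) > 0 ||
          length(GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                             drop.redundant = TRUE)) > 0))
      stop("locus collision (overlapping planted loci) in family ", fam$name)
    taken <<- suppressWarnings(c(taken, gr))
    fam$copies <- nrow(fam$loci)
    fam
  })
  structure(list(chromLengths = chromLengths, families = families,
                 organelles = organelles, gc = gc, seed = as.integer(seed)),
            class = "GenomePlan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.drawLoci <- function(copies, lens, taken) {
  loci <- data.frame(chrom = character(), start0 = integer(),
                     strand = character())
  guard <- 0L
  while (nrow(loci) < copies) {
    guard <- guard + 1L
    if (guard > 10000L) stop("could not place loci without collision")
    ch <- sample(names(lens), 1L)
    s0 <- sample.int(lens[[ch]] - 23L, 1L) - 1L
    cand <- GRanges(ch, IRanges(s0 + 1L, width = 23L))
    placed <- GRanges(loci$chrom, IRanges(loci$start0 + 1L, width = 23L))
    if (suppressWarnings(
          length(GenomicRanges::findOverlaps(cand, c(taken, placed)))) == 0L)
      loci <- rbind(loci, data.frame(chrom = ch, start0 = s0,
                                     strand = sample(c("+", "-"), 1L)))
  }
  loci
}

.randomSeq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Build a synthetic genome from a GenomePlan
#'
#' Chromosome backgrounds are i.i.d. with the planned GC fraction; each
#' planted 23-mer is written at its registered locus (reverse-complemented
#' into the forward strand for minus-strand loci). The background is then
#' rejection-sampled: any accidental exact copy of a planted
#' protospacer+PAM (either strand) outside the registry is re-randomized, so
#' genome-wide occurrence counts are exactly as planned.
#'
#' @param plan A [genomePlan()].
#' @return A list with \code{genome} (nuclear \code{DNAStringSet} with
#'   seqlengths), \code{organelles} (\code{DNAStringSet}, possibly empty) and
#'   \code{registry} (a \code{GRanges} of planted loci with metadata columns
#'   \code{target}, \code{family}; coordinates 1-based as usual for GRanges,
#'   use [writeSiteRegistry()] for 0-based BED output).
#' @export
buildGenome <- function(plan) {
  stopifnot(inherits(plan, "GenomePlan"))
  set.seed(plan$seed)
  chroms <- lapply(plan$chromLengths, .randomSeq, gc = plan$gc)
  regs <- list()
  for (fam in plan$families) {
    fwd <- ifelse(fam$loci$strand == "+", fam$target, rc(fam$target))
    for (i in seq_len(nrow(fam$loci))) {
      ch <- as.character(fam$loci$chrom[i])
      s0 <- fam$loci$start0[i]
      substr(chroms[[ch]], s0 + 1L, s0 + 23L) <- fwd[i]
    }
    regs[[fam$name]] <- GRanges(fam$loci$chrom,
                                IRanges(fam$loci$start0 + 1L, width = 23L),
                                strand = fam$loci$strand,
                                target = fam$target, family = fam$name)
  }
  registry <- if (length(regs)) suppressWarnings(do.call(c, unname(regs))) else
    GRanges(target = character(), family = character())
  genome <- DNAStringSet(unlist(chroms))
  names(genome) <- names(plan$chromLengths)
  genome <- .scrubCollisions(genome, plan, registry)
  seqlengths(genome) <- plan$chromLengths[names(genome)]
  org <- DNAStringSet(vapply(plan$organelles, .randomSeq, "", gc = plan$gc))
  names(org) <- names(plan$organelles)
  list(genome = genome, organelles = org, registry = registry)
}

# Re-randomize background stretches that accidentally spell a planted 23-mer.
.scrubCollisions <- function(genome, plan, registry) {
  targets <- unique(vapply(plan$families, `[[`, "", "target"))
  if (!length(targets)) return(genome)
  for (iter in 1:50) {
    dirty <- FALSE
    for (tg in targets) {
      for (pat in unique(c(tg, rc(tg)))) {
        hits <- vmatchPattern(pat, genome)
        for (ch in names(genome)) {
          ir <- hits[[ch]]
          if (!length(ir)) next
          gr <- GRanges(ch, ir)
          planted <- GenomicRanges::countOverlaps(gr, registry,
                                                  type = "equal") > 0
          for (j in which(!planted)) {
            dirty <- TRUE
            s <- as.character(genome[[ch]])
            substr(s, start(ir)[j], start(ir)[j] + 22L) <-
              .randomSeq(23L, plan$gc)
            genome[[ch]] <- DNAString(s)
          }
        }
      }
    }
    if (!dirty) return(genome)
  }
  stop("failed to scrub accidental target copies after 50 passes")
}

#' Plan chromatin context around planted loci
#'
#' @param windows data.frame with \code{chrom}, \code{start0}, \code{end0}
#'   (0-based half-open) and target weighted methylation levels \code{mCG},
#'   \code{mCHG}, \code{mCHH} in \[0, 1\].
#' @param depth Integer read depth for simulated cytosine calls (>= 1).
#' @param peaks data.frame with \code{chrom}, \code{start0}, \code{end0}:
#'   accessibility peak intervals (0-based half-open, start < end).
#' @param features Named list; each element a data.frame with \code{chrom},
#'   \code{start0}, \code{end0}, \code{mean} giving the planned signal level
#'   over that region for one feature track.
#' @param noiseSd Standard deviation of seeded Gaussian noise added per
#'   bedGraph bin (default 0).
#' @param seed Integer random seed.
#' @return A validated list of class \code{ChromatinPlan}.
#' @export
chromatinPlan <- function(windows, depth = 100L, peaks = NULL,
                          features = list(), noiseSd = 0, seed = 1L) {
  lv <- as.matrix(windows[, c("mCG", "mCHG", "mCHH")])
  if (any(lv < 0 | lv > 1)) stop("methylation levels must be in [0, 1]")
  if (depth < 1) stop("depth must be >= 1")
  if (!is.null(peaks) && nrow(peaks) &&
      any(peaks$start0 >= peaks$end0))
    stop("peak intervals must satisfy start < end")
  if (anyDuplicated(names(features))) stop("feature names must be unique")
  for (nm in names(features))
    if (any(features[[nm]]$mean < 0))
      stop("negative planned signal for feature ", nm)
  structure(list(windows = windows, depth = as.integer(depth),
                 peaks = peaks, features = features, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "ChromatinPlan")
}

#' Classify cytosine context at given forward-strand positions
#'
#' Plant methylation contexts: a cytosine followed by G is CG; followed by a
#' non-G then G is CHG; anything else is CHH. On the minus strand the same
#' logic applies to the reverse complement. Internal helper, exported for
#' oracle-style checking.
#'
#' @param seq Character, one chromosome sequence.
#' @param pos0 Integer vector of 0-based positions of cytosines (base C on
#'   '+', base G on '-').
#' @param strand "+" or "-" (recycled).
#' @return Character vector in \{"CG","CHG","CHH"\} (NA where the 2-bp
#'   context window runs off the sequence end).
#' @export
cytosineContext <- function(seq, pos0, strand) {
  n <- nchar(seq)
  strand <- rep_len(strand, length(pos0))
  b <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- p >= 0 & p < n
    out[ok] <- substring(seq, p[ok] + 1L, p[ok] + 1L)
    out
  }
  ctx <- rep(NA_character_, length(pos0))
  plus <- strand == "+"
  n1 <- ifelse(plus, b(pos0 + 1L), chartr("ACGT", "TGCA", b(pos0 - 1L)))
  n2 <- ifelse(plus, b(pos0 + 2L), chartr("ACGT", "TGCA", b(pos0 - 2L)))
  ctx[!is.na(n1) & n1 == "G"] <- "CG"
  ctx[!is.na(n1) & n1 != "G" & !is.na(n2) & n2 == "G"] <- "CHG"
  ctx[!is.na(n1) & n1 != "G" & !is.na(n2) & n2 != "G"] <- "CHH"
  ctx
}

#' Simulate per-cytosine methylation calls
#'
#' For every cytosine (both strands) inside each planned window, emits a
#' bisulfite-style call record with methylated count drawn
#' Binomial(depth, planned level) for the cytosine's context. Window-level
#' weighted recomputation converges to the plan as depth grows.
#'
#' @param genome \code{DNAStringSet} (nuclear genome).
#' @param plan A [chromatinPlan()].
#' @return data.frame with columns \code{chrom}, \code{pos0}, \code{strand},
#'   \code{context}, \code{mc_count}, \code{total_count}.
#' @export
simulateMethylation <- function(genome, plan) {
  stopifnot(inherits(plan, "ChromatinPlan"))
  set.seed(plan$seed)
  out <- list()
  for (i in seq_len(nrow(plan$windows))) {
    w <- plan$windows[i, ]
    ch <- as.character(w$chrom)
    if (!ch %in% names(genome)) stop("window chromosome not in genome: ", ch)
    L <- nchar(as.character(genome[[ch]]))
    if (w$start0 < 0 || w$end0 > L)
      stop("window outside genome: ", ch, ":", w$start0, "-", w$end0)
    seq <- as.character(genome[[ch]])
    sub <- substring(seq, w$start0 + 1L, w$end0)
    chars <- strsplit(sub, "")[[1]]
    posC <- w$start0 + which(chars == "C") - 1L
    posG <- w$start0 + which(chars == "G") - 1L
    if (!length(posC) && !length(posG)) {
      warning("window with no cytosines on either strand skipped: ",
              ch, ":", w$start0, "-", w$end0)
      next
    }
    pos0 <- c(posC, posG)
    strand <- rep(c("+", "-"), c(length(posC), length(posG)))
    ctx <- cytosineContext(seq, pos0, strand)
    keep <- !is.na(ctx)
    pos0 <- pos0[keep]; strand <- strand[keep]; ctx <- ctx[keep]
    level <- c(CG = w$mCG, CHG = w$mCHG, CHH = w$mCHH)[ctx]
    mc <- stats::rbinom(length(pos0), plan$depth, level)
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, pos0 = pos0, strand = strand, context = ctx,
      mc_count = mc, total_count = plan$depth)
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos0 = integer(),
                      strand = character(), context = character(),
                      mc_count = integer(), total_count = integer()))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos0, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Simulate accessibility peaks and chromatin-feature signal tracks
#'
#' Peaks are passed through as a \code{GRanges}; each planned feature region
#' is tiled into fixed-width bedGraph bins whose value is the planned mean
#' plus seeded Gaussian noise (truncated at 0).
#'
#' @param genome \code{DNAStringSet} (for bounds checking).
#' @param plan A [chromatinPlan()].
#' @param binWidth bedGraph bin width in bp (default 50).
#' @return list with \code{peaks} (\code{GRanges}) and \code{tracks} (named
#'   list of \code{GRanges} with a \code{score} column, bedGraph-style).
#' @export
simulateTracks <- function(genome, plan, binWidth = 50L) {
  stopifnot(inherits(plan, "ChromatinPlan"))
  set.seed(plan$seed + 1L)
  peaks <- GRanges()
  if (!is.null(plan$peaks) && nrow(plan$peaks))
    peaks <- GRanges(plan$peaks$chrom,
                     IRanges(plan$peaks$start0 + 1L, plan$peaks$end0))
  tracks <- lapply(plan$features, function(reg) {
    grl <- lapply(seq_len(nrow(reg)), function(i) {
      s <- seq(reg$start0[i], reg$end0[i] - 1L, by = binWidth)
      e <- pmin(s + binWidth, reg$end0[i])
      val <- pmax(0, reg$mean[i] + stats::rnorm(length(s), 0, plan$noiseSd))
      GRanges(reg$chrom[i], IRanges(s + 1L, e), score = val)
    })
    suppressWarnings(do.call(c, grl))
  })
  list(peaks = peaks, tracks = tracks)
}

#' Plan an edited amplicon read set
#'
#' @param totalReads Integer number of reads to emit.
#' @param pUnmodified,pIns1 Proportions of unmodified reads and of +1 bp
#'   insertion reads.
#' @param pDel Named numeric over deletion-size bins \code{del_1_5},
#'   \code{del_6_10}, \code{del_gt10}. All proportions must sum to 1.
#' @param insRule "templated" (duplicate the base 5' of the cut) or a fixed
#'   single base, e.g. "A".
#' @param delSizes Named list giving the candidate deletion sizes drawn
#'   (uniformly) within each bin. Defaults mimic the recurrent-allele
#'   structure of real per-site repair outcomes, where a handful of
#'   deletion alleles dominate: \code{del_1_5} = 1:5, \code{del_6_10} =
#'   6:10, \code{del_gt10} = c(12, 15).
#' @param placement "anchored" (default): a deletion of size L always
#'   removes the same block straddling the cut, so each size is one
#'   recurrent allele; "random": the block start is drawn uniformly among
#'   placements overlapping the cut.
#' @param errorRate Per-base substitution sequencing-error probability,
#'   in \[0, 0.05\].
#' @param seed Integer random seed.
#' @return A validated list of class \code{EditingPlan}.
#' @export
editingPlan <- function(totalReads, pUnmodified, pIns1,
                        pDel = c(del_1_5 = 0, del_6_10 = 0, del_gt10 = 0),
                        insRule = "templated",
                        delSizes = list(del_1_5 = 1:5, del_6_10 = 6:10,
                                        del_gt10 = c(12L, 15L)),
                        placement = c("anchored", "random"),
                        errorRate = 0, seed = 1L) {
  placement <- match.arg(placement)
  pDel <- pDel[c("del_1_5", "del_6_10", "del_gt10")]
  pDel[is.na(pDel)] <- 0
  names(pDel) <- c("del_1_5", "del_6_10", "del_gt10")
  tot <- pUnmodified + pIns1 + sum(pDel)
  if (abs(tot - 1) > 1e-9) stop("class proportions must sum to 1, got ", tot)
  if (errorRate < 0 || errorRate > 0.05)
    stop("errorRate must be in [0, 0.05]")
  if (!identical(insRule, "templated") &&
      !(is.character(insRule) && nchar(insRule) == 1 &&
        insRule %in% BASES))
    stop("insRule must be 'templated' or a single base")
  bounds <- list(del_1_5 = c(1L, 5L), del_6_10 = c(6L, 10L),
                 del_gt10 = c(11L, Inf))
  for (bin in names(bounds)) {
    sz <- delSizes[[bin]]
    if (is.null(sz) || !length(sz) ||
        any(sz < bounds[[bin]][1] | sz > bounds[[bin]][2]))
      stop("delSizes$", bin, " must lie within its bin")
  }
  structure(list(totalReads = as.integer(totalReads),
                 pUnmodified = pUnmodified, pIns1 = pIns1, pDel = pDel,
                 insRule = insRule, delSizes = delSizes,
                 placement = placement,
                 errorRate = errorRate, seed = as.integer(seed)),
            class = "EditingPlan")
}

#' Simulate edited amplicon reads with a truth log
#'
#' Reads are drawn by outcome class according to the plan. +1 bp alleles
#' insert one base at the cut junction (templated = duplicate of the base
#' immediately 5' of the cut, mirroring staggered-cut fill-in repair);
#' deletion alleles remove a contiguous block overlapping the cut with size
#' drawn uniformly within the planned bin. Substitution errors are applied
#' after editing. Quality is constant Phred+33 'I'.
#'
#' @param amplicon Character or \code{DNAString}, the reference amplicon
#'   (>= 50 bp).
#' @param cutIndex Integer, number of reference bases 5' of the cut
#'   (0-based junction index); must be >= 17 bases from either end.
#' @param plan An [editingPlan()].
#' @return list with \code{reads} (character vector), \code{truth}
#'   (data.frame: read_id, class, del_len, del_start0, ins_base).
#' @export
simulateAmpliconReads <- function(amplicon, cutIndex, plan) {
  stopifnot(inherits(plan, "EditingPlan"))
  ref <- toupper(as.character(amplicon))
  L <- nchar(ref)
  if (L < 50) stop("amplicon too short to profile (< 50 bp)")
  if (cutIndex < 17 || L - cutIndex < 17)
    stop("cut index must be >= 17 bases from either amplicon end")
  set.seed(plan$seed)
  classes <- c("unmodified", "ins1", names(plan$pDel))
  probs <- c(plan$pUnmodified, plan$pIns1, plan$pDel)
  cls <- sample(classes, plan$totalReads, replace = TRUE, prob = probs)
  insBase <- if (identical(plan$insRule, "templated"))
    substring(ref, cutIndex, cutIndex) else plan$insRule
  reads <- character(plan$totalReads)
  delLen <- rep(NA_integer_, plan$totalReads)
  delStart <- rep(NA_integer_, plan$totalReads)
  insb <- rep(NA_character_, plan$totalReads)
  for (i in seq_len(plan$totalReads)) {
    ci <- cls[i]
    if (ci == "unmodified") {
      reads[i] <- ref
    } else if (ci == "ins1") {
      reads[i] <- paste0(substring(ref, 1, cutIndex), insBase,
                         substring(ref, cutIndex + 1, L))
      insb[i] <- insBase
    } else {
      sz <- plan$delSizes[[ci]]
      len <- if (length(sz) == 1L) sz else sample(sz, 1L)
      s0 <- if (plan$placement == "anchored") cutIndex - ceiling(len / 2)
        else cutIndex - sample.int(len, 1L)  # block straddles the junction
      s0 <- max(0L, min(s0, L - len))
      reads[i] <- paste0(substring(ref, 1, s0),
                         substring(ref, s0 + len + 1L, L))
      delLen[i] <- len
      delStart[i] <- s0
    }
  }
  if (plan$errorRate > 0) {
    reads <- vapply(reads, function(r) {
      n <- nchar(r)
      hit <- which(stats::runif(n) < plan$errorRate)
      if (!length(hit)) return(r)
      ch <- strsplit(r, "")[[1]]
      ch[hit] <- vapply(ch[hit],
                        function(b) sample(setdiff(BASES, b), 1L), "")
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  }
  truth <- data.frame(read_id = sprintf("read%06d", seq_along(reads)),
                      class = cls, del_len = delLen, del_start0 = delStart,
                      ins_base = insb)
  list(reads = reads, truth = truth)
}
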