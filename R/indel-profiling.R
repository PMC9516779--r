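NULL

MUT_CLASSES <- c("ins1", "del_1_5", "del_6_10", "del_gt10")

#' Describe an amplicon and its CRISPR cut site
#'
#' Locates the 20-nt protospacer in the reference amplicon (forward, then
#' reverse complement) and derives the 0-based cut junction index: Cas9
#' cleaves between protospacer positions 17 and 18, 3 bp 5' of the PAM.
#'
#' @param reference Reference amplicon sequence (character or
#'   \code{DNAString}).
#' @param protospacer 20-nt protospacer sequence (5'->3' on the target
#'   strand).
#' @param siteId Site identifier.
#' @return list of class \code{AmpliconSpec} with \code{reference},
#'   \code{protoStart0}, \code{protoStrand}, \code{cutIndex} (number of
#'   reference bases 5' of the cut) and \code{siteId}.
#' @export
ampliconSpec <- function(reference, protospacer, siteId = "site") {
  ref <- toupper(as.character(reference))
  proto <- toupper(as.character(protospacer))
  if (nchar(proto) != 20) stop("protospacer must be 20 nt")
  if (nchar(ref) < 50) stop("amplicon too short to profile (< 50 bp)")
  p <- regexpr(proto, ref, fixed = TRUE)[1]
  if (p > 0) {
    strand <- "+"
    cut <- (p - 1L) + 17L  # junction after protospacer base 17
    pam <- substring(ref, p + 21L, p + 22L)
  } else {
    p <- regexpr(rc(proto), ref, fixed = TRUE)[1]
    if (p < 0) stop("protospacer not found in amplicon (either strand)")
    strand <- "-"
    # 23-mer occupies forward [p-3, p+19] 1-based; proto minus positions
    # 17/18 map to forward 0-based (p-1)+2 / (p-1)+1 -> junction index p+1
    cut <- (p - 1L) + 3L
    pam <- rc(substring(ref, p - 3L, p - 2L))
  }
  if (!identical(pam, "GG"))
    warning("no NGG PAM adjacent to the located protospacer")
  if (cut < 1L || cut >= nchar(ref))
    stop("cut index not interior to the amplicon")
  structure(list(reference = ref, protoStart0 = p - 1L,
                 protoStrand = strand, cutIndex = cut, siteId = siteId),
            class = "AmpliconSpec")
}

# Left-normalize an indel: shift the gap left while the flanking base
# matches, so equivalent gap placements have a canonical (leftmost) form.
.leftShiftDel <- function(ref, s0, len) {
  while (s0 > 0 &&
         substring(ref, s0, s0) == substring(ref, s0 + len, s0 + len))
    s0 <- s0 - 1L
  s0
}

.leftShiftIns <- function(ref, j, bases) {
  # insertion of `bases` at junction j (0-based); rotate left while the
  # base 5' of the junction equals the last inserted base
  while (j > 0 && substring(ref, j, j) ==
         substring(bases, nchar(bases), nchar(bases))) {
    bases <- paste0(substring(bases, nchar(bases), nchar(bases)),
                    substring(bases, 1, nchar(bases) - 1))
    j <- j - 1L
  }
  list(pos = j, bases = bases)
}

# Convert one raw op list from the C aligner into a left-normalized
# edit-script data.frame.
.normalizeOps <- function(raw, ref) {
  if (!length(raw$op))
    return(data.frame(op = character(), pos0 = integer(), len = integer(),
                      bases = character()))
  op <- raw$op; pos0 <- raw$pos0; len <- raw$len; bases <- raw$bases
  for (k in seq_along(op)) {
    if (op[k] == "D") {
      pos0[k] <- .leftShiftDel(ref, pos0[k], len[k])
      bases[k] <- NA_character_
    } else if (op[k] == "I") {
      norm <- .leftShiftIns(ref, pos0[k], bases[k])
      pos0[k] <- norm$pos
      bases[k] <- norm$bases
    }
  }
  data.frame(op = op, pos0 = pos0, len = len, bases = bases)
}

#' Globally align amplicon reads to the reference
#'
#' Needleman-Wunsch (Gotoh) global alignment with mild affine gap costs
#' (match +1, mismatch -1, gap of length L costs 1 + L; N is neutral),
#' deterministic traceback, followed by left-normalization of every indel
#' so that equivalent gap placements resolve to the leftmost position.
#' Reads with characters outside A/C/G/T/N, or with length outside
#' \[0.5x, 1.5x\] the reference length, are discarded as unalignable.
#'
#' @param reads Character vector of (merged) amplicon reads.
#' @param spec An [ampliconSpec()].
#' @return list with \code{scripts} (list of edit-op data.frames - columns
#'   \code{op} (I/D/X), \code{pos0}, \code{len}, \code{bases} - one per
#'   kept read), \code{kept} (indices of kept reads), \code{discarded}
#'   (count).
#' @export
alignReads <- function(reads, spec) {
  al <- .alignUnique(reads, spec)
  list(scripts = al$scripts[al$map], kept = al$kept,
       discarded = al$discarded)
}

# Align only the distinct read sequences; `map` expands back to kept reads.
.alignUnique <- function(reads, spec) {
  stopifnot(inherits(spec, "AmpliconSpec"))
  ref <- spec$reference
  L <- nchar(ref)
  okAlpha <- !grepl("[^ACGTN]", reads)
  okLen <- nchar(reads) >= 0.5 * L & nchar(reads) <= 1.5 * L
  kept <- which(okAlpha & okLen)
  if (!length(kept))
    return(list(scripts = list(), map = integer(), kept = integer(),
                discarded = length(reads)))
  uniq <- unique(reads[kept])
  exact <- uniq == ref
  scripts <- vector("list", length(uniq))
  empty <- data.frame(op = character(), pos0 = integer(), len = integer(),
                      bases = character())
  for (i in which(exact)) scripts[[i]] <- empty
  todo <- which(!exact)
  if (length(todo)) {
    raw <- .nwAlignOps(uniq[todo], ref, 1, -1, 1, 1)
    for (k in seq_along(todo))
      scripts[[todo[k]]] <- .normalizeOps(raw[[k]], ref)
  }
  names(scripts) <- uniq
  list(scripts = scripts, map = match(reads[kept], uniq), kept = kept,
       discarded = length(reads) - length(kept))
}

#' Classify an aligned allele into a mutation-outcome class
#'
#' An allele is "edited" iff it carries at least one insertion or deletion
#' overlapping the quantification window \[cut - w, cut + w\] around the
#' cut junction; indels entirely outside that window, and substitutions,
#' leave a read unedited. Edited alleles are labeled \code{ins1} (+1 bp)
#' iff they carry a net single 1-bp insertion and no deletion; alleles with
#' any deletion are binned by total deleted length into \code{del_1_5},
#' \code{del_6_10}, \code{del_gt10}. Pure multi-bp insertions fall into an
#' \code{ins_other} overflow class kept out of the four printed classes.
#'
#' @param ops Edit-op data.frame from [alignReads()].
#' @param spec An [ampliconSpec()].
#' @param window Half-width w of the quantification window (default 10 bp).
#' @return One of "unmodified", "ins1", "del_1_5", "del_6_10", "del_gt10",
#'   "ins_other".
#' @export
classifyAllele <- function(ops, spec, window = 10L) {
  j <- spec$cutIndex
  if (!nrow(ops)) return("unmodified")
  ins <- ops[ops$op == "I", , drop = FALSE]
  del <- ops[ops$op == "D", , drop = FALSE]
  insIn <- ins[ins$pos0 >= j - window & ins$pos0 <= j + window, ,
               drop = FALSE]
  delIn <- del[del$pos0 <= j + window & del$pos0 + del$len >= j - window, ,
               drop = FALSE]
  if (!nrow(insIn) && !nrow(delIn)) return("unmodified")
  dlen <- sum(delIn$len)
  ilen <- sum(insIn$len)
  if (dlen == 0) {
    if (ilen == 1) return("ins1")
    return("ins_other")
  }
  if (dlen <= 5) "del_1_5" else if (dlen <= 10) "del_6_10" else "del_gt10"
}

.alleleSignature <- function(ops, spec, window = 10L) {
  j <- spec$cutIndex
  ins <- ops[ops$op == "I" & ops$pos0 >= j - window & ops$pos0 <= j + window,
             , drop = FALSE]
  del <- ops[ops$op == "D" & ops$pos0 <= j + window &
               ops$pos0 + ops$len >= j - window, , drop = FALSE]
  parts <- c(sprintf("I:%d:%s", ins$pos0, ins$bases),
             sprintf("D:%d:%d", del$pos0, del$len))
  if (!length(parts)) "REF" else paste(sort(parts), collapse = "|")
}

#' Profile editing outcomes for one amplicon
#'
#' Aligns reads, groups them into alleles by their indel signature within
#' the quantification window (so substitution sequencing errors do not
#' fragment alleles), and computes: the overall indel frequency (edited /
#' classified reads x 100, no allele threshold), and the mutation-class
#' distribution + insertion rate over mutant alleles after removing alleles
#' whose share of classified reads falls below the allele threshold
#' (default 2\%, applied to mutation-profile composition only).
#'
#' @param reads Character vector of reads (or a FASTQ path, read with
#'   [readFastq()]).
#' @param spec An [ampliconSpec()].
#' @param threshold Minimum allele share of classified reads (default 0.02).
#' @param window Quantification-window half-width (default 10 bp).
#' @return A [MutationProfile-class].
#' @export
profileAmplicon <- function(reads, spec, threshold = 0.02, window = 10L) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- readFastq(reads)$seq
  total <- length(reads)
  al <- .alignUnique(reads, spec)
  if (!length(al$kept)) stop("zero alignable reads")
  uSig <- vapply(al$scripts, .alleleSignature, "", spec = spec,
                 window = window)
  uCls <- vapply(al$scripts, classifyAllele, "", spec = spec,
                 window = window)
  sig <- uSig[al$map]
  n <- length(al$kept)
  tab <- as.data.frame(table(signature = sig), stringsAsFactors = FALSE)
  tab$class <- uCls[match(tab$signature, uSig)]
  tab$count <- tab$Freq; tab$Freq <- NULL
  tab$share <- tab$count / n
  tab <- tab[order(-tab$count, tab$signature), ]
  rownames(tab) <- NULL
  edited <- sum(tab$count[tab$class != "unmodified"])
  indelFreq <- 100 * edited / n
  mut <- tab[tab$class %in% c(MUT_CLASSES, "ins_other") &
               tab$share >= threshold, , drop = FALSE]
  printed <- mut[mut$class %in% MUT_CLASSES, , drop = FALSE]
  cd <- stats::setNames(rep(NA_real_, 4), MUT_CLASSES)
  if (nrow(printed)) {
    tot <- sum(printed$count)
    for (cl in MUT_CLASSES)
      cd[cl] <- 100 * sum(printed$count[printed$class == cl]) / tot
  }
  new("MutationProfile", siteId = spec$siteId, totalReads = as.integer(total),
      classifiedReads = as.integer(n), discardedReads = as.integer(al$discarded),
      indelFrequency = indelFreq, classDistribution = cd,
      insertionRate = unname(cd["ins1"]), normalizedFrequency = NA_real_,
      alleles = tab)
}

#' Normalize an indel frequency to a positive-control site
#'
#' Divides the site indel frequency by the indel frequency of the
#' single-copy euchromatic control target measured in the same replicate,
#' x 100. Values above 100 are permitted (site edited more than the
#' control). A control frequency of 0 leaves the replicate undefined
#' (NA, with a warning) so it can be flagged and excluded.
#'
#' @param site A [MutationProfile-class] or numeric indel frequency (\%).
#' @param control A [MutationProfile-class] or numeric indel frequency (\%).
#' @return If \code{site} is a profile, the profile with
#'   \code{normalizedFrequency} set; else the numeric normalized
#'   frequency (\%).
#' @export
normalizeFrequency <- function(site, control) {
  sf <- if (is(site, "MutationProfile")) site@indelFrequency else site
  cf <- if (is(control, "MutationProfile")) control@indelFrequency else
    control
  if (is.na(cf) || cf == 0) {
    warning("control indel frequency is 0; replicate flagged as undefined")
    nf <- NA_real_
  } else nf <- 100 * sf / cf
  if (is(site, "MutationProfile")) {
    site@normalizedFrequency <- nf
    site
  } else nf
}

#' Fold change between two frequencies
#'
#' @param high,low Numeric frequencies (low must be > 0).
#' @return \code{high / low}, rounded to 2 decimals; NA with a warning when
#'   \code{low} is 0.
#' @export
foldChange <- function(high, low) {
  if (any(low == 0, na.rm = TRUE)) {
    warning("fold change undefined for zero denominator")
    return(ifelse(low == 0, NA_real_, round(high / low, 2)))
  }
  round(high / low, 2)
}
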