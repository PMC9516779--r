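#' @importFrom Biostrings readDNAStringSet
NULL

#' Scan a genome for all 20-nt + NGG CRISPR target sites
#'
#' Finds every position on both strands where a 20-mer is immediately
#' followed by an NGG PAM, and catalogs the distinct 23-mers with their
#' genomic occurrences. Windows containing any non-ACGT base are excluded.
#' Reverse-strand occurrences are reported with forward-strand coordinates
#' covering the same 23 bases and strand "-"; the catalog key is always the
#' 23-mer read 5'->3' on the target strand.
#'
#' @param genome \code{DNAStringSet} (nuclear chromosomes) or path to a
#'   FASTA file.
#' @return A [TargetCatalog-class].
#' @export
scanPamSites <- function(genome) {
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  occ <- list()
  for (ch in names(genome)) {
    seq <- toupper(as.character(genome[[ch]]))
    L <- nchar(seq)
    if (L < 23) next
    # forward: 23-mer at s..s+22 (1-based) with GG at s+21, s+22
    gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1]]
    gg <- gg[gg > 0]
    s <- gg - 21L
    s <- s[s >= 1L]
    if (length(s)) {
      kmer <- substring(seq, s, s + 22L)
      ok <- !grepl("[^ACGT]", kmer)
      if (any(ok))
        occ[[length(occ) + 1L]] <- data.frame(
          chrom = ch, start = s[ok], strand = "+", target = kmer[ok])
    }
    # reverse: forward CC at s, s+1 means the minus-strand 23-mer spanning
    # forward [s, s+22] ends in GG
    cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1]]
    cc <- cc[cc > 0]
    s <- cc[cc + 22L <= L]
    if (length(s)) {
      kmer <- substring(seq, s, s + 22L)
      ok <- !grepl("[^ACGT]", kmer)
      if (any(ok))
        occ[[length(occ) + 1L]] <- data.frame(
          chrom = ch, start = s[ok], strand = "-", target = rc(kmer[ok]))
    }
  }
  if (!length(occ))
    return(TargetCatalog(GRanges(target = character())))
  df <- do.call(rbind, occ)
  gr <- GRanges(df$chrom, IRanges(df$start, width = 23L),
                strand = df$strand, target = df$target)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  TargetCatalog(gr)
}

#' Copy-number band filter
#'
#' Retains distinct targets whose genome-wide occurrence count lies in
#' \code{[lo, hi]} (bounds inclusive); the multicopy band used for
#' identical-site discovery is 7-25 copies.
#'
#' @param catalog A [TargetCatalog-class].
#' @param lo,hi Inclusive copy-number bounds (defaults 7 and 25).
#' @return A subsetted \code{TargetCatalog}.
#' @export
filterCopyRange <- function(catalog, lo = 7L, hi = 25L) {
  if (lo > hi) stop("lo must be <= hi")
  cn <- copyNumber(catalog)
  subsetCatalog(catalog, names(cn)[cn >= lo & cn <= hi])
}

#' Simple-motif (homopolymer) filter
#'
#' A protospacer fails if it contains a run of 5 or more identical bases
#' (5 As, Ts, Gs, or Cs in a row).
#'
#' @param sequence Character vector of 20-nt protospacers (or 23-mers; the
#'   first 20 nt are used).
#' @param maxRun Run length that triggers failure (default 5).
#' @return Logical vector: TRUE = pass.
#' @export
filterSimpleMotif <- function(sequence, maxRun = 5L) {
  proto <- substr(sequence, 1L, 20L)
  pat <- sprintf("A{%d}|C{%d}|G{%d}|T{%d}", maxRun, maxRun, maxRun, maxRun)
  !grepl(pat, proto)
}

#' GC-content filter
#'
#' A protospacer passes iff its GC fraction is within \code{[lo, hi]},
#' bounds inclusive (default 40\%-60\%; on 20 nt that is 8-12 G/C bases, so
#' the comparison is exact in integers).
#'
#' @param sequence Character vector of 20-nt protospacers (or 23-mers; the
#'   first 20 nt are used).
#' @param lo,hi GC-fraction bounds (defaults 0.40, 0.60).
#' @return Logical vector: TRUE = pass.
#' @export
filterGC <- function(sequence, lo = 0.40, hi = 0.60) {
  proto <- substr(sequence, 1L, 20L)
  gc <- nchar(gsub("[^GC]", "", proto))
  n <- nchar(proto)
  gc >= lo * n - 1e-9 & gc <= hi * n + 1e-9
}

#' Organellar-presence filter
#'
#' A target fails if its full 23-mer (protospacer+PAM) occurs anywhere in
#' any organellar (chloroplast/mitochondrial) sequence, on either strand.
#'
#' @param sequence Character vector of 23-mers.
#' @param organelles \code{DNAStringSet} of organellar contigs (possibly
#'   empty) or path to a FASTA file.
#' @return Logical vector: TRUE = pass (not found in organelles).
#' @export
filterOrganellar <- function(sequence, organelles) {
  if (is.character(organelles) && length(organelles) == 1 &&
      file.exists(organelles))
    organelles <- readDNAStringSet(organelles)
  if (is.null(organelles) || length(organelles) == 0)
    return(rep(TRUE, length(sequence)))
  k <- unique(nchar(sequence))
  if (length(k) != 1) stop("sequences must have a single common length")
  # enumerate every k-mer of the organellar forward strands once; a target
  # is present on the reverse strand iff its reverse complement is in the
  # forward k-mer set
  kmers <- unlist(lapply(names(organelles), function(nm) {
    s <- toupper(as.character(organelles[[nm]]))
    if (nchar(s) < k) return(character())
    substring(s, seq_len(nchar(s) - k + 1L),
              seq_len(nchar(s) - k + 1L) + k - 1L)
  }))
  !(sequence %in% kmers | rc(sequence) %in% kmers)
}

IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT", S = "CG",
           W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT", H = "ACT",
           V = "ACG", N = "ACGT")

#' Construct a restriction enzyme record
#'
#' @param name Enzyme name.
#' @param motif Recognition motif as an IUPAC string.
#' @return list of class \code{RestrictionEnzyme}.
#' @export
restrictionEnzyme <- function(name, motif) {
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], names(IUPAC))
  if (length(bad))
    stop("malformed IUPAC motif for enzyme ", name, ": ",
         paste(bad, collapse = ""))
  structure(list(name = name, motif = motif, length = nchar(motif)),
            class = "RestrictionEnzyme")
}

#' Load a restriction enzyme table
#'
#' Reads a two-column TSV (name, IUPAC motif). With no argument, loads the
#' bundled table of common commercially available enzymes.
#'
#' @param path Path to a TSV; default = bundled table.
#' @return list of [restrictionEnzyme()] records.
#' @export
loadEnzymes <- function(path = system.file("extdata",
                                           "restriction_enzymes.tsv",
                                           package = "epicrispr")) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i)
    restrictionEnzyme(df$name[i], df$motif[i]))
}

#' Annotate restriction-site overlap with the cut position
#'
#' Cas9 cleaves between protospacer positions 17 and 18 (3 bp 5' of the
#' PAM), so an indel there destroys any restriction motif covering base 17
#' or 18 - the basis of CAPS genotyping. For each target, returns the
#' enzymes with a motif occurrence (either strand, IUPAC-expanded) within
#' the 23-mer that covers protospacer base 17 or 18 (1-based from the 5'
#' end; PAM at 21-23). Targets with no such enzyme are dropped by the
#' candidate cascade.
#'
#' @param sequence Character vector of 23-mers.
#' @param enzymes list of [restrictionEnzyme()] records.
#' @return list (one element per sequence) of character vectors of enzyme
#'   names; zero-length where no motif covers the cut region.
#' @export
annotateRestrictionOverlap <- function(sequence, enzymes) {
  subj <- DNAStringSet(sequence)
  hitNames <- vector("list", length(sequence))
  for (enz in enzymes) {
    if (!inherits(enz, "RestrictionEnzyme"))
      enz <- restrictionEnzyme(enz$name, enz$motif)
    for (pat in unique(c(enz$motif, rc(enz$motif)))) {
      if (nchar(pat) > 23) next
      m <- vmatchPattern(pat, subj, fixed = FALSE)
      for (i in seq_along(subj)) {
        ir <- m[[i]]
        if (!length(ir)) next
        # covers base 17 or 18 <=> start <= 18 and end >= 17
        if (any(start(ir) <= 18L & end(ir) >= 17L))
          hitNames[[i]] <- union(hitNames[[i]], enz$name)
      }
    }
  }
  lapply(hitNames, function(x) if (is.null(x)) character() else x)
}

#' Run the candidate filter cascade
#'
#' Applies, in order: copy-number band (7-25), homopolymer simple-motif
#' filter, GC filter (40-60\% inclusive), organellar-presence filter, and
#' (when enzymes are supplied) the restriction-overlap requirement. All
#' filters are independent predicates, so the surviving set is
#' order-invariant; the report additionally records, per sequence, the
#' first failing filter in cascade order and the count surviving each stage.
#'
#' @param catalog A [TargetCatalog-class] (from [scanPamSites()] on nuclear
#'   chromosomes only; organellar sequences are never part of copy
#'   counting).
#' @param lo,hi Copy-number bounds.
#' @param maxRun Homopolymer run triggering the simple-motif filter.
#' @param gcLo,gcHi GC bounds.
#' @param organelles \code{DNAStringSet} or FASTA path (NULL = skip).
#' @param enzymes list of [restrictionEnzyme()] (NULL = skip the
#'   restriction-overlap stage).
#' @param lazy When TRUE (default) the organellar and restriction-overlap
#'   predicates - the expensive ones - are only evaluated for sequences
#'   that pass the cheap filters; their flags are NA for sequences already
#'   removed. \code{lazy = FALSE} evaluates every predicate on every
#'   sequence (useful for checking order-invariance on small catalogs).
#'   The surviving set and first-fail labels are identical either way.
#' @return list with \code{catalog} (surviving subset), \code{report} (a
#'   data.frame: target, copies, per-filter logical columns,
#'   \code{first_fail}), \code{stageCounts} (named non-increasing integer
#'   vector) and \code{enzymeHits} (named list for survivors of the
#'   cascade).
#' @export
filterCascade <- function(catalog, lo = 7L, hi = 25L, maxRun = 5L,
                          gcLo = 0.40, gcHi = 0.60, organelles = NULL,
                          enzymes = NULL, lazy = TRUE) {
  tg <- targetSequences(catalog)
  cn <- copyNumber(catalog)[tg]
  if (lo > hi) stop("lo must be <= hi")
  passCopy <- cn >= lo & cn <= hi
  passMotif <- filterSimpleMotif(tg, maxRun)
  passGC <- filterGC(tg, gcLo, gcHi)
  reached <- passCopy & passMotif & passGC
  evalOn <- if (lazy) which(reached) else seq_along(tg)
  passOrg <- rep(NA, length(tg))
  passOrg[evalOn] <- if (is.null(organelles)) TRUE else
    filterOrganellar(tg[evalOn], organelles)
  hits <- NULL
  passRE <- rep(NA, length(tg))
  evalRE <- if (lazy) which(reached & passOrg %in% TRUE) else seq_along(tg)
  if (is.null(enzymes)) {
    passRE[evalRE] <- TRUE
  } else if (length(evalRE)) {
    hits <- annotateRestrictionOverlap(tg[evalRE], enzymes)
    passRE[evalRE] <- lengths(hits) > 0
    hits <- stats::setNames(hits, tg[evalRE])
  }
  flags <- cbind(copy_range = passCopy, simple_motif = passMotif,
                 gc = passGC, organellar = passOrg,
                 restriction_overlap = passRE)
  firstFail <- rep(NA_character_, length(tg))
  firstFail[passRE %in% FALSE] <- "restriction_overlap"
  firstFail[passOrg %in% FALSE] <- "organellar"
  firstFail[!passGC] <- "gc"
  firstFail[!passMotif] <- "simple_motif"
  firstFail[!passCopy] <- "copy_range"
  keep <- reached & passOrg %in% TRUE & passRE %in% TRUE
  stages <- c(scanned = length(tg),
              copy_range = sum(passCopy),
              simple_motif = sum(passCopy & passMotif),
              gc = sum(reached),
              organellar = sum(reached & passOrg %in% TRUE),
              restriction_overlap = sum(keep))
  report <- data.frame(target = tg, copies = as.integer(cn), flags,
                       first_fail = firstFail, row.names = NULL)
  out <- list(catalog = subsetCatalog(catalog, tg[keep]), report = report,
              stageCounts = stages)
  if (!is.null(hits)) out$enzymeHits <- hits[tg[keep]]
  out
}

#' Select multicopy families with diverse chromatin contexts
#'
#' A family (one distinct target sequence with several genomic copies) is
#' selected iff its member sites span both open and closed chromatin, at
#' least three distinct DNA-methylation domain labels, and at least two
#' distinct chromatin-state labels.
#'
#' @param catalog A [TargetCatalog-class].
#' @param annotations data.frame aligned with \code{occurrences(catalog)}
#'   (one row per occurrence, same order) with columns
#'   \code{accessibility} ("open"/"closed"), \code{domain}, \code{state}.
#' @param minDomains,minStates Diversity thresholds (defaults 3 and 2).
#' @return Character vector of selected target sequences.
#' @export
selectMCsiteFamilies <- function(catalog, annotations, minDomains = 3L,
                                 minStates = 2L) {
  occ <- occurrences(catalog)
  if (nrow(annotations) != length(occ))
    stop("annotations must have one row per occurrence")
  need <- c("accessibility", "domain", "state")
  if (!all(need %in% colnames(annotations)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  miss <- which(apply(is.na(annotations[, need]), 1, any))
  if (length(miss))
    stop("unannotated member site: ",
         paste0(seqnames(occ)[miss[1]], ":", start(occ)[miss[1]] - 1L))
  fam <- split(seq_along(occ), mcols(occ)$target)
  sel <- vapply(fam, function(idx) {
    a <- annotations[idx, ]
    any(a$accessibility == "open") && any(a$accessibility == "closed") &&
      length(unique(a$domain)) >= minDomains &&
      length(unique(a$state)) >= minStates
  }, logical(1))
  names(fam)[sel]
}
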