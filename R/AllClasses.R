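#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' TargetCatalog: distinct CRISPR targets and their genomic occurrences
#'
#' A catalog of 23-mer CRISPR-Cas9 targets (20-nt protospacer + NGG PAM)
#' found in a genome. Occurrences are stored as a \code{GRanges} over the
#' forward strand (width 23, 1-based as usual for \code{GRanges}); the
#' \code{strand} column records the target strand, and \code{mcols()$target}
#' holds the 23-mer read 5'->3' on that strand. Distinctness is by literal
#' 23-mer: a sequence and its reverse complement are separate catalog keys,
#' because Cas9 targeting is strand-specific.
#'
#' @slot occurrences \code{GRanges} with metadata column \code{target}
#'   (character, 23-mer protospacer+PAM on the target strand).
#' @slot targets \code{DataFrame} with columns \code{target} and
#'   \code{copies}; one row per distinct 23-mer, copies equals the number of
#'   occurrences of that 23-mer.
#'
#' @seealso [scanPamSites()], [filterCascade()]
#' @export
setClass("TargetCatalog",
  representation(occurrences = "GRanges", targets = "DataFrame"))

setValidity("TargetCatalog", function(object) {
  occ <- object@occurrences
  tg <- object@targets
  if (!"target" %in% colnames(mcols(occ)))
    return("occurrences must carry a 'target' metadata column")
  if (!all(c("target", "copies") %in% colnames(tg)))
    return("targets must have 'target' and 'copies' columns")
  if (anyDuplicated(tg$target))
    return("targets$target must be unique")
  cnt <- table(mcols(occ)$target)
  if (length(occ) && !identical(sort(names(cnt)), sort(as.character(tg$target))))
    return("targets and occurrences disagree on the set of distinct 23-mers")
  if (length(occ) && any(as.integer(cnt[as.character(tg$target)]) != tg$copies))
    return("copies must equal occurrence-list length per target")
  bad <- substr(tg$target, 22, 23) != "GG"
  if (any(bad)) return("every catalog key must end in GG (NGG PAM)")
  TRUE
})

#' Construct a TargetCatalog from an occurrence GRanges
#'
#' @param occurrences \code{GRanges} with a \code{target} metadata column
#'   (23-mer on the target strand); width must be 23 throughout.
#' @return A [TargetCatalog-class] object.
#' @export
TargetCatalog <- function(occurrences) {
  if (length(occurrences) && any(width(occurrences) != 23L))
    stop("all occurrences must have width 23")
  tg <- mcols(occurrences)$target
  tab <- table(tg)
  targets <- DataFrame(target = names(tab), copies = as.integer(tab))
  if (!length(occurrences))
    targets <- DataFrame(target = character(), copies = integer())
  new("TargetCatalog", occurrences = occurrences, targets = targets)
}

#' @describeIn TargetCatalog Number of distinct target sequences.
#' @param x,object A \code{TargetCatalog}.
#' @export
setMethod("length", "TargetCatalog", function(x) nrow(x@targets))

#' Accessors for TargetCatalog
#'
#' \code{occurrences()} returns the occurrence \code{GRanges};
#' \code{targetSequences()} the distinct 23-mers; \code{copyNumber()} a named
#' integer vector of genomic occurrence counts per distinct 23-mer.
#'
#' @param x A [TargetCatalog-class].
#' @return See individual descriptions.
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
occurrences <- function(x) x@occurrences

#' @rdname catalog-accessors
#' @export
targetSequences <- function(x) as.character(x@targets$target)

#' @rdname catalog-accessors
#' @export
copyNumber <- function(x) {
  stats::setNames(as.integer(x@targets$copies), as.character(x@targets$target))
}

#' Subset a catalog to a set of target sequences
#'
#' @param x A [TargetCatalog-class].
#' @param targets Character vector of 23-mers to keep.
#' @return A new \code{TargetCatalog} restricted to \code{targets}.
#' @export
subsetCatalog <- function(x, targets) {
  keep <- mcols(x@occurrences)$target %in% targets
  TargetCatalog(x@occurrences[keep])
}

setMethod("show", "TargetCatalog", function(object) {
  cat("TargetCatalog with", nrow(object@targets), "distinct targets and",
      length(object@occurrences), "genomic occurrences\n")
  if (nrow(object@targets)) {
    cn <- copyNumber(object)
    cat("  copy numbers:", paste(range(cn), collapse = "-"), "\n")
  }
})

#' MutationProfile: editing outcome summary for one amplicon
#'
#' Per-site summary of CRISPR editing outcomes called from amplicon reads:
#' overall indel frequency, the mutation-class distribution over
#' \{+1 bp, del 1-5, del 6-10, del >10\} as percent of retained mutant reads,
#' the insertion rate (the +1 bp class share), and, once a control is
#' supplied, the control-normalized frequency (which may exceed 100).
#'
#' @slot siteId character site identifier.
#' @slot totalReads integer, reads supplied.
#' @slot classifiedReads integer, reads surviving alignment filters.
#' @slot discardedReads integer, reads discarded (length/alphabet).
#' @slot indelFrequency numeric, percent of classified reads carrying an
#'   indel within the quantification window (no allele threshold applied).
#' @slot classDistribution named numeric over the four printed classes,
#'   percent of retained mutant reads (sums to 100 when any exist).
#' @slot insertionRate numeric, percent of retained mutant reads that are
#'   +1 bp insertions (equals \code{classDistribution["ins1"]}).
#' @slot normalizedFrequency numeric, site indel frequency / control indel
#'   frequency x 100 (NA until [normalizeFrequency()] is applied).
#' @slot alleles data.frame of allele signatures with counts, shares and
#'   class labels (includes alleles later removed by the share threshold).
#' @export
setClass("MutationProfile",
  representation(siteId = "character", totalReads = "integer",
                 classifiedReads = "integer", discardedReads = "integer",
                 indelFrequency = "numeric", classDistribution = "numeric",
                 insertionRate = "numeric", normalizedFrequency = "numeric",
                 alleles = "data.frame"))

setValidity("MutationProfile", function(object) {
  cd <- object@classDistribution
  want <- c("ins1", "del_1_5", "del_6_10", "del_gt10")
  if (!identical(names(cd), want))
    return(paste("classDistribution must be named", paste(want, collapse = ", ")))
  if (!all(is.na(cd)) && abs(sum(cd) - 100) > 0.01 && sum(cd) != 0)
    return("classDistribution must sum to 100 (or be all-NA/zero)")
  TRUE
})

#' @describeIn MutationProfile Overall indel frequency (percent).
#' @param x A \code{MutationProfile}.
#' @export
indelFrequency <- function(x) x@indelFrequency

#' @describeIn MutationProfile Class distribution (percent of mutant reads).
#' @export
classDistribution <- function(x) x@classDistribution

#' @describeIn MutationProfile Insertion rate (percent of mutant reads).
#' @export
insertionRate <- function(x) x@insertionRate

#' @describeIn MutationProfile Allele table.
#' @export
alleleTable <- function(x) x@alleles

setMethod("show", "MutationProfile", function(object) {
  cat("MutationProfile for", object@siteId, "\n")
  cat(sprintf("  reads: %d total, %d classified, %d discarded\n",
              object@totalReads, object@classifiedReads, object@discardedReads))
  cat(sprintf("  indel frequency: %.2f%%", object@indelFrequency))
  if (!is.na(object@normalizedFrequency))
    cat(sprintf("  (normalized: %.2f%%)", object@normalizedFrequency))
  cat("\n  class distribution (% of mutant reads):\n")
  print(round(object@classDistribution, 2))
})
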