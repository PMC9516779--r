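#' @importFrom GenomicRanges findOverlaps countOverlaps pintersect tileGenome
NULL

METH_CONTEXTS <- c("CG", "CHG", "CHH")

#' Windowed weighted methylation levels
#'
#' Tiles each chromosome into non-overlapping windows (100 bp by default;
#' the trailing window may be partial) and computes, per window and context,
#' the weighted methylation level: sum of methylated read counts divided by
#' sum of total read counts over all cytosines of that context in the
#' window, both strands combined. Read-count weighting is the standard
#' convention for plant methylomes and is robust to uneven coverage. Levels
#' are NA where a context has zero coverage; such windows are flagged.
#'
#' @param calls data.frame of per-cytosine calls: \code{chrom}, \code{pos0}
#'   (0-based), \code{strand}, \code{context} in CG/CHG/CHH,
#'   \code{mc_count}, \code{total_count}.
#' @param seqlengths Optional named vector of chromosome lengths; when
#'   given, calls outside the genome are an error and trailing windows are
#'   truncated.
#' @param windowSize Window width in bp (default 100).
#' @return data.frame, one row per window with any coverage: \code{chrom},
#'   \code{start0}, \code{end0}, \code{mCG}, \code{mCHG}, \code{mCHH},
#'   per-context informative-cytosine counts \code{nCG}, \code{nCHG},
#'   \code{nCHH}, and \code{complete} (TRUE iff all three contexts covered).
#' @export
windowMethylation <- function(calls, seqlengths = NULL, windowSize = 100L) {
  if (!all(calls$context %in% METH_CONTEXTS))
    stop("invalid context value(s): ",
         paste(setdiff(unique(calls$context), METH_CONTEXTS), collapse = ","))
  if (!is.null(seqlengths)) {
    bad <- calls$pos0 < 0 |
      calls$pos0 >= seqlengths[as.character(calls$chrom)]
    if (any(bad, na.rm = TRUE) || anyNA(bad))
      stop("call positioned outside genome at row ",
           which(bad | is.na(bad))[1])
  }
  if (!nrow(calls))
    return(data.frame(chrom = character(), start0 = integer(),
                      end0 = integer(), mCG = numeric(), mCHG = numeric(),
                      mCHH = numeric(), nCG = integer(), nCHG = integer(),
                      nCHH = integer(), complete = logical()))
  ws <- (calls$pos0 %/% windowSize) * windowSize
  key <- paste(calls$chrom, ws, sep = "\r")
  agg <- function(ctx) {
    sel <- calls$context == ctx
    mc <- rowsum(calls$mc_count[sel], key[sel])
    tt <- rowsum(calls$total_count[sel], key[sel])
    nn <- rowsum(rep(1L, sum(sel)), key[sel])
    list(mc = drop(mc), total = drop(tt), n = drop(nn))
  }
  keys <- sort(unique(key))
  out <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  res <- data.frame(chrom = out[, 1], start0 = as.integer(out[, 2]))
  res$end0 <- res$start0 + windowSize
  if (!is.null(seqlengths))
    res$end0 <- pmin(res$end0, as.integer(seqlengths[res$chrom]))
  for (ctx in METH_CONTEXTS) {
    a <- agg(ctx)
    lvl <- rep(NA_real_, length(keys))
    n <- rep(0L, length(keys))
    idx <- match(names(a$mc), keys)
    lvl[idx] <- a$mc / a$total
    n[idx] <- as.integer(a$n)
    res[[paste0("m", ctx)]] <- lvl
    res[[paste0("n", ctx)]] <- n
  }
  res$complete <- !is.na(res$mCG) & !is.na(res$mCHG) & !is.na(res$mCHH)
  rownames(res) <- NULL
  res
}

#' Classify a DNA-methylation domain from window-level mC
#'
#' Pure, precedence-ordered classification of a 100-bp window from its
#' weighted (mCG, mCHG, mCHH):
#' \enumerate{
#'   \item unmethylated: all three levels < 10\%;
#'   \item RdDM: mCHH >= 15\%;
#'   \item heterochromatin: mCG > 40\% and mCHG > 40\%;
#'   \item CG-only: mCG > 40\% with mCHG < 10\% and mCHH < 10\%;
#'   \item intermediate: everything else with data.
#' }
#' The published rules overlap (a window can satisfy both the RdDM and
#' heterochromatin conditions); RdDM takes precedence because it is defined
#' by mCHH. The mCHG/mCHH ceilings on CG-only disambiguate it from
#' heterochromatin. The five labels partition the unit cube.
#'
#' @param mCG,mCHG,mCHH Numeric vectors of weighted levels in \[0, 1\];
#'   must be defined (no NA) - exclude or flag no-data windows first.
#' @return Character vector of domain labels.
#' @export
classifyDomain <- function(mCG, mCHG, mCHH) {
  n <- max(length(mCG), length(mCHG), length(mCHH))
  mCG <- rep_len(mCG, n); mCHG <- rep_len(mCHG, n); mCHH <- rep_len(mCHH, n)
  if (anyNA(mCG) || anyNA(mCHG) || anyNA(mCHH))
    stop("undefined methylation level; exclude no-data windows first")
  if (any(c(mCG, mCHG, mCHH) < 0 | c(mCG, mCHG, mCHH) > 1))
    stop("methylation levels must be in [0, 1]")
  out <- rep("intermediate", n)
  out[mCG > 0.40 & mCHG < 0.10 & mCHH < 0.10] <- "CG-only"
  out[mCG > 0.40 & mCHG > 0.40] <- "heterochromatin"
  out[mCHH >= 0.15] <- "RdDM"
  out[mCG < 0.10 & mCHG < 0.10 & mCHH < 0.10] <- "unmethylated"
  out
}

#' Call accessibility of target sites from ATAC-style peaks
#'
#' A site is "open" iff at least one peak interval overlaps its 23-mer
#' interval by >= 1 bp (half-open abutment is no overlap), else "closed".
#'
#' @param sites \code{GRanges} of 23-mer site intervals.
#' @param peaks \code{GRanges} of peaks, or a BED file path.
#' @return Character vector "open"/"closed", one per site.
#' @export
callAccessibility <- function(sites, peaks) {
  if (is.character(peaks)) peaks <- readBed(peaks)
  ifelse(countOverlaps(sites, peaks, ignore.strand = TRUE) > 0,
         "open", "closed")
}

#' Mean chromatin-feature signal in 1-kb windows around sites
#'
#' For each site, takes the window from 500 bp upstream to 500 bp
#' downstream of the site center (the floor midpoint of the 23-mer) and
#' computes the coverage-weighted mean of each bedGraph track over it.
#' Intervals partially overlapping the window contribute pro rata; bases
#' with no coverage count as signal 0. Windows running past a chromosome
#' end are truncated with a warning.
#'
#' @param sites \code{GRanges} of 23-mer site intervals (with seqlengths if
#'   truncation should be detected).
#' @param tracks Named list of bedGraph-style \code{GRanges} (with
#'   \code{score}), or named character vector of bedGraph file paths.
#' @param flank Half-width of the window in bp (default 500).
#' @return Numeric matrix, sites x features (raw, unnormalized).
#' @export
featureWindowMeans <- function(sites, tracks, flank = 500L) {
  if (is.character(tracks))
    tracks <- lapply(tracks, readBedGraph)
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be named")
  center0 <- (start(sites) - 1L) + 11L  # floor midpoint of the 23-bp site
  ws <- center0 - flank
  we <- center0 + flank
  sl <- seqlengths(sites)[as.character(seqnames(sites))]
  clip <- pmax(ws, 0L)
  clipEnd <- we
  if (!all(is.na(sl))) clipEnd <- pmin(we, ifelse(is.na(sl), we, sl))
  if (any(clip != ws | clipEnd != we))
    warning("feature window truncated at chromosome bounds for ",
            sum(clip != ws | clipEnd != we), " site(s)")
  win <- GRanges(seqnames(sites), IRanges(clip + 1L, clipEnd))
  mat <- matrix(0, length(sites), length(tracks),
                dimnames = list(names(sites), names(tracks)))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    hits <- findOverlaps(win, tr, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- pintersect(win[S4Vectors::queryHits(hits)],
                       tr[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
      contrib <- width(ov) * tr$score[S4Vectors::subjectHits(hits)]
      sums <- rowsum(contrib, S4Vectors::queryHits(hits))
      idx <- as.integer(rownames(sums))
      mat[idx, j] <- drop(sums)
    }
    mat[, j] <- mat[, j] / width(win)
  }
  mat
}

#' Per-base methylation across a 23-bp target site
#'
#' For each of the 23 positions of a site (5'->3' on the target strand),
#' the weighted methylation level at that base - combining calls on either
#' strand at the same genomic position - on a 0-100 scale; NA for positions
#' with no cytosine call on either strand (e.g. A/T bases).
#'
#' @param site \code{GRanges} of length 1, width 23 (strand respected).
#' @param calls Per-cytosine call data.frame (see [windowMethylation()]).
#' @return Numeric vector of length 23 (0-100 scale, NA = no data).
#' @export
perBaseMethylation <- function(site, calls) {
  stopifnot(length(site) == 1, width(site) == 23)
  pos0 <- (start(site) - 1L):(end(site) - 1L)
  sel <- calls$chrom == as.character(seqnames(site)) & calls$pos0 %in% pos0
  sub <- calls[sel, ]
  lvl <- rep(NA_real_, 23L)
  if (nrow(sub)) {
    mc <- rowsum(sub$mc_count, sub$pos0)
    tt <- rowsum(sub$total_count, sub$pos0)
    idx <- match(as.integer(rownames(mc)), pos0)
    lvl[idx] <- 100 * drop(mc) / drop(tt)
  }
  if (as.character(strand(site)) == "-") lvl <- rev(lvl)
  lvl
}

#' Min-max normalize a feature matrix to 0-1
#'
#' Each column is rescaled as (x - min) / (max - min), so 1 marks the site
#' with the highest level of that feature and 0 the lowest. Constant
#' columns map to all-0 with a warning.
#'
#' @param mat Numeric matrix, sites x features, >= 2 rows.
#' @return Matrix of the same shape on \[0, 1\].
#' @export
normalizeFeatures <- function(mat) {
  if (is.null(dim(mat)) || nrow(mat) == 0 || ncol(mat) == 0)
    stop("empty feature matrix")
  if (nrow(mat) < 2) stop("need >= 2 sites to normalize")
  out <- apply(mat, 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) {
      warning("constant feature column mapped to 0", call. = FALSE)
      rep(0, length(x))
    } else (x - rng[1]) / diff(rng)
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Assemble per-site chromatin annotations
#'
#' Convenience wrapper joining, for each target site: the methylation
#' domain of the single 100-bp tiling window containing the cut site
#' (between protospacer positions 17 and 18), the accessibility call, a
#' chromatin-state label (consumed verbatim from a precomputed interval
#' annotation), and raw + normalized feature means.
#'
#' @param sites \code{GRanges} of 23-mer sites (strand-aware).
#' @param windows Output of [windowMethylation()].
#' @param peaks \code{GRanges} of accessibility peaks.
#' @param tracks Named list of bedGraph \code{GRanges} (may be empty).
#' @param states Optional \code{GRanges} with a \code{state} metadata
#'   column; a site takes the state of the first interval overlapping it.
#' @param windowSize Methylation tiling width (default 100).
#' @return data.frame: one row per site with \code{domain},
#'   \code{accessibility}, \code{state}, and feature columns; the
#'   normalized matrix is in attribute \code{"normalized"}.
#' @export
annotateSites <- function(sites, windows, peaks, tracks = list(),
                          states = NULL, windowSize = 100L) {
  cut0 <- cutPosition(sites)
  key <- paste(seqnames(sites), (cut0 %/% windowSize) * windowSize)
  wkey <- paste(windows$chrom, windows$start0)
  idx <- match(key, wkey)
  domain <- rep(NA_character_, length(sites))
  ok <- !is.na(idx) & !is.na(windows$complete[pmax(idx, 1L)]) &
    windows$complete[pmax(idx, 1L)]
  if (any(ok))
    domain[ok] <- classifyDomain(windows$mCG[idx[ok]],
                                 windows$mCHG[idx[ok]],
                                 windows$mCHH[idx[ok]])
  acc <- callAccessibility(sites, peaks)
  state <- rep(NA_character_, length(sites))
  if (!is.null(states)) {
    h <- findOverlaps(sites, states, ignore.strand = TRUE, select = "first")
    state[!is.na(h)] <- as.character(states$state[h[!is.na(h)]])
  }
  ann <- data.frame(site = names(sites) %||% as.character(seq_along(sites)),
                    domain = domain, accessibility = acc, state = state)
  if (length(tracks)) {
    raw <- featureWindowMeans(sites, tracks)
    ann <- cbind(ann, as.data.frame(raw))
    attr(ann, "normalized") <- normalizeFeatures(raw)
  }
  ann
}

#' 0-based position of the base 5' of the Cas9 cut
#'
#' The blunt Cas9 cut falls between protospacer positions 17 and 18, i.e.
#' 3 bp 5' of the PAM. For a forward-strand 23-mer starting at 0-based s,
#' the returned position is s+16 (protospacer base 17); for a minus-strand
#' site it is the mirrored forward coordinate.
#'
#' @param sites \code{GRanges} of width-23 site intervals with strand.
#' @return Integer vector of 0-based genomic positions.
#' @export
cutPosition <- function(sites) {
  s0 <- start(sites) - 1L
  ifelse(as.character(strand(sites)) == "-", s0 + 6L, s0 + 16L)
}
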