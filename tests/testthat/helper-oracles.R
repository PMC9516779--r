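# Independent oracles used across tests: deliberately naive implementations
# (substring enumeration, per-base expansion) that share no code with the
# package's scanning/aggregation paths.

oracleRC <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""), "", USE.NAMES = FALSE))
}

# enumerate every 23-bp window on both strands and keep NGG-ended targets
oracleScan <- function(seqs) {
  out <- list()
  for (ch in names(seqs)) {
    s <- seqs[[ch]]
    L <- nchar(s)
    if (L < 23) next
    starts <- seq_len(L - 22L)
    win <- substring(s, starts, starts + 22L)
    ok <- !grepl("[^ACGT]", win)
    fwd <- ok & substring(win, 22L, 23L) == "GG"
    if (any(fwd))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts[fwd], strand = "+", target = win[fwd])
    rcw <- oracleRC(win)
    rev <- ok & substring(rcw, 22L, 23L) == "GG"
    if (any(rev))
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = starts[rev], strand = "-", target = rcw[rev])
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), target = character()))
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand), ]
}

# predicate oracles for the filter cascade, written from the rules directly
oracleGCPass <- function(target) {
  proto <- strsplit(substr(target, 1, 20), "")
  vapply(proto, function(p) {
    gc <- sum(p %in% c("G", "C"))
    gc >= 8 && gc <= 12
  }, logical(1))
}

oracleMotifPass <- function(target) {
  vapply(strsplit(substr(target, 1, 20), ""), function(p) {
    max(rle(p)$lengths) < 5
  }, logical(1))
}

oracleOrganellePass <- function(target, orgSeqs) {
  if (!length(orgSeqs)) return(rep(TRUE, length(target)))
  vapply(target, function(tg) {
    for (s in orgSeqs) {
      if (grepl(tg, s, fixed = TRUE)) return(FALSE)
      if (grepl(oracleRC(tg), s, fixed = TRUE)) return(FALSE)
    }
    TRUE
  }, logical(1), USE.NAMES = FALSE)
}

# IUPAC motif occurrence oracle: expand the motif to all literal strings
# and test every offset of the 23-mer (both strands of the motif)
oracleIUPACOverlap <- function(target, motif) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  expand <- function(m) {
    parts <- codes[strsplit(m, "")[[1]]]
    apply(do.call(expand.grid, parts), 1, paste, collapse = "")
  }
  lits <- unique(c(expand(motif), oracleRC(expand(motif))))
  ml <- nchar(motif)
  for (off in seq_len(23 - ml + 1)) {
    piece <- substr(target, off, off + ml - 1)
    if (piece %in% lits && off <= 18 && off + ml - 1 >= 17) return(TRUE)
  }
  FALSE
}

# per-base expansion oracle for coverage-weighted window means
oracleWindowMean <- function(track, chrom, start0, end0) {
  vals <- rep(0, end0 - start0)
  for (i in seq_along(track)) {
    if (as.character(GenomicRanges::seqnames(track))[i] != chrom) next
    s0 <- GenomicRanges::start(track)[i] - 1L
    e0 <- GenomicRanges::end(track)[i]
    for (p in seq(max(s0, start0), min(e0, end0) - 1L))
      if (p >= start0 && p < end0)
        vals[p - start0 + 1L] <- vals[p - start0 + 1L] + track$score[i]
  }
  mean(vals)
}

# brute-force weighted window methylation from raw calls
oracleWindowMeth <- function(calls, chrom, start0, end0, context) {
  sel <- calls$chrom == chrom & calls$pos0 >= start0 & calls$pos0 < end0 &
    calls$context == context
  if (!any(sel)) return(NA_real_)
  sum(calls$mc_count[sel]) / sum(calls$total_count[sel])
}

randomGenomeChar <- function(n, gc = 0.4) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

asCharGenome <- function(dss) {
  stats::setNames(lapply(names(dss), function(n) as.character(dss[[n]])),
                  names(dss))
}

catalogAsDf <- function(catalog) {
  occ <- occurrences(catalog)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(occ)),
                   start = GenomicRanges::start(occ),
                   strand = as.character(GenomicRanges::strand(occ)),
                   target = S4Vectors::mcols(occ)$target)
  df[order(df$chrom, df$start, df$strand), ]
}

expect_same_occurrences <- function(catalog, oracleDf) {
  got <- catalogAsDf(catalog)
  rownames(got) <- rownames(oracleDf) <- NULL
  expect_equal(got, oracleDf)
}
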