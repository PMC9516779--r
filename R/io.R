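#' @importFrom rtracklayer import export
#' @importFrom jsonlite write_json read_json toJSON fromJSON
NULL

#' Read / write BED intervals
#'
#' Thin wrappers over \code{rtracklayer} keeping the package's 0-based BED
#' convention at file boundaries (GRanges in memory are 1-based as usual).
#'
#' @param path File path.
#' @param gr \code{GRanges} to write.
#' @return \code{readBed} returns a \code{GRanges}; a malformed line raises
#'   an error naming the offending line number.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(starts) | is.na(ends) | starts >= ends)
  if (length(bad)) stop("malformed BED line ", bad[1], " in ", path)
  GRanges(vapply(fields, `[[`, "", 1), IRanges(starts + 1L, ends))
}

#' @rdname readBed
#' @export
writeBed <- function(gr, path) {
  export(gr, path, format = "BED")
  invisible(path)
}

#' Read / write bedGraph signal tracks
#'
#' @param path File path.
#' @param gr \code{GRanges} with a numeric \code{score} column.
#' @return \code{readBedGraph} returns a \code{GRanges} with \code{score}.
#' @export
readBedGraph <- function(path) {
  gr <- import(path, format = "bedGraph")
  gr
}

#' @rdname readBedGraph
#' @export
writeBedGraph <- function(gr, path) {
  export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write FASTQ with constant Phred+33 quality
#'
#' Minimal plain-text FASTQ support for merged amplicon reads; qualities
#' are not used by the profiler, so writing emits constant 'I' (Q40).
#'
#' @param path File path.
#' @param reads Character vector of read sequences.
#' @param ids Read identifiers (default read000001, ...).
#' @return \code{readFastq} returns list(\code{id}, \code{seq}).
#' @export
readFastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  idx <- seq(1, length(lines), by = 4)
  list(id = sub("^@", "", lines[idx]), seq = toupper(lines[idx + 1L]))
}

#' @rdname readFastq
#' @export
writeFastq <- function(reads, path,
                       ids = sprintf("read%06d", seq_along(reads))) {
  qual <- strrep("I", nchar(reads))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), path)
  invisible(path)
}

#' Read / write the per-cytosine methylation call table
#'
#' Tab-separated, with header: chrom, pos0 (0-based), strand, context
#' (CG/CHG/CHH), mc_count, total_count.
#'
#' @param path File path.
#' @param calls data.frame as produced by [simulateMethylation()].
#' @return \code{readCytosineCalls} returns the calls data.frame.
#' @export
readCytosineCalls <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos0", "strand", "context", "mc_count", "total_count")
  if (!all(need %in% colnames(df)))
    stop("cytosine call table must have columns ",
         paste(need, collapse = ", "))
  df
}

#' @rdname readCytosineCalls
#' @export
writeCytosineCalls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a planted-site registry as BED plus a TSV table
#'
#' @param registry \code{GRanges} from [buildGenome()].
#' @param prefix Output path prefix; writes \code{<prefix>.bed} (0-based)
#'   and \code{<prefix>.tsv}.
#' @return Invisibly, the two paths.
#' @export
writeSiteRegistry <- function(registry, prefix) {
  bed <- paste0(prefix, ".bed")
  tsv <- paste0(prefix, ".tsv")
  df <- data.frame(chrom = as.character(seqnames(registry)),
                   start0 = start(registry) - 1L,
                   end0 = end(registry),
                   strand = as.character(strand(registry)),
                   target = mcols(registry)$target,
                   family = mcols(registry)$family)
  writeLines(with(df, paste(chrom, start0, end0, family, 0, strand,
                            sep = "\t")), bed)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed = bed, tsv = tsv))
}

#' Write a genome (and organelles) as FASTA
#'
#' @param built Output of [buildGenome()].
#' @param prefix Path prefix; writes \code{<prefix>_nuclear.fa} and, when
#'   organelles exist, \code{<prefix>_organelles.fa}.
#' @return Invisibly, the written paths.
#' @export
writeGenome <- function(built, prefix) {
  nuc <- paste0(prefix, "_nuclear.fa")
  Biostrings::writeXStringSet(built$genome, nuc)
  paths <- nuc
  if (length(built$organelles)) {
    org <- paste0(prefix, "_organelles.fa")
    Biostrings::writeXStringSet(built$organelles, org)
    paths <- c(paths, org)
  }
  invisible(paths)
}

#' Serialize a truth log (or any plan) to JSON
#'
#' @param x A plan or truth-log object (lists/data.frames).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeTruthLog <- function(x, path) {
  write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
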