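#' Read aligned 3'READS records from SAM or TSV
#'
#' Loads the subset of alignment information the poly(A)-site caller needs:
#' aligned span (0-based half-open), strand, MAPQ, and the soft-clipped
#' bases at the read's 5' end in *read orientation*. For a minus-strand
#' alignment the read's 5' soft clip sits at the genomic right edge and the
#' SAM SEQ is the reverse complement of the read, so the trailing clip is
#' reverse-complemented back. MAPQ-0 multi-mappers are loaded; filtering is
#' the caller's job. Records with CIGAR operations outside M/I/D/S/H/N/=/X
#' are skipped with a warning count.
#'
#' The TSV dialect is a header line followed by the columns of the returned
#' data.frame, for pipelines that pre-extract the fields.
#'
#' @param path `.sam` file (text SAM with `@SQ` header) or `.tsv`.
#' @param format `"sam"` or `"tsv"`; inferred from the extension if `NULL`.
#' @return data.frame with columns `read_id`, `chrom`, `align_strand`,
#'   `align_start`, `align_end`, `mapq`, `clip5_seq`, `clip3_len`.
#' @export
read_alignments <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", tsv = "tsv",
                     stop("cannot infer alignment format from extension: ",
                          ext, call. = FALSE))
  }
  if (format == "tsv") {
    aln <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(clip5_seq = "character"))
    need <- c("read_id", "chrom", "align_strand", "align_start",
              "align_end", "mapq", "clip5_seq", "clip3_len")
    miss <- setdiff(need, names(aln))
    if (length(miss)) {
      stop("alignment TSV lacks columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    aln$clip5_seq[is.na(aln$clip5_seq)] <- ""
    return(aln[need])
  }
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  cigar <- x$cigar
  ok <- !grepl("[^0-9MIDSHN=X]", cigar)
  n_skip <- sum(!ok)
  if (n_skip) {
    warning(n_skip, " record(s) skipped (unsupported CIGAR operation)",
            call. = FALSE)
  }
  cigar <- cigar[ok]
  seqs <- as.character(x$seq)[ok]
  flag <- x$flag[ok]
  minus <- bitwAnd(flag, 16L) > 0L
  refw <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  # leading/trailing soft-clip lengths in SAM (reference) orientation
  lead <- trail <- integer(length(cigar))
  has_lead <- grepl("^[0-9]+S", cigar)
  lead[has_lead] <- as.integer(sub("^([0-9]+)S.*", "\\1", cigar[has_lead]))
  has_trail <- grepl("[0-9]+S$", cigar)
  trail[has_trail] <-
    as.integer(sub(".*?([0-9]+)S$", "\\1", cigar[has_trail]))
  clip5_sam <- ifelse(minus, trail, lead)   # read 5' clip, SAM orientation
  clip3_len <- ifelse(minus, lead, trail)
  clip5_seq <- character(length(cigar))
  for (i in seq_along(cigar)) {
    if (clip5_sam[i] == 0L) next
    if (minus[i]) {
      tail_seq <- substr(seqs[i], nchar(seqs[i]) - clip5_sam[i] + 1L,
                         nchar(seqs[i]))
      clip5_seq[i] <- reverse_complement(tail_seq)
    } else {
      clip5_seq[i] <- substr(seqs[i], 1L, clip5_sam[i])
    }
  }
  data.frame(
    read_id = x$qname[ok],
    chrom = as.character(x$rname)[ok],
    align_strand = ifelse(minus, "-", "+"),
    align_start = x$pos[ok] - 1L,
    align_end = x$pos[ok] - 1L + refw,
    mapq = x$mapq[ok],
    clip5_seq = clip5_seq,
    clip3_len = as.integer(clip3_len),
    stringsAsFactors = FALSE)
}

#' Write alignment records as SAM or TSV
#'
#' The SAM writer emits a minimal valid single-end SAM: `@SQ` lines from
#' `chrom_sizes`, CIGAR `<clip>S<match>M` (clip placed per strand), and SEQ
#' reconstructed with `A`-filled aligned portions (sequence content of the
#' aligned span is irrelevant downstream; only the soft clip matters).
#'
#' @param aln alignment data.frame as returned by [read_alignments()].
#' @param path output `.sam` or `.tsv` file.
#' @param chrom_sizes named vector (required for SAM `@SQ` header).
#' @param format `"sam"` or `"tsv"`; inferred from the extension if `NULL`.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path, chrom_sizes = NULL, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", tsv = "tsv",
                     stop("cannot infer alignment format from extension: ",
                          ext, call. = FALSE))
  }
  if (format == "tsv") {
    utils::write.table(aln, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (is.null(chrom_sizes)) {
    stop("`chrom_sizes` is required to write SAM", call. = FALSE)
  }
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  n <- nrow(aln)
  lines <- character(n)
  for (i in seq_len(n)) {
    m <- aln$align_end[i] - aln$align_start[i]
    clip <- aln$clip5_seq[i]
    minus <- aln$align_strand[i] == "-"
    aligned <- strrep("A", m)
    if (nzchar(clip)) {
      if (minus) {
        # read 5' clip is genomically rightmost; SEQ is revcomp(read)
        seq <- paste0(aligned, reverse_complement(clip))
        cig <- sprintf("%dM%dS", m, nchar(clip))
      } else {
        seq <- paste0(clip, aligned)
        cig <- sprintf("%dS%dM", nchar(clip), m)
      }
    } else {
      seq <- aligned
      cig <- sprintf("%dM", m)
    }
    lines[i] <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                        aln$read_id[i], if (minus) 16L else 0L,
                        aln$chrom[i], aln$align_start[i] + 1L,
                        aln$mapq[i], cig, seq)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
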