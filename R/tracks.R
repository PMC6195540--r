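#' Binned genome coverage track
#'
#' A `coverage_track` holds fixed-width binned signal per chromosome for one
#' species namespace of a (possibly concatenated two-species) genome, plus
#' the provenance of normalization steps applied. Bin values are mean
#' per-base coverage over the bin; the last bin of a chromosome may be
#' partial and averages over its actual length. Missing bins are `NA`.
#'
#' @param values named list, one numeric vector per chromosome with
#'   `ceiling(chrom_length / bin_width)` entries.
#' @param bin_width bin width in nt.
#' @param chrom_sizes named vector of chromosome lengths (nt).
#' @param species `"experimental"` or `"spikein"`.
#' @param provenance character vector of applied steps (labels from
#'   `raw`, `scl`, `normSI`, `sclWT`, `minus_ctrl`, `ratio`).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, bin_width, chrom_sizes,
                           species = c("experimental", "spikein"),
                           provenance = "raw") {
  species <- match.arg(species)
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  if (is.null(names(values)) || !all(names(values) %in% names(chrom_sizes))) {
    stop("track chromosomes must be named and present in chrom_sizes",
         call. = FALSE)
  }
  for (chrom in names(values)) {
    nb <- ceiling(chrom_sizes[[chrom]] / bin_width)
    if (length(values[[chrom]]) != nb) {
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   chrom, nb, length(values[[chrom]])), call. = FALSE)
    }
    v <- values[[chrom]]
    if (any(!is.na(v) & !is.finite(v))) {
      stop("non-finite (non-NA) bin value on ", chrom, call. = FALSE)
    }
  }
  structure(list(values = values[sort(names(values))],
                 bin_width = as.integer(bin_width),
                 chrom_sizes = chrom_sizes[sort(names(values))],
                 species = species,
                 provenance = provenance),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track: %d chromosome(s), bin %d nt, species %s\n  provenance: %s\n",
    length(x$values), x$bin_width, x$species,
    paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

# Actual genomic length of every bin of a chromosome (last may be partial).
bin_lengths <- function(track, chrom) {
  len <- track$chrom_sizes[[chrom]]
  bw <- track$bin_width
  n <- length(track$values[[chrom]])
  out <- rep(bw, n)
  out[n] <- len - (n - 1L) * bw
  out
}

# Per-base expansion of one chromosome's bins.
expand_per_base <- function(track, chrom) {
  rep(track$values[[chrom]], times = bin_lengths(track, chrom))
}

validate_signal <- function(sig, what = "signal") {
  need <- c("chrom", "start", "end", "value")
  if (!is.data.frame(sig) || !all(need %in% names(sig))) {
    stop(what, " must be a data.frame with chrom/start/end/value",
         call. = FALSE)
  }
  if (any(sig$start < 0)) stop("negative coordinates in ", what, call. = FALSE)
  if (any(sig$end <= sig$start)) {
    stop("empty or inverted interval in ", what, call. = FALSE)
  }
  sig <- sig[order(sig$chrom, sig$start), , drop = FALSE]
  by_chrom <- split(seq_len(nrow(sig)), sig$chrom)
  for (idx in by_chrom) {
    if (length(idx) > 1L &&
        any(sig$start[idx][-1L] < sig$end[idx][-length(idx)])) {
      stop("overlapping intervals in ", what, call. = FALSE)
    }
  }
  rownames(sig) <- NULL
  sig
}

#' Read a bedGraph or WIG signal file
#'
#' Returns a per-base interval signal: a data.frame with columns `chrom`,
#' `start`, `end` (0-based half-open) and `value`, sorted, with overlapping
#' intervals rejected. Gaps between intervals read back as signal 0 when the
#' signal is binned.
#'
#' @param path bedGraph (`.bedgraph`/`.bg`) or WIG (`.wig`) file; the format
#'   is taken from the extension unless `format` is given.
#' @param format `"bedGraph"` or `"wig"`.
#' @return data.frame interval signal.
#' @export
read_signal <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, wig = "wig", bedgraph = , bg = , bedg = "bedGraph",
                     stop("cannot infer signal format from extension: ", ext,
                          call. = FALSE))
  }
  gr <- rtracklayer::import(path, format = format)
  sig <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(S4Vectors::mcols(gr)$score),
    stringsAsFactors = FALSE)
  validate_signal(sig, basename(path))
}

#' Write an interval signal as bedGraph
#'
#' @param sig interval signal data.frame (`chrom`, `start`, `end`, `value`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path) {
  sig <- validate_signal(sig)
  gr <- GenomicRanges::GRanges(
    sig$chrom, IRanges::IRanges(sig$start + 1L, sig$end), score = sig$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Bin a per-base interval signal into a coverage track
#'
#' Each bin value is the mean per-base signal over the bin's covered length;
#' bases not covered by any interval count as 0, and the partial last bin of
#' a chromosome averages over its actual length.
#'
#' @param sig interval signal data.frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_width bin width in nt (>= 1); 10 nt is the convention used for
#'   all normalization and correlation steps.
#' @param species species namespace for the resulting track.
#' @return A [coverage_track] with provenance `raw`.
#' @export
bin_track <- function(sig, chrom_sizes, bin_width = 10,
                      species = "experimental") {
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  sig <- validate_signal(sig)
  unknown <- setdiff(unique(sig$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop("signal on chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  values <- list()
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    nb <- ceiling(len / bin_width)
    sums <- numeric(nb)
    rows <- which(sig$chrom == chrom)
    if (length(rows) && any(sig$end[rows] > len)) {
      stop("interval exceeds length of chromosome ", chrom, call. = FALSE)
    }
    for (r in rows) {
      s <- sig$start[r]; e <- sig$end[r]; v <- sig$value[r]
      b0 <- s %/% bin_width
      b1 <- (e - 1L) %/% bin_width
      if (b0 == b1) {
        sums[b0 + 1L] <- sums[b0 + 1L] + v * (e - s)
      } else {
        bins <- b0:b1
        lo <- pmax(s, bins * bin_width)
        hi <- pmin(e, (bins + 1L) * bin_width)
        sums[bins + 1L] <- sums[bins + 1L] + v * (hi - lo)
      }
    }
    blen <- rep(bin_width, nb)
    blen[nb] <- len - (nb - 1L) * bin_width
    values[[chrom]] <- sums / blen
  }
  coverage_track(values, bin_width, chrom_sizes, species = species,
                 provenance = "raw")
}

#' Write a coverage track as fixed-step WIG or bedGraph
#'
#' WIG output uses one `fixedStep chrom=... start=1 step=w span=w` block per
#' chromosome; bedGraph output writes one interval per bin. Missing (`NA`)
#' bins are omitted in bedGraph and written as `NaN` (configurable sentinel)
#' in WIG. Values are rendered with 10 significant digits. Chromosomes with
#' no bins emit no data lines.
#'
#' @param track a [coverage_track].
#' @param path output file.
#' @param format `"wig"` or `"bedgraph"`.
#' @param na WIG sentinel string for missing bins.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("wig", "bedgraph"),
                        na = "NaN") {
  format <- match.arg(format)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt_val <- function(v) formatC(v, digits = 10, format = "g")
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    if (format == "wig") {
      writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                         chrom, track$bin_width, track$bin_width), con)
      out <- fmt_val(v)
      out[is.na(v)] <- na
      writeLines(out, con)
    } else {
      keep <- !is.na(v)
      if (!any(keep)) next
      starts <- (seq_along(v) - 1L) * track$bin_width
      ends <- pmin(starts + track$bin_width, track$chrom_sizes[[chrom]])
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         fmt_val(v[keep])), con)
    }
  }
  invisible(path)
}

#' Resample a coverage track to a new bin width
#'
#' Per-base expansion followed by per-bin mean, so any combination of old and
#' new widths is handled uniformly. `NA` bins stay `NA` wherever they cover a
#' new bin entirely; partially covered new bins average the non-missing
#' bases.
#'
#' @param track a [coverage_track].
#' @param bin_width new bin width (nt).
#' @return A [coverage_track] at the new resolution (provenance preserved).
#' @export
resample_track <- function(track, bin_width) {
  if (bin_width == track$bin_width) return(track)
  values <- lapply(names(track$values), function(chrom) {
    base <- expand_per_base(track, chrom)
    len <- length(base)
    nb <- ceiling(len / bin_width)
    grp <- rep(seq_len(nb), each = bin_width, length.out = len)
    out <- tapply(base, grp, function(x) {
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    })
    as.numeric(out)
  })
  names(values) <- names(track$values)
  coverage_track(values, bin_width, track$chrom_sizes,
                 species = track$species, provenance = track$provenance)
}

# Mean track signal over a genomic window [start, end), per-base weighted.
# Returns NA if the window is outside the chromosome or the track has no
# such chromosome.
window_mean <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$values)) return(NA_real_)
  len <- track$chrom_sizes[[chrom]]
  if (start < 0 || end > len || end <= start) return(NA_real_)
  bw <- track$bin_width
  v <- track$values[[chrom]]
  b0 <- start %/% bw
  b1 <- (end - 1L) %/% bw
  bins <- b0:b1
  lo <- pmax(start, bins * bw)
  hi <- pmin(end, (bins + 1L) * bw)
  sum(v[bins + 1L] * (hi - lo)) / (end - start)
}
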