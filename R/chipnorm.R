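# ChIP-seq normalization chains: library-size scaling ("sclWT-ctrl"),
# spike-in scaling ("normSI", "normSI_sclWT", "normSI_sclWT-ctrl"), and
# ratio tracks.

same_bins <- function(a, b) {
  identical(names(a$values), names(b$values)) &&
    a$bin_width == b$bin_width &&
    all(lengths(a$values) == lengths(b$values))
}

scale_track <- function(track, factor, step) {
  track$values <- lapply(track$values, function(v) v * factor)
  track$provenance <- c(track$provenance, step)
  track
}

#' Total signal of a track in coverage-bases
#'
#' Sum over bins of bin value times the bin's covered genomic length (the
#' partial last bin contributes its actual length), i.e. the per-base
#' integral of the signal. Missing bins contribute 0.
#'
#' @param track a [coverage_track].
#' @return scalar coverage-bases.
#' @export
total_signal <- function(track) {
  tot <- 0
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (!length(v)) next
    bl <- bin_lengths(track, chrom)
    tot <- tot + sum(v * bl, na.rm = TRUE)
  }
  tot
}

#' Scale a track to a reference total
#'
#' Multiplies all bins so that [total_signal()] equals `target`. The default
#' target, 1e8 coverage-bases, is the equivalent of 1 million mapped reads
#' of 100 nt — the reference depth all tracks are put on before comparison.
#'
#' @param track a [coverage_track].
#' @param target reference total in coverage-bases (default 1e8).
#' @param step provenance label to append (default `"scl"`).
#' @return list with `track` (scaled) and `factor`.
#' @export
scale_to_reference <- function(track, target = 1e8, step = "scl") {
  tot <- total_signal(track)
  if (tot <= 0) {
    stop("cannot scale a track with non-positive total signal", call. = FALSE)
  }
  factor <- target / tot
  list(track = scale_track(track, factor, step), factor = factor)
}

#' Subtract an input (control) track from an IP track
#'
#' Bin-wise difference. Negative values are retained by default, matching
#' how subtracted tracks enter downstream averaging; `clamp = TRUE` floors
#' at zero for display. A bin missing in either operand is missing in the
#' result.
#'
#' @param ip_track,input_track [coverage_track]s with identical bin
#'   structure.
#' @param clamp floor negative differences at 0.
#' @return A [coverage_track] with provenance `minus_ctrl` appended.
#' @export
subtract_input <- function(ip_track, input_track, clamp = FALSE) {
  if (!same_bins(ip_track, input_track)) {
    stop("IP and input tracks have different bin structure", call. = FALSE)
  }
  out <- ip_track
  for (chrom in names(out$values)) {
    v <- ip_track$values[[chrom]] - input_track$values[[chrom]]
    if (clamp) v <- pmax(v, 0)
    out$values[[chrom]] <- v
  }
  out$provenance <- c(ip_track$provenance, "minus_ctrl")
  out
}

#' Library-size normalization without spike-in ("sclWT-ctrl")
#'
#' Scales IP and input each to the reference total over the experimental
#' genome, then subtracts the input from the IP. This chain is scale
#' invariant: multiplying either raw track by a positive constant leaves
#' the result unchanged.
#'
#' @param ip,input experimental-species [coverage_track]s.
#' @param target reference total (default 1e8 coverage-bases).
#' @param clamp passed to [subtract_input()].
#' @return list with `track` (final) and `factors` (named scalars).
#' @export
normalize_no_spikein <- function(ip, input, target = 1e8, clamp = FALSE) {
  si <- scale_to_reference(ip, target)
  sc <- scale_to_reference(input, target)
  list(track = subtract_input(si$track, sc$track, clamp = clamp),
       factors = c(ip = si$factor, input = sc$factor))
}

#' Spike-in normalization of a WT/mutant sample pair
#'
#' Implements the spike-in chain for quantitative WT-vs-mutant comparison.
#' Per data set, the spike-in (reference species) signal total defines the
#' scaling factor (`target / total(spike)`), applied to the experimental
#' species signal (`normSI`). The WT experimental IP is then scaled to the
#' reference total and the *same* factor is applied to the mutant IP
#' (`normSI_sclWT`), preserving the mutant/WT occupancy ratio that the
#' spike-in measures; inputs are chained analogously through their own
#' spike factors and the WT-input factor. Finally each input is subtracted
#' from its IP (`normSI_sclWT-ctrl`).
#'
#' @param wt,mut lists with elements `ip_exp`, `ip_spike`, `input_exp`,
#'   `input_spike` ([coverage_track]s; inputs may be `NULL` to skip
#'   subtraction).
#' @param target reference total (default 1e8 coverage-bases).
#' @param clamp passed to [subtract_input()].
#' @return list with `wt_sclWT`, `mut_sclWT` (pre-subtraction
#'   `normSI_sclWT` IP tracks), `wt_final`, `mut_final`
#'   (`normSI_sclWT-ctrl`, equal to the sclWT tracks when inputs are
#'   absent), and `records` (per-sample ordered factor lists).
#' @export
normalize_spikein_pair <- function(wt, mut, target = 1e8, clamp = FALSE) {
  norm_si <- function(sample, label, part) {
    spike <- sample[[paste0(part, "_spike")]]
    exp_tr <- sample[[paste0(part, "_exp")]]
    if (is.null(exp_tr)) return(NULL)
    if (is.null(spike)) {
      stop("sample ", label, " lacks a spike-in track for ", part,
           call. = FALSE)
    }
    tot <- total_signal(spike)
    if (tot <= 0) {
      stop("zero spike-in total for sample ", label, call. = FALSE)
    }
    factor <- target / tot
    list(track = scale_track(exp_tr, factor, "normSI"), factor = factor)
  }
  wt_ip <- norm_si(wt, "WT", "ip")
  mut_ip <- norm_si(mut, "mutant", "ip")
  f_wt_ip <- target / total_signal(wt_ip$track)
  wt_ip_scl <- scale_track(wt_ip$track, f_wt_ip, "sclWT")
  mut_ip_scl <- scale_track(mut_ip$track, f_wt_ip, "sclWT")
  records <- list(
    wt_ip = list(sample_id = "wt_ip", reference_total = target,
                 factors = c(normSI = wt_ip$factor, sclWT = f_wt_ip)),
    mut_ip = list(sample_id = "mut_ip", reference_total = target,
                  factors = c(normSI = mut_ip$factor, sclWT = f_wt_ip)))
  wt_final <- wt_ip_scl
  mut_final <- mut_ip_scl
  if (!is.null(wt$input_exp) && !is.null(mut$input_exp)) {
    wt_in <- norm_si(wt, "WT", "input")
    mut_in <- norm_si(mut, "mutant", "input")
    f_wt_in <- target / total_signal(wt_in$track)
    wt_in_scl <- scale_track(wt_in$track, f_wt_in, "sclWT")
    mut_in_scl <- scale_track(mut_in$track, f_wt_in, "sclWT")
    wt_final <- subtract_input(wt_ip_scl, wt_in_scl, clamp = clamp)
    mut_final <- subtract_input(mut_ip_scl, mut_in_scl, clamp = clamp)
    records$wt_input <- list(sample_id = "wt_input",
                             reference_total = target,
                             factors = c(normSI = wt_in$factor,
                                         sclWT = f_wt_in))
    records$mut_input <- list(sample_id = "mut_input",
                              reference_total = target,
                              factors = c(normSI = mut_in$factor,
                                          sclWT = f_wt_in))
  }
  list(wt_sclWT = wt_ip_scl, mut_sclWT = mut_ip_scl,
       wt_final = wt_final, mut_final = mut_final, records = records)
}

#' Bin-wise ratio of two normalized tracks
#'
#' Bins where the denominator is below `min_denominator` become missing
#' (`NA`), never infinite — low-signal bins would otherwise dominate ratio
#' summaries such as Ser2-P / total RNAPII.
#'
#' @param numerator,denominator [coverage_track]s with identical bin
#'   structure.
#' @param min_denominator minimal denominator value for a defined ratio.
#' @return A [coverage_track] with provenance `ratio`.
#' @export
ratio_track <- function(numerator, denominator, min_denominator = 1) {
  if (!same_bins(numerator, denominator)) {
    stop("numerator and denominator have different bin structure",
         call. = FALSE)
  }
  out <- numerator
  for (chrom in names(out$values)) {
    den <- denominator$values[[chrom]]
    v <- numerator$values[[chrom]] / den
    v[is.na(den) | den < min_denominator] <- NA_real_
    out$values[[chrom]] <- v
  }
  out$provenance <- c(numerator$provenance, "ratio")
  out
}

#' Replay recorded normalization factors on a raw track
#'
#' Applies a record's ordered factors to a raw track, reproducing the
#' normalized track (provenance bookkeeping aside, bit for bit).
#'
#' @param track raw [coverage_track].
#' @param record one element of the `records` list returned by
#'   [normalize_spikein_pair()].
#' @return A [coverage_track].
#' @export
replay_factors <- function(track, record) {
  for (i in seq_along(record$factors)) {
    track <- scale_track(track, record$factors[[i]],
                         names(record$factors)[i])
  }
  track
}
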