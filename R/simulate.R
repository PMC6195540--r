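# Synthetic-data generator: toy two-species genome, 3'READS alignments
# with planted poly(A) sites and decoys, and spike-in ChIP coverage with a
# known global occupancy factor and read-through shift. Every simulator is
# a pure function of (inputs, seed), and the truth table records what was
# planted so downstream stages can be checked for exact recovery.

#' Simulation configuration
#'
#' Defaults emulate the study conditions at desk scale: 31 independently
#' transcribed monocistronic snoRNAs of which 4 have no assignable PAS
#' (mirroring snoRNA genes with barely detectable transcription), a 0.9:0.1
#' experimental/spike-in chromatin ratio, a mutant whose global RNAPII
#' occupancy is 0.4 of WT, and a 200 nt termination read-through shift.
#'
#' @param n_mrna,n_snorna,n_snrna gene counts per biotype.
#' @param n_no_pas number of snoRNA genes left without planted PAS.
#' @param chrom_length experimental chromosome length (nt).
#' @param spike_chrom_length spike-in chromosome length (nt).
#' @param depth expected total coverage-bases per ChIP sample when Poisson
#'   noise is on.
#' @param frac_one_t,frac_low_mapq,frac_cds_internal decoy rates, as
#'   fractions of the planted PAS read count: single-T soft clips, MAPQ <=
#'   10 records, and PAS-like reads inside mRNA CDS.
#' @param t_run_geom_p geometric parameter for untemplated-T run lengths
#'   (run length = 2 + Geom(p)).
#' @param alpha mutant/WT global occupancy factor (> 0).
#' @param readthrough_shift nt by which mutant IP signal extends past gene
#'   3' ends.
#' @param spike_fraction fraction of simulated chromatin signal assigned to
#'   the spike-in species (0 < f < 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_mrna = 20, n_snorna = 31, n_snrna = 5,
                       n_no_pas = 4, chrom_length = 300000,
                       spike_chrom_length = 50000, depth = 1e6,
                       frac_one_t = 0.05, frac_low_mapq = 0.05,
                       frac_cds_internal = 0.05, t_run_geom_p = 0.5,
                       alpha = 0.4, readthrough_shift = 200,
                       spike_fraction = 0.1) {
  cfg <- list(n_mrna = n_mrna, n_snorna = n_snorna, n_snrna = n_snrna,
              n_no_pas = n_no_pas, chrom_length = chrom_length,
              spike_chrom_length = spike_chrom_length, depth = depth,
              frac_one_t = frac_one_t, frac_low_mapq = frac_low_mapq,
              frac_cds_internal = frac_cds_internal,
              t_run_geom_p = t_run_geom_p, alpha = alpha,
              readthrough_shift = readthrough_shift,
              spike_fraction = spike_fraction)
  rates <- c(cfg$frac_one_t, cfg$frac_low_mapq, cfg$frac_cds_internal)
  if (any(rates < 0 | rates > 1)) {
    stop("decoy rates must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$alpha <= 0) stop("alpha must be positive", call. = FALSE)
  if (cfg$spike_fraction <= 0 || cfg$spike_fraction >= 1) {
    stop("spike_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (any(c(cfg$n_mrna, cfg$n_snorna, cfg$n_snrna) < 0)) {
    stop("gene counts must be non-negative", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

exp_chrom <- "sp_I"
spike_chrom <- "sc_I"

#' Generate a toy annotation with planted PAS
#'
#' Places non-overlapping genes on both strands of one experimental
#' chromosome with at least 1 kb intergenic spacing (mRNAs get a single CDS
#' interval), and plants 1-2 poly(A) sites 20-300 nt downstream of each
#' gene's annotated 3' end, except for `n_no_pas` randomly chosen snoRNAs
#' that get none. A second chromosome carries the spike-in species
#' namespace. Deterministic under `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @return list with `annotation` (a [term_annotation]) and `truth` (a
#'   `truth_table`: `planted_pas` data.frame, `alpha`,
#'   `readthrough_shift`, `spike_fraction`, `seed`).
#' @export
make_toy_annotation <- function(cfg, seed) {
  with_seed(seed, {
    n_genes <- cfg$n_mrna + cfg$n_snorna + cfg$n_snrna
    if (n_genes < 1L) stop("no genes requested", call. = FALSE)
    biotypes <- sample(c(rep("mRNA", cfg$n_mrna),
                         rep("snoRNA_mono", cfg$n_snorna),
                         rep("snRNA", cfg$n_snrna)))
    lens <- integer(n_genes)
    lens[biotypes == "mRNA"] <- sample(800:2000, sum(biotypes == "mRNA"),
                                       replace = TRUE)
    lens[biotypes == "snoRNA_mono"] <-
      sample(80:200, sum(biotypes == "snoRNA_mono"), replace = TRUE)
    lens[biotypes == "snRNA"] <- sample(100:500, sum(biotypes == "snRNA"),
                                        replace = TRUE)
    gaps <- sample(1000:2500, n_genes + 1L, replace = TRUE)
    starts <- cumsum(c(gaps[1L], lens[-n_genes] + gaps[-c(1L, n_genes + 1L)]))
    ends <- starts + lens
    if (ends[n_genes] + gaps[n_genes + 1L] > cfg$chrom_length) {
      stop("genes do not fit on the chromosome; increase `chrom_length` ",
           "(need >= ", ends[n_genes] + gaps[n_genes + 1L], " nt)",
           call. = FALSE)
    }
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    ids <- sprintf("%s%03d",
                   c(mRNA = "SPGENE.", snoRNA_mono = "SPSNORNA.",
                     snRNA = "SPSNRNA.")[biotypes],
                   seq_len(n_genes))
    genes <- data.frame(gene_id = ids, chrom = exp_chrom, strand = strands,
                        start = starts, end = ends, biotype = biotypes,
                        stringsAsFactors = FALSE)
    cds <- genes[genes$biotype == "mRNA", c("gene_id", "start", "end")]
    if (nrow(cds)) {
      cds$start <- cds$start + 60L
      cds$end <- cds$end - 120L
    }
    chrom_sizes <- stats::setNames(
      c(cfg$chrom_length, cfg$spike_chrom_length),
      c(exp_chrom, spike_chrom))
    ann <- term_annotation(genes, cds, chrom_sizes)
    sno_ids <- genes$gene_id[genes$biotype == "snoRNA_mono"]
    no_pas <- if (cfg$n_no_pas > 0 && length(sno_ids)) {
      sample(sno_ids, min(cfg$n_no_pas, length(sno_ids)))
    } else character()
    pas_rows <- list()
    for (i in seq_len(n_genes)) {
      if (ids[i] %in% no_pas) next
      n_pas <- sample(1:2, 1L)
      dists <- sort(sample(20:300, n_pas))
      counts <- sample(5:50, n_pas)
      a3 <- if (strands[i] == "+") ends[i] else starts[i]
      pos <- if (strands[i] == "+") a3 - 1L + dists else a3 - dists
      pas_rows[[length(pas_rows) + 1L]] <- data.frame(
        gene_id = ids[i], chrom = exp_chrom, strand = strands[i],
        position = pos, expected_read_count = counts,
        planted_distance = dists, stringsAsFactors = FALSE)
    }
    planted <- do.call(rbind, pas_rows)
    if (is.null(planted)) {
      planted <- data.frame(gene_id = character(), chrom = character(),
                            strand = character(), position = integer(),
                            expected_read_count = integer(),
                            planted_distance = integer(),
                            stringsAsFactors = FALSE)
    }
    planted <- planted[order(planted$chrom, planted$position), , drop = FALSE]
    rownames(planted) <- NULL
    truth <- structure(
      list(planted_pas = planted, no_pas_genes = sort(no_pas),
           alpha = cfg$alpha, readthrough_shift = cfg$readthrough_shift,
           spike_fraction = cfg$spike_fraction, seed = seed),
      class = "truth_table")
    list(annotation = ann, truth = truth)
  })
}

#' Simulate 3'READS alignment records
#'
#' For each planted PAS, emits `expected_read_count` records whose
#' alignment abuts the cleavage site on the antisense strand of the gene,
#' with a 5' soft clip of untemplated Ts (run length `2 + Geom(p)`) and
#' MAPQ in 20-60. Decoys are injected at the configured rates: single-T
#' clips (rejected by the T-run filter), records with MAPQ <= 10, and
#' PAS-like reads cleaved inside mRNA CDS far from any same-strand 3' end
#' (rejected by the CDS rule). Deterministic under `seed`.
#'
#' @param ann,truth from [make_toy_annotation()].
#' @param cfg the [sim_config()].
#' @param seed integer seed.
#' @return Alignment data.frame (see [read_alignments()] for columns).
#' @export
simulate_3reads_alignments <- function(ann, truth, cfg, seed) {
  with_seed(seed, {
    planted <- truth$planted_pas
    rows <- list()
    t_run_len <- function(n) 2L + stats::rgeom(n, cfg$t_run_geom_p)
    emit <- function(chrom, strand, pos, n, mapq_range = 20:60,
                     t_len = NULL, tag = "pas") {
      if (n < 1L) return(NULL)
      alen <- sample(30:50, n, replace = TRUE)
      tl <- if (is.null(t_len)) t_run_len(n) else rep(t_len, n)
      clip <- strrep("T", tl)
      if (strand == "+") {         # transcript +, alignment -
        a_end <- pos + 1L
        a_start <- a_end - alen
        a_strand <- "-"
      } else {                     # transcript -, alignment +
        a_start <- pos
        a_end <- a_start + alen
        a_strand <- "+"
      }
      data.frame(read_id = sprintf("%s_%s_%d_%d", tag, chrom, pos,
                                   seq_len(n)),
                 chrom = chrom, align_strand = a_strand,
                 align_start = a_start, align_end = a_end,
                 mapq = sample(mapq_range, n, replace = TRUE),
                 clip5_seq = clip, clip3_len = 0L,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(planted))) {
      rows[[length(rows) + 1L]] <- emit(
        planted$chrom[i], planted$strand[i], planted$position[i],
        planted$expected_read_count[i])
    }
    n_planted <- sum(planted$expected_read_count)
    rnd_pos <- function(n) sample(100:(cfg$chrom_length - 100L), n)
    n_one_t <- round(cfg$frac_one_t * n_planted)
    if (n_one_t > 0) {
      for (p in rnd_pos(n_one_t)) {
        rows[[length(rows) + 1L]] <- emit(
          exp_chrom, sample(c("+", "-"), 1L), p, 1L, t_len = 1L,
          tag = "decoy1t")
      }
    }
    n_low <- round(cfg$frac_low_mapq * n_planted)
    if (n_low > 0) {
      for (p in rnd_pos(n_low)) {
        rows[[length(rows) + 1L]] <- emit(
          exp_chrom, sample(c("+", "-"), 1L), p, 1L, mapq_range = 0:10,
          tag = "decoylq")
      }
    }
    n_cds <- round(cfg$frac_cds_internal * n_planted)
    mrna <- ann$genes[ann$genes$biotype == "mRNA", , drop = FALSE]
    if (n_cds > 0 && nrow(mrna)) {
      n_sites <- max(1L, n_cds %/% 3L)
      picks <- sample(seq_len(nrow(mrna)), n_sites, replace = TRUE)
      for (j in picks) {
        # cleavage just inside the CDS 5' region: > 500 nt from the gene's
        # own 3' end, > 1 kb from any other same-strand 3' end
        pos <- if (mrna$strand[j] == "+") mrna$start[j] + 70L else
          mrna$end[j] - 171L
        rows[[length(rows) + 1L]] <- emit(
          exp_chrom, mrna$strand[j], pos, 3L, tag = "decoycds")
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# Per-base trapezoid occupancy of one gene over its (possibly extended)
# transcribed interval, in genomic orientation.
gene_trapezoid <- function(start, end, height = 10) {
  len <- end - start
  ramp <- min(100L, len %/% 4L)
  v <- rep(height, len)
  if (ramp > 0) {
    edge <- height * seq_len(ramp) / ramp
    v[seq_len(ramp)] <- edge
    v[(len - ramp + 1L):len] <- rev(edge)
  }
  v
}

per_base_to_signal <- function(values, chrom) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values != 0
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             value = r$values[keep], stringsAsFactors = FALSE)
}

#' Simulate two-species ChIP coverage
#'
#' The experimental-species IP signal is a per-gene trapezoid over
#' `[tss, 3' end]`, extended by `readthrough_shift` nt past the 3' end for
#' the mutant, whose whole track is then scaled so that its total is
#' exactly `alpha` times the WT total — the mutant redistributes occupancy
#' downstream *and* loses it globally, as in a termination-defective
#' strain. The spike-in species carries a uniform signal independent of
#' condition whose total is `spike_fraction / (1 - spike_fraction)` times
#' the WT experimental total of the channel. The input channel is a
#' uniform background, identical between conditions. With
#' `noise = "poisson"` the expected signal is rescaled so the sample
#' (experimental + spike-in) totals `cfg$depth` coverage-bases and every
#' 10 nt bin is replaced by a Poisson draw of its expected count.
#' Deterministic under `seed`.
#'
#' @param ann,truth from [make_toy_annotation()].
#' @param cfg the [sim_config()].
#' @param condition `"WT"` or `"mutant"`.
#' @param channel `"IP"` or `"input"`.
#' @param seed integer seed.
#' @param noise `"none"` or `"poisson"`.
#' @return list with `experimental` and `spikein` per-base interval
#'   signals (data.frames as accepted by [bin_track()]).
#' @export
simulate_chip_coverage <- function(ann, truth, cfg,
                                   condition = c("WT", "mutant"),
                                   channel = c("IP", "input"),
                                   seed, noise = c("none", "poisson")) {
  condition <- match.arg(condition)
  channel <- match.arg(channel)
  noise <- match.arg(noise)
  g <- ann$genes[ann$genes$chrom == exp_chrom, , drop = FALSE]
  len_exp <- ann$chrom_sizes[[exp_chrom]]
  len_spk <- ann$chrom_sizes[[spike_chrom]]
  shape_track <- function(shift) {
    v <- numeric(len_exp)
    for (i in seq_len(nrow(g))) {
      if (g$strand[i] == "+") {
        s <- g$start[i]; e <- min(g$end[i] + shift, len_exp)
      } else {
        s <- max(g$start[i] - shift, 0L); e <- g$end[i]
      }
      tz <- gene_trapezoid(s, e)
      if (g$strand[i] == "-") tz <- rev(tz)
      v[(s + 1L):e] <- v[(s + 1L):e] + tz
    }
    v
  }
  if (channel == "IP") {
    wt_v <- shape_track(0L)
    if (condition == "WT") {
      exp_v <- wt_v
    } else {
      mut_v <- shape_track(truth$readthrough_shift)
      exp_v <- mut_v * truth$alpha * sum(wt_v) / sum(mut_v)
    }
    spike_total_ref <- sum(wt_v)
  } else {
    exp_v <- rep(2, len_exp)       # near-uniform chromatin background
    spike_total_ref <- sum(exp_v)
  }
  spike_level <- truth$spike_fraction / (1 - truth$spike_fraction) *
    spike_total_ref / len_spk
  spk_v <- rep(spike_level, len_spk)
  if (noise == "poisson") {
    scale <- cfg$depth / (sum(exp_v) + sum(spk_v))
    exp_v <- exp_v * scale
    spk_v <- spk_v * scale
    poissonize <- function(v) {
      nb <- ceiling(length(v) / 10)
      grp <- rep(seq_len(nb), each = 10, length.out = length(v))
      mu <- tapply(v, grp, sum)
      draw <- stats::rpois(nb, mu)
      blen <- tabulate(grp, nb)
      rep(draw / blen, times = blen)
    }
    # separate deterministic substreams per (condition, channel, species)
    sub <- match(condition, c("WT", "mutant")) * 2L +
      match(channel, c("IP", "input"))
    exp_v <- with_seed(seed * 16L + sub * 2L, poissonize(exp_v))
    spk_v <- with_seed(seed * 16L + sub * 2L + 1L, poissonize(spk_v))
  }
  list(experimental = per_base_to_signal(exp_v, exp_chrom),
       spikein = per_base_to_signal(spk_v, spike_chrom))
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf(paste0(
    "truth_table: %d planted PAS over %d genes (%d without PAS)\n",
    "  alpha = %g, readthrough_shift = %d nt, spike_fraction = %g\n"),
    nrow(x$planted_pas), length(unique(x$planted_pas$gene_id)),
    length(x$no_pas_genes), x$alpha, x$readthrough_shift,
    x$spike_fraction))
  invisible(x)
}
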