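# Independent oracles and small fixture builders used across tests.

# Brute-force binning: expand the signal to one value per base, then take
# the plain mean within each bin.
brute_force_bin <- function(sig, chrom_sizes, bin_width) {
  out <- list()
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    base <- numeric(len)
    rows <- which(sig$chrom == chrom)
    for (r in rows) {
      base[(sig$start[r] + 1):sig$end[r]] <- sig$value[r]
    }
    nb <- ceiling(len / bin_width)
    grp <- rep(seq_len(nb), each = bin_width, length.out = len)
    out[[chrom]] <- as.numeric(tapply(base, grp, mean))
  }
  out
}

# Mean signal per base over [start, end) from a binned track, brute force.
brute_force_window_mean <- function(track, chrom, start, end) {
  base <- rep(track$values[[chrom]],
              times = polyAterm:::bin_lengths(track, chrom))
  mean(base[(start + 1):end])
}

# Exact two-sided Wilcoxon signed-rank p-value by full enumeration of the
# 2^n sign assignments (midranks, zeros already removed).
brute_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Random interval signal on the given chromosomes (non-overlapping).
random_signal <- function(chrom_sizes, n_intervals = 20) {
  rows <- list()
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    cuts <- sort(sample(0:len, min(2 * n_intervals, len), replace = FALSE))
    cuts <- unique(c(0, cuts, len))
    starts <- cuts[-length(cuts)]
    ends <- cuts[-1]
    keep <- sample(c(TRUE, FALSE), length(starts), replace = TRUE)
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                end = ends[keep],
                                value = round(stats::runif(sum(keep), 0, 20), 2),
                                stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Minimal annotation: named arguments become gene-table columns.
toy_annotation <- function(genes, cds = NULL, chrom_sizes = c(chrI = 100000)) {
  term_annotation(genes, cds, chrom_sizes)
}

toy_gene <- function(gene_id, start, end, strand = "+", chrom = "chrI",
                     biotype = "snoRNA_mono") {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             start = start, end = end, biotype = biotype,
             stringsAsFactors = FALSE)
}

# Uniform-value coverage track on one chromosome.
flat_track <- function(value, nbins = 10, bin_width = 10, chrom = "chrI",
                       species = "experimental", chrom_len = NULL) {
  chrom_len <- if (is.null(chrom_len)) nbins * bin_width else chrom_len
  cs <- stats::setNames(chrom_len, chrom)
  coverage_track(stats::setNames(list(rep(value, nbins)), chrom),
                 bin_width, cs, species = species)
}
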