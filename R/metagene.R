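# Multi-anchor metagene ("aggregate and profile") machinery: fixed-length
# block layouts around each gene, strand-aware window extraction, mean
# aggregation with missing-as-zero, and block-confined smoothing.

default_block_windows <- function(mode) {
  if (mode == "four_anchor") {
    c(upstream_gene = 20L, upstream_intergenic = 50L, gene = 100L,
      downstream_intergenic = 50L, downstream_gene = 20L)
  } else {
    c(upstream_intergenic = 50L, gene = 100L, downstream_intergenic = 50L)
  }
}

#' Build the per-gene window layout for a metagene profile
#'
#' Absolute (fixed-length) layout in profile order (the gene's 5' to 3'
#' direction; minus-strand genes are mirrored). In `four_anchor` mode there
#' are five blocks: upstream gene (signal ignored), upstream intergenic
#' (windows aligned toward the TSS), the gene of interest (split: the first
#' half of the windows anchored at the TSS walking 3'-ward, the second half
#' anchored at the 3' end walking 5'-ward; for an odd count the TSS half
#' gets the extra window), downstream intergenic (aligned at the 3' end),
#' and downstream gene (ignored). Intergenic windows extending into the
#' neighboring gene are marked missing, so adjacent genes cannot
#' contaminate the profile. In `two_anchor` mode only the three middle
#' blocks exist and intergenic windows are clipped at chromosome ends only,
#' deliberately admitting neighbor signal so read-through past the 3' end
#' stays visible. Gene-block windows beyond the actual gene length, and any
#' window outside the chromosome, are missing (counted as 0 at
#' aggregation).
#'
#' Neighbors are the strand-agnostic adjacent genes; chromosome ends act as
#' neighbors at the boundary.
#'
#' @param gene_id gene of interest.
#' @param ann a [term_annotation].
#' @param mode `"four_anchor"` or `"two_anchor"`.
#' @param window_width window width in nt (default 10).
#' @param block_windows named integer vector of windows per block (defaults
#'   via the mode; names as above).
#' @return data.frame in profile order: `block`, `window` (1-based overall
#'   index), `start`, `end` (0-based half-open, `NA` for ignore/missing),
#'   `missing`, `ignore`.
#' @export
build_block_layout <- function(gene_id, ann,
                               mode = c("four_anchor", "two_anchor"),
                               window_width = 10,
                               block_windows = NULL) {
  mode <- match.arg(mode)
  if (is.null(block_windows)) block_windows <- default_block_windows(mode)
  g <- ann$genes[ann$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("unknown gene_id: ", gene_id, call. = FALSE)
  w <- as.integer(window_width)
  chrom_len <- ann$chrom_sizes[[g$chrom]]
  plus <- g$strand == "+"
  tss_b <- if (plus) g$start else g$end        # TSS boundary coordinate
  end_b <- if (plus) g$end else g$start        # 3' end boundary coordinate
  gene_len <- g$end - g$start
  # flanking free space in the gene's own orientation
  prev_g <- ann$genes[match(g$prev_gene, ann$genes$gene_id), , drop = FALSE]
  next_g <- ann$genes[match(g$next_gene, ann$genes$gene_id), , drop = FALSE]
  left_free <- g$start - (if (nrow(prev_g) && !is.na(g$prev_gene))
    prev_g$end else 0)
  right_free <- (if (nrow(next_g) && !is.na(g$next_gene))
    next_g$start else chrom_len) - g$end
  up_free <- max(0, if (plus) left_free else right_free)
  down_free <- max(0, if (plus) right_free else left_free)
  if (mode == "two_anchor") {
    up_free <- if (plus) g$start else chrom_len - g$end
    down_free <- if (plus) chrom_len - g$end else g$start
  }
  dir <- if (plus) 1L else -1L
  # genomic [start,end) of the window spanning sense offsets [o0,o1) from a
  # boundary coordinate b (offsets increase 5'->3')
  win_at <- function(b, o0, o1) {
    if (plus) c(b + o0, b + o1) else c(b - o1, b - o0)
  }
  rows <- list()
  add <- function(block, starts, ends, missing, ignore = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      block = block, start = starts, end = ends, missing = missing,
      ignore = ignore, stringsAsFactors = FALSE)
  }
  blocks <- names(block_windows)
  for (bl in blocks) {
    n <- block_windows[[bl]]
    if (bl %in% c("upstream_gene", "downstream_gene")) {
      add(bl, rep(NA_integer_, n), rep(NA_integer_, n), rep(TRUE, n),
          ignore = TRUE)
    } else if (bl == "upstream_intergenic") {
      i <- seq_len(n)
      off1 <- -(n - i) * w          # window sense-offset upper bound (<= 0)
      off0 <- -(n - i + 1L) * w
      coords <- vapply(i, function(k) win_at(tss_b, off0[k], off1[k]),
                       numeric(2L))
      miss <- (n - i + 1L) * w > up_free
      add(bl, coords[1L, ], coords[2L, ], miss)
    } else if (bl == "gene") {
      h <- ceiling(n / 2)
      starts <- ends <- numeric(n); miss <- logical(n)
      for (j in seq_len(h)) {       # TSS-anchored half
        cc <- win_at(tss_b, (j - 1L) * w, j * w)
        starts[j] <- cc[1L]; ends[j] <- cc[2L]
        miss[j] <- j * w > gene_len
      }
      m <- n - h
      for (k in seq_len(m)) {       # 3'-end-anchored half
        cc <- win_at(end_b, -(m - k + 1L) * w, -(m - k) * w)
        starts[h + k] <- cc[1L]; ends[h + k] <- cc[2L]
        miss[h + k] <- (m - k + 1L) * w > gene_len
      }
      add(bl, starts, ends, miss)
    } else if (bl == "downstream_intergenic") {
      i <- seq_len(n)
      coords <- vapply(i, function(k) win_at(end_b, (k - 1L) * w, k * w),
                       numeric(2L))
      miss <- i * w > down_free
      add(bl, coords[1L, ], coords[2L, ], miss)
    } else {
      stop("unknown block label: ", bl, call. = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # any window that leaves the chromosome is missing
  oob <- !out$ignore & !out$missing &
    (out$start < 0 | out$end > chrom_len)
  out$missing <- out$missing | oob
  out$window <- seq_len(nrow(out))
  attr(out, "window_width") <- w
  attr(out, "mode") <- mode
  out[c("block", "window", "start", "end", "missing", "ignore")]
}

#' Extract a gene-by-window signal matrix
#'
#' One row per gene, one column per layout window; each cell is the mean
#' track signal over the window's genomic span (per-base weighted, so any
#' track bin width works). Missing/ignored windows are `NA` here and become
#' 0 (or stay out, for ignore blocks) at aggregation.
#'
#' @param track a [coverage_track].
#' @param layouts named list of layouts from [build_block_layout()], all
#'   with the same block structure.
#' @param ann the [term_annotation] the layouts were built from (gene
#'   chromosome lookup).
#' @return numeric matrix genes x windows with the layout template in
#'   attribute `layout`.
#' @export
extract_gene_matrix <- function(track, layouts, ann) {
  stopifnot(length(layouts) >= 1L)
  template <- layouts[[1L]][c("block", "window", "ignore")]
  nw <- nrow(template)
  mat <- matrix(NA_real_, nrow = length(layouts), ncol = nw,
                dimnames = list(names(layouts), NULL))
  for (gi in seq_along(layouts)) {
    lay <- layouts[[gi]]
    if (nrow(lay) != nw) {
      stop("layouts have inconsistent window counts", call. = FALSE)
    }
    chrom <- ann$genes$chrom[match(names(layouts)[gi], ann$genes$gene_id)]
    live <- which(!lay$missing & !lay$ignore)
    for (j in live) {
      mat[gi, j] <- window_mean(track, chrom, lay$start[j], lay$end[j])
    }
  }
  attr(mat, "layout") <- template
  mat
}

#' Aggregate a gene matrix into a metagene profile
#'
#' Per-window arithmetic mean across genes with missing data counted as 0,
#' so every gene contributes to every non-ignored window and short genes
#' pull the aggregate toward 0 rather than dropping out. Ignore-block
#' windows keep `NA` values (they reserve x-axis space only).
#'
#' @param mat matrix from [extract_gene_matrix()].
#' @param stat aggregate statistic; only `"mean"` is supported.
#' @return An object of class `metagene_profile`: data.frame `block`,
#'   `window`, `value`, `n_contributing`, with `window_width` and
#'   `smoothing` attributes.
#' @export
aggregate_profile <- function(mat, stat = "mean") {
  stat <- match.arg(stat, "mean")
  if (!nrow(mat)) stop("empty gene set", call. = FALSE)
  layout <- attr(mat, "layout")
  zeroed <- mat
  zeroed[is.na(zeroed)] <- 0
  value <- colMeans(zeroed)
  value[layout$ignore] <- NA_real_
  n_contributing <- colSums(!is.na(mat))
  out <- data.frame(block = layout$block, window = layout$window,
                    value = value, n_contributing = n_contributing,
                    stringsAsFactors = FALSE)
  structure(out, class = c("metagene_profile", "data.frame"),
            smoothing = 0L)
}

#' Smooth a metagene profile within blocks
#'
#' Centered moving average extending up to `s` windows on each side,
#' shrinking near block edges and never crossing block boundaries (each
#' block is anchored differently, so averaging across a boundary would mix
#' anchors). `s = 0` is the identity; ignore blocks stay `NA`.
#'
#' @param profile a `metagene_profile`.
#' @param s smoothing half-width in windows (default 6).
#' @return The smoothed `metagene_profile`.
#' @export
smooth_profile <- function(profile, s = 6) {
  stopifnot(s >= 0)
  if (s == 0) return(profile)
  out <- profile
  for (bl in unique(profile$block)) {
    idx <- which(profile$block == bl)
    v <- profile$value[idx]
    if (all(is.na(v))) next
    n <- length(v)
    sm <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - s); hi <- min(n, i + s)
      sm[i] <- mean(v[lo:hi])
    }
    out$value[idx] <- sm
  }
  attr(out, "smoothing") <- s
  out
}

#' Metagene profile for a gene set over a track
#'
#' Convenience wrapper: layouts, extraction, aggregation, smoothing.
#'
#' @param track a [coverage_track].
#' @param ann a [term_annotation].
#' @param genes character vector of gene ids.
#' @param mode,window_width,block_windows passed to [build_block_layout()].
#' @param smoothing half-width passed to [smooth_profile()] (default 6).
#' @return A `metagene_profile`.
#' @export
metagene_profile <- function(track, ann, genes,
                             mode = c("four_anchor", "two_anchor"),
                             window_width = 10, block_windows = NULL,
                             smoothing = 6) {
  mode <- match.arg(mode)
  layouts <- lapply(genes, build_block_layout, ann = ann, mode = mode,
                    window_width = window_width,
                    block_windows = block_windows)
  names(layouts) <- genes
  mat <- extract_gene_matrix(track, layouts, ann)
  prof <- aggregate_profile(mat)
  attr(prof, "window_width") <- window_width
  smooth_profile(prof, s = smoothing)
}

#' 3'-flank half-maximum crossing of a metagene profile
#'
#' Locates, over the 3'-anchored half of the gene block and the downstream
#' intergenic block, the first window after the profile maximum whose value
#' drops below half of that maximum, and returns its sense-strand offset in
#' nt from the 3'-end anchor (negative = inside the gene). Used to quantify
#' termination read-through: a termination-defective condition displaces
#' this crossing downstream relative to WT.
#'
#' @param profile a `metagene_profile` built in a mode whose gene block is
#'   followed by a `downstream_intergenic` block.
#' @param window_width window width in nt used to build the profile (taken
#'   from the profile attribute when present).
#' @return nt offset of the half-maximum crossing from the 3' end anchor,
#'   or `NA` if the profile never drops below half-maximum.
#' @export
halfmax_crossing_3p <- function(profile, window_width = NULL) {
  window_width <- window_width %||% attr(profile, "window_width") %||% 10
  gene_idx <- which(profile$block == "gene")
  down_idx <- which(profile$block == "downstream_intergenic")
  if (!length(gene_idx) || !length(down_idx)) {
    stop("profile lacks gene/downstream_intergenic blocks", call. = FALSE)
  }
  h <- ceiling(length(gene_idx) / 2)
  tail_gene <- gene_idx[(h + 1):length(gene_idx)]
  idx <- c(tail_gene, down_idx)
  # sense offset of each window's center from the 3' end boundary
  m <- length(tail_gene)
  off <- c(-(rev(seq_len(m)) - 0.5) * window_width,
           (seq_along(down_idx) - 0.5) * window_width)
  v <- profile$value[idx]
  keep <- !is.na(v)
  v <- v[keep]; off <- off[keep]
  if (!length(v)) return(NA_real_)
  imax <- which.max(v)
  half <- v[imax] / 2
  after <- which(seq_along(v) > imax & v < half)
  if (!length(after)) return(NA_real_)
  off[after[1L]]
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile: %d windows in %d block(s), smoothing %d\n",
              nrow(x), length(unique(x$block)),
              attr(x, "smoothing") %||% 0L))
  for (bl in unique(x$block)) {
    v <- x$value[x$block == bl]
    cat(sprintf("  %-22s %3d windows, mean %s\n", bl, length(v),
                if (all(is.na(v))) "ignored" else
                  formatC(mean(v, na.rm = TRUE), digits = 4,
                          format = "g")))
  }
  invisible(x)
}

#' Plot a metagene profile
#'
#' Line plot of mean signal per window with block boundaries marked.
#'
#' @param x a `metagene_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$window, x$value, type = "l", xlab = "window",
                 ylab = "mean signal", ...)
  bounds <- cumsum(rle(x$block)$lengths)
  graphics::abline(v = bounds[-length(bounds)] + 0.5, lty = 3,
                   col = "grey50")
  invisible(x)
}

#' Write a metagene profile as TSV
#'
#' @param profile a `metagene_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
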