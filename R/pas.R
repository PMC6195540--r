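#' Detect poly(A)-site (PAS) reads
#'
#' A 3'READS record evidences a cleavage/polyadenylation event when it is
#' uniquely mapped (MAPQ strictly greater than `min_mapq_exclusive`) and its
#' 5' soft clip starts with a run of at least `min_t` untemplated `T`s (the
#' reverse-complemented poly(A) tail). Only the *leading* T run counts;
#' non-T bases after the run are ignored.
#'
#' The transcript sense strand is the opposite of the alignment strand. The
#' cleavage position is the 0-based coordinate of the last templated
#' transcript nucleotide: the aligned base adjacent to the 5' soft clip
#' (`align_end - 1` for minus-strand alignments / plus-strand transcripts,
#' `align_start` for plus-strand alignments / minus-strand transcripts).
#'
#' @param aln alignment data.frame from [read_alignments()] or
#'   [simulate_3reads_alignments()].
#' @param min_t minimal untemplated-T run length (default 2).
#' @param min_mapq_exclusive MAPQ threshold, strict (default 10).
#' @return data.frame of PAS reads: `chrom`, `strand` (transcript sense),
#'   `cleavage_pos`, `n_untemplated_t`, `mapq`, with rejection counts in
#'   attribute `rejected` (`low_mapq`, `short_t_run`).
#' @export
detect_pas_reads <- function(aln, min_t = 2, min_mapq_exclusive = 10) {
  t_run <- leading_run(aln$clip5_seq, "T")
  pass_mapq <- aln$mapq > min_mapq_exclusive
  pass_t <- t_run >= min_t
  keep <- pass_mapq & pass_t
  minus_aln <- aln$align_strand == "-"
  out <- data.frame(
    chrom = aln$chrom[keep],
    strand = ifelse(minus_aln[keep], "+", "-"),
    cleavage_pos = ifelse(minus_aln[keep], aln$align_end[keep] - 1L,
                          aln$align_start[keep]),
    n_untemplated_t = t_run[keep],
    mapq = aln$mapq[keep],
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$cleavage_pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- c(low_mapq = sum(!pass_mapq),
                             short_t_run = sum(pass_mapq & !pass_t))
  out
}

#' Call PAS sites from PAS reads
#'
#' Groups PAS reads of one sample by (chromosome, strand, cleavage
#' position). With `merge_window > 0`, same-strand positions within the
#' window are clustered and merged to the read-weighted mode position (the
#' position carrying most reads; ties go to the smaller coordinate). All
#' sites are returned including singletons — the read-support filter is
#' applied at gene assignment, where the original analysis attaches it.
#' `rpm` is reads per million PAS reads of the sample, so `sum(rpm)` over a
#' sample's site table is 1e6.
#'
#' @param pas_reads data.frame from [detect_pas_reads()].
#' @param merge_window merge window in nt (default 0 = single-nucleotide
#'   sites).
#' @return data.frame of sites ordered by (chrom, position): `chrom`,
#'   `strand`, `position`, `read_count`, `rpm`.
#' @export
call_pas_sites <- function(pas_reads, merge_window = 0) {
  total <- nrow(pas_reads)
  if (!total) {
    return(data.frame(chrom = character(), strand = character(),
                      position = integer(), read_count = integer(),
                      rpm = numeric(), stringsAsFactors = FALSE))
  }
  key <- split(seq_len(total),
               paste(pas_reads$chrom, pas_reads$strand, sep = "\r"))
  rows <- lapply(names(key), function(k) {
    idx <- key[[k]]
    tab <- table(pas_reads$cleavage_pos[idx])
    pos <- as.integer(names(tab))
    cnt <- as.integer(tab)
    o <- order(pos)
    pos <- pos[o]; cnt <- cnt[o]
    if (merge_window > 0 && length(pos) > 1L) {
      cluster <- cumsum(c(1L, as.integer(diff(pos) > merge_window)))
      pos2 <- integer(0); cnt2 <- integer(0)
      for (cl in split(seq_along(pos), cluster)) {
        best <- cl[which.max(cnt[cl])]  # ties: first = smallest position
        pos2 <- c(pos2, pos[best])
        cnt2 <- c(cnt2, sum(cnt[cl]))
      }
      pos <- pos2; cnt <- cnt2
    }
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(chrom = parts[1L], strand = parts[2L], position = pos,
               read_count = cnt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$position, out$strand), , drop = FALSE]
  out$rpm <- out$read_count * 1e6 / total
  rownames(out) <- NULL
  out
}

# Signed distance from a gene's annotated 3' end to a cleavage position,
# measured along the sense strand (positive = downstream). Zero when the
# cleavage base is the last annotated base.
pas_distance <- function(position, strand, annotated_3end) {
  n <- max(length(position), length(strand), length(annotated_3end))
  position <- rep_len(position, n)
  strand <- rep_len(strand, n)
  annotated_3end <- rep_len(annotated_3end, n)
  ifelse(strand == "+",
         position - (annotated_3end - 1L),
         annotated_3end - position)
}

#' Assign PAS sites to gene 3' ends
#'
#' Sites supported by at least `min_support` reads are associated with the
#' closest same-strand gene 3' end. A site outside every CDS is assigned
#' when the nearest 3' end lies within `window` nt (rule `standard_1kb`);
#' a site falling inside a CDS is assigned only when a same-strand 3' end
#' lies within `overlap_window` nt (rule `overlap_500`, rescuing genes that
#' overlap coding regions). Each site is assigned to at most one gene; ties
#' on distance go to the downstream gene, then to the lexicographically
#' smaller `gene_id`.
#'
#' @param sites data.frame from [call_pas_sites()].
#' @param ann a [term_annotation] (patched).
#' @param window assignment window in nt (default 1000).
#' @param overlap_window CDS-overlap rescue window in nt (default 500).
#' @param min_support minimal read support (default 2).
#' @return data.frame of assignments: site columns plus `gene_id`,
#'   `distance` (signed, downstream-positive), `in_cds_of` (NA or the id of
#'   a CDS the site falls in) and `rule`.
#' @export
assign_pas_to_genes <- function(sites, ann, window = 1000,
                                overlap_window = 500, min_support = 2) {
  g <- ann$genes
  cds <- ann$cds
  cds_chrom <- if (nrow(cds)) g$chrom[match(cds$gene_id, g$gene_id)] else character()
  res <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (sites$read_count[i] < min_support) next
    chrom <- sites$chrom[i]; strand <- sites$strand[i]
    pos <- sites$position[i]
    in_cds <- if (nrow(cds)) {
      hit <- which(cds_chrom == chrom & cds$start <= pos & pos < cds$end)
      if (length(hit)) cds$gene_id[hit[1L]] else NA_character_
    } else NA_character_
    cand <- which(g$chrom == chrom & g$strand == strand)
    if (!length(cand)) next
    d <- pas_distance(pos, strand, g$annotated_3end[cand])
    lim <- if (is.na(in_cds)) window else overlap_window
    ok <- abs(d) <= lim
    if (!any(ok)) next
    cand <- cand[ok]; d <- d[ok]
    # nearest 3' end; ties toward downstream (d > 0), then smaller gene_id
    o <- order(abs(d), -sign(d), g$gene_id[cand])
    best <- o[1L]
    res[[i]] <- data.frame(
      chrom = chrom, strand = strand, position = pos,
      read_count = sites$read_count[i], rpm = sites$rpm[i],
      gene_id = g$gene_id[cand[best]], distance = d[best],
      in_cds_of = in_cds,
      rule = if (is.na(in_cds)) "standard_1kb" else "overlap_500",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), strand = character(),
                      position = integer(), read_count = integer(),
                      rpm = numeric(), gene_id = character(),
                      distance = numeric(), in_cds_of = character(),
                      rule = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strongest PAS per gene
#'
#' The strongest site is the assigned site with maximal read count; ties are
#' broken by smaller absolute distance to the annotated 3' end, then by the
#' upstream-most position along the sense strand.
#'
#' @param assignments data.frame from [assign_pas_to_genes()].
#' @param gene_id single gene id, or `NULL` for a per-gene table over all
#'   assigned genes.
#' @return For one gene: a one-row data.frame, or `NULL` when the gene has
#'   no assignment. For all genes: a data.frame keyed by `gene_id`.
#' @export
strongest_pas <- function(assignments, gene_id = NULL) {
  pick <- function(a) {
    sense_pos <- ifelse(a$strand == "+", a$position, -a$position)
    o <- order(-a$read_count, abs(a$distance), sense_pos)
    a[o[1L], , drop = FALSE]
  }
  if (!is.null(gene_id)) {
    a <- assignments[assignments$gene_id == gene_id, , drop = FALSE]
    if (!nrow(a)) return(NULL)
    out <- pick(a)
    rownames(out) <- NULL
    return(out)
  }
  parts <- split(assignments, assignments$gene_id)
  out <- do.call(rbind, lapply(parts, pick))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Update transcriptional 3'-end coordinates from strongest PAS
#'
#' Replaces each mapped gene's `annotated_3end` (and the corresponding
#' extremity of its half-open interval) so the gene extends through the
#' cleavage base of its strongest PAS in the reference sample: for a `+`
#' strand gene the new end is `position + 1`, for a `-` strand gene the new
#' start is `position`. Genes absent from the map are untouched; a PAS
#' upstream of the TSS refuses the update for that gene (with a warning).
#' Re-applying the same map is idempotent.
#'
#' @param ann a [term_annotation].
#' @param strongest data.frame with `gene_id` and `position` (e.g. from
#'   [strongest_pas()]).
#' @return The updated [term_annotation]; the old/new coordinate table is in
#'   attribute `update_table` (`gene_id`, `old_3end`, `new_3end`).
#' @export
update_3end_coordinates <- function(ann, strongest) {
  g <- ann$genes
  tab <- NULL
  for (i in seq_len(nrow(strongest))) {
    j <- match(strongest$gene_id[i], g$gene_id)
    if (is.na(j)) next
    pos <- strongest$position[i]
    if (g$strand[j] == "+") {
      if (pos < g$start[j]) {
        warning("PAS upstream of TSS for ", g$gene_id[j],
                "; 3' end not updated", call. = FALSE)
        next
      }
      old <- g$annotated_3end[j]
      g$end[j] <- pos + 1L
      g$annotated_3end[j] <- pos + 1L
    } else {
      if (pos >= g$end[j]) {
        warning("PAS upstream of TSS for ", g$gene_id[j],
                "; 3' end not updated", call. = FALSE)
        next
      }
      old <- g$annotated_3end[j]
      g$start[j] <- pos
      g$annotated_3end[j] <- pos
    }
    tab <- rbind(tab, data.frame(gene_id = g$gene_id[j], old_3end = old,
                                 new_3end = g$annotated_3end[j],
                                 stringsAsFactors = FALSE))
  }
  ann$genes <- g
  ann <- rebuild_neighbor_index(ann)
  attr(ann, "update_table") <- tab
  ann
}

#' Distance and read-density statistics across conditions
#'
#' For each condition: per-gene signed distance of the strongest PAS to the
#' annotated 3' end and the summed RPM over all of the gene's assigned
#' sites, with group medians. Conditions are compared pairwise on genes
#' present in both, with the exact Wilcoxon signed-rank test
#' ([wilcoxon_signed_rank()]).
#'
#' @param assignments_by_condition named list of assignment data.frames.
#' @param genes optional character vector restricting the gene set (e.g.
#'   monocistronic snoRNAs).
#' @return An object of class `pas_distance_stats`: `per_gene` (long
#'   data.frame of condition, gene_id, distance, sum_rpm), `medians`, and
#'   `tests` (paired Wilcoxon per condition pair, for distance and density).
#' @export
distance_and_density_stats <- function(assignments_by_condition,
                                       genes = NULL) {
  conds <- names(assignments_by_condition)
  if (is.null(conds) || !length(conds)) {
    stop("`assignments_by_condition` must be a non-empty named list",
         call. = FALSE)
  }
  per_gene <- do.call(rbind, lapply(conds, function(cond) {
    a <- assignments_by_condition[[cond]]
    if (!is.null(genes)) a <- a[a$gene_id %in% genes, , drop = FALSE]
    if (!nrow(a)) return(NULL)
    st <- strongest_pas(a)
    sums <- tapply(a$rpm, a$gene_id, sum)
    data.frame(condition = cond, gene_id = st$gene_id,
               distance = st$distance,
               sum_rpm = as.numeric(sums[st$gene_id]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_gene)) stop("no assignments in any condition", call. = FALSE)
  medians <- do.call(rbind, lapply(split(per_gene, per_gene$condition),
    function(d) data.frame(condition = d$condition[1L],
                           n_genes = nrow(d),
                           median_distance = stats::median(d$distance),
                           median_sum_rpm = stats::median(d$sum_rpm),
                           stringsAsFactors = FALSE)))
  rownames(medians) <- NULL
  tests <- NULL
  if (length(conds) >= 2L) {
    pairs <- utils::combn(conds, 2L, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(p) {
      a <- per_gene[per_gene$condition == p[1L], ]
      b <- per_gene[per_gene$condition == p[2L], ]
      common <- intersect(a$gene_id, b$gene_id)
      if (!length(common)) {
        stop("no genes shared between conditions ", p[1L], " and ", p[2L],
             call. = FALSE)
      }
      ai <- match(common, a$gene_id); bi <- match(common, b$gene_id)
      wd <- wilcoxon_signed_rank(a$distance[ai], b$distance[bi])
      wr <- wilcoxon_signed_rank(a$sum_rpm[ai], b$sum_rpm[bi])
      data.frame(cond_a = p[1L], cond_b = p[2L], n_pairs = length(common),
                 distance_W = unname(wd$statistic), distance_p = wd$p.value,
                 density_W = unname(wr$statistic), density_p = wr$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(per_gene = per_gene, medians = medians, tests = tests),
            class = "pas_distance_stats")
}

#' @export
print.pas_distance_stats <- function(x, ...) {
  cat("PAS distance / read-density statistics\n")
  print(x$medians, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("paired Wilcoxon signed-rank tests:\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Write a PAS assignment table and BED6 export
#'
#' @param assignments data.frame from [assign_pas_to_genes()].
#' @param path output TSV path; a `.bed` file with the same stem is written
#'   alongside when `bed = TRUE` (score = read count, name = gene id).
#' @param bed also write BED6.
#' @return `path`, invisibly.
#' @export
write_pas_table <- function(assignments, path, bed = TRUE) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (bed && nrow(assignments)) {
    bed_path <- paste0(tools::file_path_sans_ext(path), ".bed")
    bed_df <- data.frame(assignments$chrom, assignments$position,
                         assignments$position + 1L, assignments$gene_id,
                         assignments$read_count, assignments$strand)
    utils::write.table(bed_df, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
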