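#' Gene annotation container
#'
#' A `term_annotation` bundles a gene table, CDS intervals, chromosome sizes
#' and a strand-agnostic neighbor index. All internal coordinates are 0-based
#' half-open; GTF (1-based closed) is converted at the boundary.
#'
#' The gene table has one row per gene with columns `gene_id`, `chrom`,
#' `strand` (`+`/`-`), `start`, `end`, `biotype` (one of `mRNA`,
#' `snoRNA_mono`, `snoRNA_intronic`, `snRNA`, `lncRNA`, `other`),
#' `annotated_3end` and `tss`. At load time `annotated_3end` equals `end`
#' for `+` strand genes and `start` for `-` strand genes (the strand-aware
#' transcript end as a half-open boundary); `tss` is the opposite extremity.
#'
#' @param genes data.frame with the columns above (`annotated_3end`/`tss`
#'   filled in when missing).
#' @param cds data.frame of CDS intervals (`gene_id`, `start`, `end`),
#'   0-based half-open; may be empty.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @return An object of class `term_annotation`.
#' @export
term_annotation <- function(genes, cds = NULL, chrom_sizes) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  miss <- setdiff(need, names(genes))
  if (length(miss)) {
    stop("gene table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicated gene_id in gene table", call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  bad <- genes$end <= genes$start
  if (any(bad)) {
    stop("gene(s) with end <= start: ",
         paste(genes$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  if (is.null(chrom_sizes) || is.null(names(chrom_sizes))) {
    stop("`chrom_sizes` must be a named vector", call. = FALSE)
  }
  unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop("gene chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(genes$annotated_3end)) {
    genes$annotated_3end <- ifelse(genes$strand == "+", genes$end, genes$start)
  }
  if (is.null(genes$tss)) {
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  }
  if (is.null(cds)) {
    cds <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  if (nrow(cds)) {
    g <- match(cds$gene_id, genes$gene_id)
    if (anyNA(g)) {
      stop("CDS interval for unknown gene_id", call. = FALSE)
    }
    out_of_gene <- cds$start < genes$start[g] | cds$end > genes$end[g]
    if (any(out_of_gene)) {
      stop("CDS interval outside its gene body", call. = FALSE)
    }
  }
  rownames(genes) <- genes$gene_id
  ann <- structure(
    list(genes = genes, cds = cds,
         chrom_sizes = chrom_sizes[sort(names(chrom_sizes))]),
    class = "term_annotation")
  rebuild_neighbor_index(ann)
}

# Strand-agnostic per-chromosome ordering; prev/next gene along the genome.
rebuild_neighbor_index <- function(ann) {
  g <- ann$genes
  ord <- order(g$chrom, g$start, g$end, g$gene_id)
  prev_gene <- next_gene <- rep(NA_character_, nrow(g))
  ids <- g$gene_id[ord]
  chroms <- g$chrom[ord]
  n <- length(ids)
  if (n > 1L) {
    same_prev <- c(FALSE, chroms[-1L] == chroms[-n])
    prev_gene[ord][same_prev] <- ids[which(same_prev) - 1L]
    next_gene[ord][c(same_prev[-1L], FALSE)] <-
      ids[which(c(same_prev[-1L], FALSE)) + 1L]
  }
  ann$genes$prev_gene <- prev_gene
  ann$genes$next_gene <- next_gene
  ann
}

#' @export
print.term_annotation <- function(x, ...) {
  cat(sprintf("term_annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(x$chrom_sizes)))
  tab <- table(x$genes$biotype)
  cat("  biotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

default_biotype_map <- function() {
  c(protein_coding = "mRNA", mRNA = "mRNA",
    snoRNA = "snoRNA_mono", snoRNA_mono = "snoRNA_mono",
    snoRNA_intronic = "snoRNA_intronic",
    snRNA = "snRNA", ncRNA = "lncRNA", lncRNA = "lncRNA")
}

#' Read a GTF gene annotation
#'
#' Parses a GTF file (PomBase-style dialect; attribute keys configurable)
#' into a [term_annotation]. GTF 1-based closed coordinates are converted to
#' the internal 0-based half-open convention, so a GTF feature `100..200`
#' becomes `start = 99, end = 200`. Records with non-positive width are a
#' parse error. Genes without CDS lines load with empty `cds_intervals`.
#'
#' @param path GTF file.
#' @param chrom_sizes named vector of chromosome lengths; when `NULL`,
#'   inferred as the maximal annotated end per chromosome.
#' @param attribute_map list with entries `gene_id` (attribute holding the
#'   gene identifier), `biotype` (attribute holding the biotype) and
#'   `biotype_values` (named character mapping raw biotype strings to the
#'   internal vocabulary; unmapped values become `"other"`).
#' @return A [term_annotation].
#' @export
read_annotation <- function(path, chrom_sizes = NULL,
                            attribute_map = list()) {
  amap <- utils::modifyList(
    list(gene_id = "gene_id", biotype = "gene_biotype",
         biotype_values = default_biotype_map()),
    attribute_map)
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  gid <- as.character(meta[[amap$gene_id]])
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no 'gene' features in ", path, call. = FALSE)
  raw_bt <- if (amap$biotype %in% names(meta)) {
    as.character(meta[[amap$biotype]])
  } else {
    rep(NA_character_, length(gr))
  }
  bt <- unname(amap$biotype_values[raw_bt])
  bt[is.na(bt)] <- "other"
  genes <- data.frame(
    gene_id = gid[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    biotype = bt[is_gene],
    stringsAsFactors = FALSE)
  is_cds <- type == "CDS"
  cds <- data.frame(
    gene_id = gid[is_cds],
    start = GenomicRanges::start(gr)[is_cds] - 1L,
    end = GenomicRanges::end(gr)[is_cds],
    stringsAsFactors = FALSE)
  cds <- cds[cds$gene_id %in% genes$gene_id, , drop = FALSE]
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  term_annotation(genes, cds, chrom_sizes)
}

#' Write an annotation back to GTF
#'
#' Emits `gene` and `CDS` features in 1-based closed GTF coordinates, so
#' that read/write round-trips reproduce the original integers.
#'
#' @param ann a [term_annotation].
#' @param path output file.
#' @param source source field for column 2.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, source = "polyAterm") {
  g <- ann$genes
  attr_str <- function(gene_id, biotype) {
    sprintf('gene_id "%s"; gene_biotype "%s";', gene_id, biotype)
  }
  lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   g$chrom, source, g$start + 1L, g$end, g$strand,
                   attr_str(g$gene_id, g$biotype))
  if (nrow(ann$cds)) {
    gi <- match(ann$cds$gene_id, g$gene_id)
    lines <- c(lines, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom[gi], source, ann$cds$start + 1L,
                              ann$cds$end, g$strand[gi],
                              attr_str(g$gene_id[gi], g$biotype[gi])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Apply annotation patches
#'
#' Applies manual corrections to an annotation. The only supported action is
#' `invert_strand`, used when inspection of the data shows a gene annotated
#' on the wrong strand (in fission yeast this affects three monocistronic
#' snoRNAs): the strand flips and `annotated_3end`/`tss` swap extremities;
#' coordinates and biotype are untouched. Applying the same patch twice
#' restores the original annotation.
#'
#' @param ann a [term_annotation].
#' @param patches data.frame with columns `gene_id` and `action`, or a
#'   character vector of gene ids (implying `invert_strand`).
#' @return The patched [term_annotation].
#' @export
apply_annotation_patches <- function(ann, patches) {
  if (is.character(patches)) {
    patches <- data.frame(gene_id = patches, action = "invert_strand",
                          stringsAsFactors = FALSE)
  }
  if (!nrow(patches)) return(ann)
  unknown <- setdiff(patches$gene_id, ann$genes$gene_id)
  if (length(unknown)) {
    stop("patch names unknown gene_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(patches$action), "invert_strand")
  if (length(bad)) {
    stop("unsupported patch action(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  i <- match(patches$gene_id, ann$genes$gene_id)
  g <- ann$genes
  g$strand[i] <- ifelse(g$strand[i] == "+", "-", "+")
  g$annotated_3end[i] <- ifelse(g$strand[i] == "+", g$end[i], g$start[i])
  g$tss[i] <- ifelse(g$strand[i] == "+", g$start[i], g$end[i])
  ann$genes <- g
  ann
}

# CDS intervals of one gene as a two-column matrix.
gene_cds <- function(ann, gene_id) {
  ci <- ann$cds[ann$cds$gene_id == gene_id, , drop = FALSE]
  cbind(start = ci$start, end = ci$end)
}
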