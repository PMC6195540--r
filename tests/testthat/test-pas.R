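pas_aln <- function(clip5, mapq, align_strand = "-", start = 1000,
                    width = 40, chrom = "chrI") {
  data.frame(read_id = paste0("r", seq_along(clip5)), chrom = chrom,
             align_strand = align_strand, align_start = start,
             align_end = start + width, mapq = mapq, clip5_seq = clip5,
             clip3_len = 0L, stringsAsFactors = FALSE)
}

test_that("PAS-read detection applies the T-run and MAPQ rules", {
  aln <- pas_aln(c("TT", "T", "TTT", "TTAG", ""), c(30, 60, 10, 30, 30))
  reads <- detect_pas_reads(aln)
  # TT/30 accepted; T/60 rejected (one T); TTT/10 rejected (MAPQ strict);
  # TTAG/30 accepted with leading-run length 2; empty clip rejected
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$n_untemplated_t, c(2L, 2L))
  expect_equal(attr(reads, "rejected"),
               c(low_mapq = 1L, short_t_run = 2L))
})

test_that("cleavage position abuts the soft clip on either strand", {
  minus_aln <- pas_aln("TT", 30, align_strand = "-", start = 1000,
                       width = 40)
  r <- detect_pas_reads(minus_aln)
  expect_equal(r$strand, "+")          # sense = opposite of alignment
  expect_equal(r$cleavage_pos, 1039)   # right edge - 1
  plus_aln <- pas_aln("TT", 30, align_strand = "+", start = 1000,
                      width = 40)
  r2 <- detect_pas_reads(plus_aln)
  expect_equal(r2$strand, "-")
  expect_equal(r2$cleavage_pos, 1000)  # left edge
})

test_that("site calling groups reads, fills RPM, and can merge windows", {
  aln <- rbind(pas_aln(rep("TT", 3), rep(30, 3), start = 960, width = 40),
               pas_aln("TTT", 30, start = 965, width = 40))
  reads <- detect_pas_reads(aln)
  sites <- call_pas_sites(reads)
  expect_equal(nrow(sites), 2L)        # 999 and 1004, merge_window = 0
  expect_equal(sites$read_count, c(3L, 1L))
  expect_equal(sites$rpm, c(3, 1) * 1e6 / 4)
  expect_equal(sites$rpm[2], 250000)   # 1 read of 4 total
  merged <- call_pas_sites(reads, merge_window = 10)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$position, 999)   # read-weighted mode position
  expect_equal(merged$read_count, 4L)
})

test_that("detect -> call is invariant to record order and sums RPM to 1e6", {
  set.seed(3)
  cfg <- sim_config(n_mrna = 4, n_snorna = 8, n_snrna = 2, n_no_pas = 0,
                    chrom_length = 80000)
  toy <- make_toy_annotation(cfg, seed = 3)
  aln <- simulate_3reads_alignments(toy$annotation, toy$truth, cfg, seed = 4)
  s1 <- call_pas_sites(detect_pas_reads(aln))
  s2 <- call_pas_sites(detect_pas_reads(aln[sample(nrow(aln)), ]))
  expect_equal(s1, s2)
  expect_equal(sum(s1$rpm), 1e6, tolerance = 1e-9)
})

three_gene_ann <- function() {
  genes <- rbind(
    toy_gene("snoA", 5000, 5150, strand = "+"),
    toy_gene("mrnaB", 8000, 9500, strand = "+", biotype = "mRNA"),
    toy_gene("geneC", 9050, 9120, strand = "+", biotype = "snoRNA_mono"))
  cds <- data.frame(gene_id = "mrnaB", start = 8060, end = 9380)
  toy_annotation(genes, cds)
}

pas_site <- function(position, read_count, strand = "+", chrom = "chrI",
                     rpm = read_count) {
  data.frame(chrom = chrom, strand = strand, position = position,
             read_count = read_count, rpm = rpm, stringsAsFactors = FALSE)
}

test_that("assignment follows the 1 kb rule, CDS veto, and 500 nt rescue", {
  ann <- three_gene_ann()
  # 300 nt downstream of snoA's 3' end, same strand, outside any CDS
  a1 <- assign_pas_to_genes(pas_site(5449, 2), ann)
  expect_equal(a1$gene_id, "snoA")
  expect_equal(a1$rule, "standard_1kb")
  expect_equal(a1$distance, 300)
  # 1200 nt downstream: beyond the window, unassigned
  expect_equal(nrow(assign_pas_to_genes(pas_site(6349, 5), ann)), 0L)
  # inside mrnaB's CDS but 400 nt before overlapping geneC's 3' end
  a3 <- assign_pas_to_genes(pas_site(8719, 4), ann)
  expect_equal(a3$gene_id, "geneC")
  expect_equal(a3$rule, "overlap_500")
  expect_equal(a3$in_cds_of, "mrnaB")
  expect_equal(a3$distance, -400)
  # inside the CDS and farther than 500 nt from every 3' end: vetoed
  expect_equal(nrow(assign_pas_to_genes(pas_site(8400, 4), ann)), 0L)
  # single-read support never assigns, even at a perfect position
  expect_equal(nrow(assign_pas_to_genes(pas_site(5449, 1), ann)), 0L)
})

test_that("assignment is strand-specific and ties break downstream", {
  genes <- rbind(toy_gene("up", 1000, 2000, strand = "+"),
                 toy_gene("down", 2400, 3000, strand = "+"))
  ann <- toy_annotation(genes)
  # equidistant (200 nt) between up's 3' end (2000) and down's 3' end
  # measured upstream: position 2199 is +200 from up, -800 from down
  a <- assign_pas_to_genes(pas_site(2199, 3), ann)
  expect_equal(a$gene_id, "up")
  # minus-strand site at the same spot is not assigned to + genes
  expect_equal(nrow(assign_pas_to_genes(pas_site(2199, 3, strand = "-"),
                                        ann)), 0L)
  # exact |distance| tie between two + strand 3' ends at 2000 and 2800:
  # a site at 2399 is +400 from gA and -400 from gB
  genes3 <- rbind(toy_gene("gA", 1000, 2000, strand = "+"),
                  toy_gene("gB", 2200, 2800, strand = "+"))
  ann3 <- toy_annotation(genes3)
  a3 <- assign_pas_to_genes(pas_site(2399, 3), ann3)
  expect_equal(abs(a3$distance), 400)
  expect_equal(a3$gene_id, "gA")  # downstream of gA (d > 0) wins the tie
})

test_that("strongest PAS maximizes count, then proximity, then upstream", {
  a <- data.frame(chrom = "chrI", strand = "+",
                  position = c(5079, 5199, 5299),
                  read_count = c(10, 3, 10), rpm = c(10, 3, 10),
                  gene_id = "g", distance = c(80, 200, 300),
                  in_cds_of = NA, rule = "standard_1kb",
                  stringsAsFactors = FALSE)
  expect_equal(strongest_pas(a, "g")$position, 5079)  # count tie -> |d|
  b <- a[1:2, ]
  b$read_count <- c(5, 5); b$distance <- c(80, 200)
  expect_equal(strongest_pas(b, "g")$distance, 80)
  expect_null(strongest_pas(a, "absent"))
})

pas_distance_of <- function(ann, id, pos) {
  g <- ann$genes[id, ]
  polyAterm:::pas_distance(pos, g$strand, g$annotated_3end)
}

test_that("3'-end updates cover the cleavage base, refuse upstream PAS, and
           are idempotent", {
  genes <- rbind(toy_gene("gP", 4000, 5000, strand = "+"),
                 toy_gene("gM", 7000, 7500, strand = "-"),
                 toy_gene("gU", 9000, 9200, strand = "+"))
  ann <- toy_annotation(genes)
  strongest <- data.frame(gene_id = c("gP", "gM", "gU"),
                          position = c(5078, 6920, 8500),
                          stringsAsFactors = FALSE)
  expect_warning(up <- update_3end_coordinates(ann, strongest),
                 "upstream of TSS")
  # + strand: gene extends through the cleavage base
  expect_equal(up$genes["gP", "end"], 5079)
  expect_equal(up$genes["gP", "annotated_3end"], 5079)
  expect_equal(pas_distance_of(up, "gP", 5078), 0)
  # - strand: new start at the cleavage base
  expect_equal(up$genes["gM", "start"], 6920)
  expect_equal(up$genes["gM", "annotated_3end"], 6920)
  # PAS upstream of the TSS leaves the gene untouched
  expect_equal(up$genes["gU", "end"], 9200)
  # genes absent from the map unchanged; re-application idempotent
  expect_warning(up2 <- update_3end_coordinates(up, strongest),
                 "upstream of TSS")
  expect_equal(up2$genes, up$genes)
})

test_that("distance/density statistics report per-gene values and medians", {
  mk <- function(gene, dist, rpm) {
    data.frame(chrom = "chrI", strand = "+", position = 1000 + dist,
               read_count = 5, rpm = rpm, gene_id = gene, distance = dist,
               in_cds_of = NA, rule = "standard_1kb",
               stringsAsFactors = FALSE)
  }
  cond1 <- rbind(mk("g1", 60, 5), mk("g2", 77, 2.5), mk("g2", 150, 7.5),
                 mk("g3", 90, 1))
  cond2 <- rbind(mk("g1", 100, 1), mk("g2", 131, 4), mk("g3", 160, 2))
  st <- distance_and_density_stats(list(wt = cond1, mut = cond2))
  m <- st$medians
  expect_equal(m$median_distance[m$condition == "wt"], 77)
  # summed density over g2's two sites
  pg <- st$per_gene
  expect_equal(pg$sum_rpm[pg$condition == "wt" & pg$gene_id == "g2"], 10)
  expect_equal(st$tests$n_pairs, 3L)
  expect_true(st$tests$distance_p > 0 && st$tests$distance_p <= 1)
})

test_that("noise-free synthetic closure recovers every planted site exactly
           and assigns no decoy", {
  cfg0 <- sim_config(n_mrna = 6, n_snorna = 10, n_snrna = 2, n_no_pas = 0,
                     chrom_length = 120000, frac_one_t = 0,
                     frac_low_mapq = 0, frac_cds_internal = 0)
  toy <- make_toy_annotation(cfg0, seed = 21)
  aln <- simulate_3reads_alignments(toy$annotation, toy$truth, cfg0,
                                    seed = 22)
  sites <- call_pas_sites(detect_pas_reads(aln))
  planted <- toy$truth$planted_pas
  expect_equal(nrow(sites), nrow(planted))
  o <- order(planted$position, planted$strand)
  expect_equal(sites$position, planted$position[o])
  expect_equal(sites$strand, planted$strand[o])
  expect_equal(sites$read_count, planted$expected_read_count[o])
  # with decoys on, every planted site is still assigned and no decoy is
  cfg1 <- sim_config(n_mrna = 6, n_snorna = 10, n_snrna = 2, n_no_pas = 0,
                     chrom_length = 120000, frac_one_t = 0.2,
                     frac_low_mapq = 0.2, frac_cds_internal = 0.2)
  aln1 <- simulate_3reads_alignments(toy$annotation, toy$truth, cfg1,
                                     seed = 23)
  asg <- assign_pas_to_genes(call_pas_sites(detect_pas_reads(aln1)),
                             toy$annotation)
  key <- function(p, s, st) paste(p, s, st)
  expect_setequal(key(asg$position, asg$strand, asg$gene_id),
                  key(planted$position, planted$strand, planted$gene_id))
  # every single-T decoy read fails detection
  aln2 <- simulate_3reads_alignments(toy$annotation, toy$truth, cfg1,
                                     seed = 24)
  one_t <- grepl("^decoy1t", aln2$read_id)
  det <- detect_pas_reads(aln2[one_t, , drop = FALSE])
  expect_equal(nrow(det), 0L)
  expect_gt(sum(one_t), 0L)
})
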