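test_that("toy annotation honors gene counts, spacing, and determinism", {
  cfg <- sim_config(n_mrna = 0, n_snorna = 31, n_snrna = 0, n_no_pas = 0,
                    chrom_length = 150000)
  toy <- make_toy_annotation(cfg, seed = 5)
  g <- toy$annotation$genes
  expect_equal(sum(g$biotype == "snoRNA_mono"), 31L)
  expect_gte(nrow(toy$truth$planted_pas), 31L)
  # min intergenic distance over all adjacent pairs >= 1000 nt
  o <- order(g$start)
  gaps <- g$start[o][-1] - g$end[o][-length(o)]
  expect_true(all(gaps >= 1000))
  # deterministic under the seed, and pure (RNG state restored)
  toy2 <- make_toy_annotation(cfg, seed = 5)
  expect_identical(toy$annotation$genes, toy2$annotation$genes)
  expect_identical(toy$truth$planted_pas, toy2$truth$planted_pas)
  expect_error(make_toy_annotation(sim_config(chrom_length = 10000),
                                   seed = 1),
               "chrom_length")
})

test_that("planted PAS lie 20-300 nt downstream of their gene's 3' end", {
  cfg <- sim_config(n_mrna = 5, n_snorna = 10, n_snrna = 2, n_no_pas = 3,
                    chrom_length = 120000)
  toy <- make_toy_annotation(cfg, seed = 8)
  p <- toy$truth$planted_pas
  g <- toy$annotation$genes
  d <- polyAterm:::pas_distance(p$position, p$strand,
                                g[p$gene_id, "annotated_3end"])
  expect_true(all(d >= 20 & d <= 300))
  expect_equal(d, p$planted_distance)
  expect_equal(length(toy$truth$no_pas_genes), 3L)
  expect_true(all(!toy$truth$no_pas_genes %in% p$gene_id))
})

test_that("noise-free alignments realize the planted counts and T runs", {
  cfg <- sim_config(n_mrna = 0, n_snorna = 1, n_snrna = 0, n_no_pas = 0,
                    chrom_length = 20000, frac_one_t = 0,
                    frac_low_mapq = 0, frac_cds_internal = 0)
  toy <- make_toy_annotation(cfg, seed = 2)
  aln <- simulate_3reads_alignments(toy$annotation, toy$truth, cfg,
                                    seed = 2)
  expect_equal(nrow(aln), sum(toy$truth$planted_pas$expected_read_count))
  expect_true(all(grepl("^T{2,}$", aln$clip5_seq)))
  expect_true(all(aln$mapq > 10))
  aln2 <- simulate_3reads_alignments(toy$annotation, toy$truth, cfg,
                                     seed = 2)
  expect_identical(aln, aln2)
})

test_that("adversarial single-T fraction yields only rejectable records", {
  cfg <- sim_config(n_mrna = 0, n_snorna = 2, n_snrna = 0, n_no_pas = 2,
                    chrom_length = 30000, frac_one_t = 1)
  toy <- make_toy_annotation(cfg, seed = 3)
  # no planted PAS at all when every snoRNA is PAS-less
  expect_equal(nrow(toy$truth$planted_pas), 0L)
})

test_that("single-T decoys carry exactly one T and fail detection", {
  cfg <- sim_config(n_mrna = 2, n_snorna = 4, n_snrna = 0, n_no_pas = 0,
                    chrom_length = 50000, frac_one_t = 0.5,
                    frac_low_mapq = 0, frac_cds_internal = 0)
  toy <- make_toy_annotation(cfg, seed = 6)
  aln <- simulate_3reads_alignments(toy$annotation, toy$truth, cfg,
                                    seed = 7)
  one_t <- grepl("^decoy1t", aln$read_id)
  expect_true(all(aln$clip5_seq[one_t] == "T"))
  det <- detect_pas_reads(aln)
  expect_equal(nrow(det), sum(!one_t))
})

test_that("noise-free coverage encodes alpha and the read-through shift", {
  cfg <- sim_config(n_mrna = 3, n_snorna = 6, n_snrna = 0, n_no_pas = 0,
                    chrom_length = 80000, alpha = 0.4,
                    readthrough_shift = 200)
  toy <- make_toy_annotation(cfg, seed = 9)
  ann <- toy$annotation
  wt <- simulate_chip_coverage(ann, toy$truth, cfg, "WT", "IP", seed = 9)
  mut <- simulate_chip_coverage(ann, toy$truth, cfg, "mutant", "IP",
                                seed = 9)
  tot <- function(sig) sum((sig$end - sig$start) * sig$value)
  # construction contract: spike-normalized total ratio is exactly alpha
  ratio <- (tot(mut$experimental) / tot(mut$spikein)) /
    (tot(wt$experimental) / tot(wt$spikein))
  expect_equal(ratio, 0.4, tolerance = 1e-12)
  # mutant signal covers (3' end, 3' end + 200]; WT is zero there
  base_cov <- function(sig, len) {
    v <- numeric(len)
    for (i in seq_len(nrow(sig))) {
      v[(sig$start[i] + 1):sig$end[i]] <- v[(sig$start[i] + 1):sig$end[i]] +
        sig$value[i]
    }
    v
  }
  len <- ann$chrom_sizes[["sp_I"]]
  wt_v <- base_cov(wt$experimental, len)
  mut_v <- base_cov(mut$experimental, len)
  for (i in seq_len(nrow(ann$genes))) {
    g <- ann$genes[i, ]
    rt <- if (g$strand == "+") (g$end + 1):(g$end + 200) else
      (g$start - 199):g$start
    expect_true(all(mut_v[rt] > 0), info = g$gene_id)
    expect_true(all(wt_v[rt] == 0), info = g$gene_id)
  }
})

test_that("Poisson coverage recovers alpha through the spike-in chain", {
  cfg <- sim_config(n_mrna = 3, n_snorna = 6, n_snrna = 0, n_no_pas = 0,
                    chrom_length = 80000, alpha = 0.4, depth = 1e6)
  toy <- make_toy_annotation(cfg, seed = 13)
  ann <- toy$annotation
  get <- function(cond) {
    cov <- simulate_chip_coverage(ann, toy$truth, cfg, cond, "IP",
                                  seed = 13, noise = "poisson")
    list(ip_exp = bin_track(cov$experimental, ann$chrom_sizes["sp_I"], 10),
         ip_spike = bin_track(cov$spikein, ann$chrom_sizes["sc_I"], 10,
                              species = "spikein"),
         input_exp = NULL, input_spike = NULL)
  }
  res <- normalize_spikein_pair(get("WT"), get("mutant"))
  alpha_hat <- total_signal(res$mut_sclWT) / total_signal(res$wt_sclWT)
  expect_lt(abs(alpha_hat / 0.4 - 1), 0.02)
})
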