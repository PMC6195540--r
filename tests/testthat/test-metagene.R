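layout_ann <- function() {
  genes <- rbind(
    toy_gene("up", 1000, 2000, strand = "+", biotype = "mRNA"),
    toy_gene("mid", 4000, 4200, strand = "+"),
    toy_gene("dn", 6000, 7000, strand = "+", biotype = "mRNA"),
    toy_gene("neg", 9000, 9200, strand = "-"))
  toy_annotation(genes, chrom_sizes = c(chrI = 20000))
}

test_that("the split gene block anchors both halves as specified", {
  ann <- layout_ann()
  lay <- build_block_layout("mid", ann, mode = "four_anchor",
                            window_width = 10,
                            block_windows = c(upstream_gene = 2,
                                              upstream_intergenic = 10,
                                              gene = 30,
                                              downstream_intergenic = 10,
                                              downstream_gene = 2))
  gb <- lay[lay$block == "gene", ]
  # first 15 windows cover [TSS, TSS+150); last 15 cover [3'end-150, 3'end)
  expect_equal(gb$start[1:15], 4000 + 10 * (0:14))
  expect_equal(gb$end[15], 4150)
  expect_equal(gb$start[16:30], 4050 + 10 * (0:14))
  expect_equal(gb$end[30], 4200)
  # gene is 200 nt with 30 windows: windows beyond 150 from an anchor
  # overlap the middle; none is missing
  expect_false(any(gb$missing))
  # ignore blocks reserve space but carry no coordinates
  expect_true(all(lay$ignore[lay$block == "upstream_gene"]))
  expect_true(all(is.na(lay$start[lay$ignore])))
})

test_that("gene windows beyond the feature length are missing", {
  genes <- toy_gene("tiny", 5000, 5100, strand = "+")
  ann <- toy_annotation(genes, chrom_sizes = c(chrI = 20000))
  lay <- build_block_layout("tiny", ann, mode = "two_anchor",
                            window_width = 10,
                            block_windows = c(upstream_intergenic = 5,
                                              gene = 30,
                                              downstream_intergenic = 5))
  gb <- lay[lay$block == "gene", ]
  # 100 nt gene: only 10 windows from each anchor fit
  expect_equal(which(!gb$missing), c(1:10, 21:30))
})

test_that("minus-strand layouts mirror genomic coordinates", {
  ann <- layout_ann()
  bw <- c(upstream_intergenic = 4, gene = 6, downstream_intergenic = 4)
  lay <- build_block_layout("neg", ann, mode = "two_anchor",
                            window_width = 10, block_windows = bw)
  # gene neg: [9000, 9200) on -; TSS boundary 9200, 3' end boundary 9000
  up <- lay[lay$block == "upstream_intergenic", ]
  expect_equal(up$start[4], 9200)      # window adjacent to the TSS
  expect_equal(up$end[4], 9210)
  expect_equal(up$start[1], 9230)      # furthest window first in profile
  gb <- lay[lay$block == "gene", ]
  expect_equal(gb$start[1], 9190)      # first gene window abuts the TSS
  expect_equal(gb$end[1], 9200)
  dn <- lay[lay$block == "downstream_intergenic", ]
  expect_equal(dn$end[1], 9000)        # first downstream window at 3' end
  expect_equal(dn$start[1], 8990)
  # profile order runs opposite to genomic order
  expect_true(all(diff(gb$start) < 0))
})

test_that("four-anchor intergenic windows never reach the neighbor gene", {
  ann <- layout_ann()
  lay <- build_block_layout("mid", ann, mode = "four_anchor",
                            window_width = 10,
                            block_windows = c(upstream_gene = 2,
                                              upstream_intergenic = 250,
                                              gene = 10,
                                              downstream_intergenic = 250,
                                              downstream_gene = 2))
  up <- lay[lay$block == "upstream_intergenic" & !lay$missing, ]
  expect_true(all(up$start >= 2000))   # upstream gene ends at 2000
  dn <- lay[lay$block == "downstream_intergenic" & !lay$missing, ]
  expect_true(all(dn$end <= 6000))     # downstream gene starts at 6000
})

test_that("extraction matches a brute-force per-base oracle", {
  ann <- layout_ann()
  set.seed(17)
  sig <- random_signal(c(chrI = 20000), n_intervals = 40)
  tr <- bin_track(sig, c(chrI = 20000), bin_width = 10)
  genes <- c("mid", "neg")
  layouts <- lapply(genes, build_block_layout, ann = ann,
                    mode = "two_anchor", window_width = 10,
                    block_windows = c(upstream_intergenic = 8, gene = 12,
                                      downstream_intergenic = 8))
  names(layouts) <- genes
  mat <- extract_gene_matrix(tr, layouts, ann)
  for (gi in seq_along(genes)) {
    lay <- layouts[[gi]]
    for (j in which(!lay$missing)) {
      expect_equal(unname(mat[gi, j]),
                   brute_force_window_mean(tr, "chrI", lay$start[j],
                                           lay$end[j]),
                   tolerance = 1e-12)
    }
  }
  # constant track: all non-missing cells equal the constant
  ct <- flat_track(7, nbins = 2000, bin_width = 10, chrom = "chrI")
  mat7 <- extract_gene_matrix(ct, layouts, ann)
  expect_true(all(mat7[!is.na(mat7)] == 7))
})

test_that("aggregation averages genes with missing-as-zero", {
  layout <- data.frame(block = "gene", window = 1:2,
                       ignore = FALSE, stringsAsFactors = FALSE)
  mat <- rbind(c(2, 4), c(4, 8))
  attr(mat, "layout") <- layout
  prof <- aggregate_profile(mat)
  expect_equal(prof$value, c(3, 6))
  mat2 <- rbind(c(NA, 2), c(6, 2))
  attr(mat2, "layout") <- layout
  prof2 <- aggregate_profile(mat2)
  expect_equal(prof2$value[1], 3)      # (0 + 6) / 2
  expect_equal(prof2$n_contributing, c(1, 2))
  # permutation invariance over genes
  mat3 <- mat2[2:1, ]
  attr(mat3, "layout") <- layout
  expect_equal(aggregate_profile(mat3)$value, prof2$value)
  expect_error(aggregate_profile(mat2[0, , drop = FALSE]), "empty")
})

test_that("smoothing is a block-confined centered moving average", {
  layout <- data.frame(block = rep(c("a", "b"), c(5, 3)), window = 1:8,
                       ignore = FALSE, stringsAsFactors = FALSE)
  mat <- matrix(c(0, 0, 1, 0, 0, 1, 0, 0), nrow = 1)
  attr(mat, "layout") <- layout
  prof <- aggregate_profile(mat)
  sm <- smooth_profile(prof, s = 1)
  # impulse in block a spreads to 1/3 over three windows, shrinking at edges
  expect_equal(sm$value[1:5], c(0, 1/3, 1/3, 1/3, 0))
  # block b smooths independently: impulse at its first window
  expect_equal(sm$value[6:8], c(1/2, 1/3, 0))
  # identity and constant cases
  expect_equal(smooth_profile(prof, s = 0)$value, prof$value)
  const <- aggregate_profile(structure(matrix(5, 1, 8), layout = layout))
  expect_equal(smooth_profile(const, s = 3)$value, rep(5, 8))
})

test_that("a single gene with s = 0 reproduces the track over its windows", {
  ann <- layout_ann()
  set.seed(23)
  sig <- random_signal(c(chrI = 20000), n_intervals = 30)
  tr <- bin_track(sig, c(chrI = 20000), bin_width = 10)
  prof <- metagene_profile(tr, ann, "mid", mode = "two_anchor",
                           window_width = 10,
                           block_windows = c(upstream_intergenic = 5,
                                             gene = 10,
                                             downstream_intergenic = 5),
                           smoothing = 0)
  gb <- which(prof$block == "gene")[1:5]   # TSS-anchored half, in-gene
  # gene mid: [4000, 4200), windows align with 10 nt track bins
  expect_equal(prof$value[gb], tr$values$chrI[401:405])
})

test_that("read-through shifts the 3' half-maximum crossing downstream", {
  cfg <- sim_config(n_mrna = 0, n_snorna = 12, n_snrna = 0, n_no_pas = 0,
                    chrom_length = 100000, alpha = 1,
                    readthrough_shift = 200)
  toy <- make_toy_annotation(cfg, seed = 31)
  ann <- toy$annotation
  wt <- simulate_chip_coverage(ann, toy$truth, cfg, "WT", "IP", seed = 31)
  mut <- simulate_chip_coverage(ann, toy$truth, cfg, "mutant", "IP",
                                seed = 31)
  mk <- function(cov) bin_track(cov$experimental, ann$chrom_sizes["sp_I"],
                                10)
  genes <- ann$genes$gene_id
  p_wt <- metagene_profile(mk(wt), ann, genes, mode = "two_anchor")
  p_mut <- metagene_profile(mk(mut), ann, genes, mode = "two_anchor")
  shift <- halfmax_crossing_3p(p_mut) - halfmax_crossing_3p(p_wt)
  expect_gte(shift, 150)
})
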