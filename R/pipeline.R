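# Pipeline configuration and subcommand drivers. Each run_* function is a
# thin orchestration layer over the module functions, writing plain-text
# artifacts plus an effective-config provenance file; the Rscript front-end
# in inst/scripts/polyaterm dispatches to run_subcommand().

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: `min_t = 2` untemplated
#' Ts, MAPQ strictly `> 10`, assignment window 1000 nt with 500 nt CDS
#' overlap rescue, minimal support 2 reads, 10 nt bins, reference total 1e8
#' coverage-bases, smoothing 6 windows, correlation resolution 10 nt.
#'
#' @param ... overrides for individual keys; unknown keys are rejected.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_t = 2, min_mapq_exclusive = 10, merge_window = 0,
    window = 1000, overlap_window = 500, min_support = 2,
    bin_width = 10, target = 1e8, clamp_negative = FALSE,
    min_denominator = 1, smoothing = 6, resolution = 10,
    window_width = 10, metagene_mode = "two_anchor",
    chrom_species_map = list(sp_ = "experimental", sc_ = "spikein"),
    seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(utils::modifyList(defaults, overrides),
            class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#'
#' Unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Species of a chromosome under a prefix map
#'
#' Concatenated two-species genomes are represented by chromosome name
#' prefixes (e.g. `sp_` vs `sc_`) rather than renamed references.
#'
#' @param chrom chromosome name(s).
#' @param map named list prefix -> species.
#' @return character vector of species.
#' @export
chrom_species <- function(chrom, map = pipeline_config()$chrom_species_map) {
  out <- rep(NA_character_, length(chrom))
  for (prefix in names(map)) {
    hit <- startsWith(chrom, prefix)
    out[hit] <- map[[prefix]]
  }
  if (anyNA(out)) {
    stop("chromosome(s) match no species prefix: ",
         paste(unique(chrom[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

write_provenance <- function(outdir, config, extra = list()) {
  prov <- c(list(package = "polyAterm",
                 version = as.character(utils::packageVersion("polyAterm")),
                 config = unclass(config)), extra)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the `simulate` stage
#'
#' Writes `annotation.gtf`, `alignments.sam`, the eight
#' `{wt,mut}_{ip,input}_{exp,spike}.bedgraph` coverage files, and
#' `truth.json` into `outdir`.
#'
#' @param outdir output directory (created).
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param noise `"none"` or `"poisson"` for the coverage simulation.
#' @param config a [pipeline_config()].
#' @return list with `annotation`, `truth` and the artifact paths,
#'   invisibly.
#' @export
run_simulate <- function(outdir, cfg = sim_config(), seed = 1L,
                         noise = "none", config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_annotation(cfg, seed)
  ann <- toy$annotation
  write_annotation(ann, file.path(outdir, "annotation.gtf"))
  aln <- simulate_3reads_alignments(ann, toy$truth, cfg, seed + 1L)
  write_alignments(aln, file.path(outdir, "alignments.sam"),
                   chrom_sizes = ann$chrom_sizes)
  for (cond in c("WT", "mutant")) {
    for (chan in c("IP", "input")) {
      cov <- simulate_chip_coverage(ann, toy$truth, cfg, cond, chan,
                                    seed = seed + 2L, noise = noise)
      stem <- sprintf("%s_%s", ifelse(cond == "WT", "wt", "mut"),
                      tolower(chan))
      write_signal(cov$experimental,
                   file.path(outdir, paste0(stem, "_exp.bedgraph")))
      write_signal(cov$spikein,
                   file.path(outdir, paste0(stem, "_spike.bedgraph")))
    }
  }
  jsonlite::write_json(
    list(planted_pas = toy$truth$planted_pas,
         no_pas_genes = toy$truth$no_pas_genes,
         alpha = toy$truth$alpha,
         readthrough_shift = toy$truth$readthrough_shift,
         spike_fraction = toy$truth$spike_fraction, seed = seed),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  write_provenance(outdir, config, list(stage = "simulate", seed = seed))
  invisible(list(annotation = ann, truth = toy$truth, outdir = outdir))
}

#' Run the `pas-call` stage
#'
#' Detect PAS reads, call and assign sites, pick per-gene strongest sites,
#' and write the PAS table (TSV + BED6) and the updated-3'-end table.
#'
#' @param alignments path to SAM/TSV alignments, or an alignment
#'   data.frame.
#' @param annotation path to a GTF, or a [term_annotation].
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @param patches optional gene ids to strand-invert before assignment.
#' @return list with `sites`, `assignments`, `strongest`,
#'   `updated_annotation`, invisibly.
#' @export
run_pas_call <- function(alignments, annotation, outdir,
                         config = pipeline_config(), patches = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ann <- if (is.character(annotation)) read_annotation(annotation)
         else annotation
  if (!is.null(patches)) ann <- apply_annotation_patches(ann, patches)
  aln <- if (is.character(alignments)) read_alignments(alignments)
         else alignments
  reads <- detect_pas_reads(aln, min_t = config$min_t,
                            min_mapq_exclusive = config$min_mapq_exclusive)
  sites <- call_pas_sites(reads, merge_window = config$merge_window)
  assignments <- assign_pas_to_genes(
    sites, ann, window = config$window,
    overlap_window = config$overlap_window,
    min_support = config$min_support)
  strongest <- strongest_pas(assignments)
  updated <- update_3end_coordinates(ann, strongest)
  write_pas_table(assignments, file.path(outdir, "pas_assignments.tsv"))
  utils::write.table(sites, file.path(outdir, "pas_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ut <- attr(updated, "update_table")
  if (!is.null(ut)) {
    ut$strongest_rpm <- strongest$rpm[match(ut$gene_id, strongest$gene_id)]
    utils::write.table(ut, file.path(outdir, "updated_3ends.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_provenance(outdir, config, list(
    stage = "pas-call", n_reads = nrow(aln), n_pas_reads = nrow(reads),
    n_sites = nrow(sites), n_assigned = nrow(assignments)))
  invisible(list(sites = sites, assignments = assignments,
                 strongest = strongest, updated_annotation = updated))
}

load_sim_sample <- function(dir, cond, chan, chrom_sizes, bin_width) {
  stem <- sprintf("%s_%s", cond, chan)
  exp_sig <- read_signal(file.path(dir, paste0(stem, "_exp.bedgraph")))
  spk_sig <- read_signal(file.path(dir, paste0(stem, "_spike.bedgraph")))
  exp_chroms <- names(chrom_sizes)[
    chrom_species(names(chrom_sizes)) == "experimental"]
  spk_chroms <- setdiff(names(chrom_sizes), exp_chroms)
  list(exp = bin_track(exp_sig, chrom_sizes[exp_chroms], bin_width,
                       species = "experimental"),
       spike = bin_track(spk_sig, chrom_sizes[spk_chroms], bin_width,
                         species = "spikein"))
}

#' Run the `chip-norm` stage on a simulate output directory
#'
#' Bins the eight bedGraphs at `config$bin_width`, applies the spike-in
#' WT/mutant chain, and writes the normalized tracks (WIG) plus the
#' normalization factors (JSON).
#'
#' @param simdir directory written by [run_simulate()].
#' @param outdir output directory.
#' @param chrom_sizes named vector covering both species.
#' @param config a [pipeline_config()].
#' @return the [normalize_spikein_pair()] result, invisibly.
#' @export
run_chip_norm <- function(simdir, outdir, chrom_sizes,
                          config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bw <- config$bin_width
  wt_ip <- load_sim_sample(simdir, "wt", "ip", chrom_sizes, bw)
  wt_in <- load_sim_sample(simdir, "wt", "input", chrom_sizes, bw)
  mut_ip <- load_sim_sample(simdir, "mut", "ip", chrom_sizes, bw)
  mut_in <- load_sim_sample(simdir, "mut", "input", chrom_sizes, bw)
  res <- normalize_spikein_pair(
    wt = list(ip_exp = wt_ip$exp, ip_spike = wt_ip$spike,
              input_exp = wt_in$exp, input_spike = wt_in$spike),
    mut = list(ip_exp = mut_ip$exp, ip_spike = mut_ip$spike,
               input_exp = mut_in$exp, input_spike = mut_in$spike),
    target = config$target, clamp = config$clamp_negative)
  write_track(res$wt_sclWT, file.path(outdir, "wt_normSI_sclWT.wig"))
  write_track(res$mut_sclWT, file.path(outdir, "mut_normSI_sclWT.wig"))
  write_track(res$wt_final, file.path(outdir, "wt_normSI_sclWT-ctrl.wig"))
  write_track(res$mut_final, file.path(outdir, "mut_normSI_sclWT-ctrl.wig"))
  jsonlite::write_json(res$records, file.path(outdir, "factors.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(outdir, config, list(
    stage = "chip-norm",
    alpha_hat = total_signal(res$mut_sclWT) / total_signal(res$wt_sclWT)))
  invisible(res)
}

#' Run the `metagene` stage
#'
#' @param track a [coverage_track] (normalized).
#' @param ann a [term_annotation].
#' @param genes gene ids to aggregate over.
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @param label file stem for the profile TSV.
#' @return the `metagene_profile`, invisibly.
#' @export
run_metagene <- function(track, ann, genes, outdir,
                         config = pipeline_config(), label = "profile") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prof <- metagene_profile(track, ann, genes,
                           mode = config$metagene_mode,
                           window_width = config$window_width,
                           smoothing = config$smoothing)
  write_profile(prof, file.path(outdir, paste0(label, ".tsv")))
  write_provenance(outdir, config, list(stage = "metagene",
                                        n_genes = length(genes)))
  invisible(prof)
}

#' Run the `correlate` stage
#'
#' @param tracks named list of [coverage_track]s.
#' @param outdir output directory.
#' @param config a [pipeline_config()].
#' @return the `track_correlation`, invisibly.
#' @export
run_correlate <- function(tracks, outdir, config = pipeline_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mat <- genome_matrix(tracks, resolution = config$resolution)
  corr <- pearson_matrix(mat)
  write_correlation(corr, file.path(outdir, "correlation.tsv"))
  write_provenance(outdir, config, list(stage = "correlate"))
  invisible(corr)
}

#' Run the full synthetic demonstration pipeline
#'
#' Chains simulate, pas-call, chip-norm, metagene, and correlate on
#' synthetic data and writes `summary.json` reporting PAS recovery against
#' the planted truth, the recovered occupancy factor, and the read-through
#' shift of the mutant metagene 3' flank. Byte-reproducible under a fixed
#' seed.
#'
#' @param outdir output directory.
#' @param seed integer seed.
#' @param cfg a [sim_config()].
#' @param config a [pipeline_config()].
#' @param noise coverage noise model (`"none"` or `"poisson"`).
#' @return the summary list, invisibly.
#' @export
run_full_demo <- function(outdir, seed = 1L, cfg = sim_config(),
                          config = pipeline_config(), noise = "none") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- run_simulate(file.path(outdir, "simulate"), cfg, seed,
                      noise = noise, config = config)
  ann <- sim$annotation
  truth <- sim$truth
  pas <- run_pas_call(file.path(outdir, "simulate", "alignments.sam"),
                      ann, file.path(outdir, "pas"), config = config)
  norm <- run_chip_norm(file.path(outdir, "simulate"),
                        file.path(outdir, "norm"), ann$chrom_sizes,
                        config = config)
  sno <- ann$genes$gene_id[ann$genes$biotype == "snoRNA_mono"]
  sno_pas <- intersect(sno, unique(truth$planted_pas$gene_id))
  prof_wt <- run_metagene(norm$wt_sclWT, ann, sno_pas,
                          file.path(outdir, "metagene"), config = config,
                          label = "wt_snoRNA")
  prof_mut <- run_metagene(norm$mut_sclWT, ann, sno_pas,
                           file.path(outdir, "metagene"), config = config,
                           label = "mut_snoRNA")
  corr <- run_correlate(
    list(wt_sclWT = norm$wt_sclWT, mut_sclWT = norm$mut_sclWT,
         wt_final = norm$wt_final, mut_final = norm$mut_final),
    file.path(outdir, "correlate"), config = config)
  planted <- truth$planted_pas
  called <- pas$assignments
  key <- function(d, pos) paste(d$chrom, d$strand, pos, sep = ":")
  planted_keys <- key(planted, planted$position)
  called_keys <- key(called, called$position)
  shift_wt <- halfmax_crossing_3p(prof_wt, config$window_width)
  shift_mut <- halfmax_crossing_3p(prof_mut, config$window_width)
  summary <- list(
    seed = seed,
    n_planted_pas = nrow(planted),
    n_called_assigned = nrow(called),
    n_planted_recovered = sum(planted_keys %in% called_keys),
    n_genes_with_planted_pas = length(unique(planted$gene_id)),
    n_genes_with_assigned_pas = length(unique(called$gene_id)),
    alpha_true = truth$alpha,
    alpha_recovered = total_signal(norm$mut_sclWT) /
      total_signal(norm$wt_sclWT),
    readthrough_shift_true = truth$readthrough_shift,
    halfmax_crossing_wt_nt = shift_wt,
    halfmax_crossing_mut_nt = shift_mut,
    halfmax_shift_nt = shift_mut - shift_wt,
    mean_wt_mut_correlation = unname(corr$r["wt_sclWT", "mut_sclWT"]))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Dispatch a pipeline subcommand
#'
#' Entry point used by the `polyaterm` command-line script. Supported
#' subcommands: `simulate`, `full-demo` (the file-driven stages `pas-call`,
#' `chip-norm`, `metagene`, `correlate` are reachable through `full-demo`
#' or the R API).
#'
#' @param name subcommand name.
#' @param args character vector of `--flag value` arguments (`--out`,
#'   `--seed`, `--noise`, `--config`).
#' @return 0 on success (invisibly); errors propagate.
#' @export
run_subcommand <- function(name, args = character()) {
  parse_flags <- function(args) {
    out <- list()
    i <- 1L
    while (i <= length(args)) {
      if (!startsWith(args[i], "--") || i == length(args)) {
        stop("usage: polyaterm <subcommand> --flag value ...",
             call. = FALSE)
      }
      out[[substring(args[i], 3L)]] <- args[i + 1L]
      i <- i + 2L
    }
    out
  }
  flags <- parse_flags(args)
  known <- c("out", "seed", "noise", "config")
  unknown <- setdiff(names(flags), known)
  if (length(unknown)) {
    stop("unknown flag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  outdir <- flags$out %||% stop("--out is required", call. = FALSE)
  seed <- as.integer(flags$seed %||%
                       stop("--seed is required", call. = FALSE))
  noise <- flags$noise %||% "none"
  config <- if (!is.null(flags$config)) read_pipeline_config(flags$config)
            else pipeline_config()
  switch(name,
    "simulate" = run_simulate(outdir, sim_config(), seed, noise = noise,
                              config = config),
    "full-demo" = run_full_demo(outdir, seed, config = config,
                                noise = noise),
    stop("unknown subcommand: ", name, call. = FALSE))
  invisible(0L)
}
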