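# Genome-wide track correlation: shared bin matrix at fixed resolution,
# pairwise Pearson coefficients, average-linkage clustering, group means.

#' Assemble the genome-wide bin matrix of several tracks
#'
#' Resamples every track to the requested resolution and stacks one row per
#' genomic bin across the shared chromosome set. By default, bins missing
#' in *any* track are dropped from all (complete rows), so every pairwise
#' coefficient is computed over the same bins; `pairwise = TRUE` keeps all
#' bins (downstream correlation then uses pairwise-complete observations).
#'
#' @param tracks named list of [coverage_track]s on the same chromosomes.
#' @param resolution bin size in nt (default 10).
#' @param pairwise keep rows with missing values.
#' @return numeric matrix bins x tracks (column names = track names).
#' @export
genome_matrix <- function(tracks, resolution = 10, pairwise = FALSE) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("`tracks` must be a fully named list", call. = FALSE)
  }
  chroms <- names(tracks[[1L]]$values)
  for (tr in tracks) {
    if (!identical(names(tr$values), chroms)) {
      stop("tracks cover different chromosome sets", call. = FALSE)
    }
  }
  res <- lapply(tracks, resample_track, bin_width = resolution)
  cols <- lapply(res, function(tr) unlist(tr$values, use.names = FALSE))
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(tracks)
  if (!pairwise) {
    mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  }
  mat
}

#' Pairwise Pearson correlation matrix with hierarchical clustering
#'
#' Standard Pearson coefficient per track pair, followed by average-linkage
#' hierarchical clustering on the distance `1 - r`.
#'
#' @param mat bin matrix from [genome_matrix()].
#' @param use passed to [stats::cor()] (`"everything"` for complete-row
#'   matrices, `"pairwise.complete.obs"` for pairwise mode).
#' @return An object of class `track_correlation`: `labels`, `r`
#'   (symmetric, unit diagonal), `n_bins`, `dendrogram`
#'   (a [stats::hclust] object).
#' @export
pearson_matrix <- function(mat, use = "everything") {
  if (ncol(mat) < 2L) stop("need at least two tracks", call. = FALSE)
  vars <- apply(mat, 2L, stats::var, na.rm = TRUE)
  zv <- names(vars)[!is.na(vars) & vars == 0]
  if (length(zv)) {
    stop("zero-variance track(s): ", paste(zv, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(mat, use = use)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(labels = colnames(mat), r = r, n_bins = nrow(mat),
                 dendrogram = hc),
            class = "track_correlation")
}

#' @export
print.track_correlation <- function(x, ...) {
  cat(sprintf("track_correlation: %d tracks over %d bins\n",
              length(x$labels), x$n_bins))
  print(round(x$r, 3))
  invisible(x)
}

#' Mean correlation between two groups of tracks
#'
#' Average of the Pearson coefficients over the A-by-B block of the matrix
#' (e.g. 3' processing factors vs CTD modifications).
#'
#' @param corr a `track_correlation`.
#' @param group_a,group_b disjoint, non-empty label sets.
#' @return scalar mean coefficient.
#' @export
group_mean <- function(corr, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), corr$labels)
  if (length(missing)) {
    stop("unknown track label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mean(corr$r[group_a, group_b])
}

#' Write a correlation matrix and its dendrogram
#'
#' TSV matrix plus a newick-style dendrogram text file (same stem,
#' `.nwk`).
#'
#' @param corr a `track_correlation`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(corr, path) {
  utils::write.table(cbind(track = corr$labels, as.data.frame(corr$r)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  nwk <- paste0(hclust_to_newick(corr$dendrogram), ";")
  writeLines(nwk, paste0(tools::file_path_sans_ext(path), ".nwk"))
  invisible(path)
}

hclust_to_newick <- function(hc) {
  build <- function(i) {
    if (i < 0) return(hc$labels[-i])
    pair <- hc$merge[i, ]
    sprintf("(%s,%s):%s", build(pair[1L]), build(pair[2L]),
            formatC(hc$height[i], digits = 6, format = "g"))
  }
  build(nrow(hc$merge))
}
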