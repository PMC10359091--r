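## Cell-type clustering of predicted methylation profiles: K-means on the
## cells x CpG-position matrix, t-SNE for visualization, and adjusted Rand
## index scoring against known cell types (ARI on the full matrix versus ARI
## on the top two t-SNE components).

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions
#' (up to label renaming), about 0 for random labelings.
#'
#' @param labels_a,labels_b vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("labelings must have equal length")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Build the cells x CpG-position matrix of predicted levels
#'
#' Columns are (chrom, position) of the C and G of every reference CpG inside
#' the promoter sequence windows; values are the model predictions at those
#' offsets. With `fill_missing`, positions whose true level is unavailable are
#' set to `fill_value` (the convention used when mixing in true levels is -1).
#'
#' @param graphs_by_cell named list: per cell, a list of `promoter_graph`s
#'   (one per chromosome).
#' @param preds_by_cell matching predictions (matrices per graph).
#' @param use one of "pred_all" (predictions at every CpG position),
#'   "pred_masked" (predictions where truth exists, `fill_value` elsewhere) or
#'   "true" (true levels where available, `fill_value` elsewhere).
#' @param genome named character vector of sequences (to locate CpGs).
#' @param fill_value value for unavailable positions (default -1).
#' @return numeric matrix, rownames = cell ids.
#' @export
prediction_matrix <- function(graphs_by_cell, preds_by_cell,
                              use = c("pred_all", "pred_masked", "true"),
                              genome, fill_value = -1) {
  use <- match.arg(use)
  rows <- lapply(names(graphs_by_cell), function(cid) {
    gs <- graphs_by_cell[[cid]]
    ps <- preds_by_cell[[cid]]
    unlist(lapply(seq_along(gs), function(k) {
      gr <- gs[[k]]
      vals <- lapply(seq_len(nrow(gr$regions)), function(r) {
        reg <- gr$regions[r, ]
        sq <- substr(genome[[reg$chrom]], reg$seq_start + 1L, reg$seq_end)
        off <- sort(c(cpg_offsets(sq)$c_off, cpg_offsets(sq)$g_off))
        if (length(off) == 0) return(numeric())
        v <- switch(use,
          pred_all = ps[[k]][r, off],
          pred_masked = ifelse(gr$mask[r, off], ps[[k]][r, off], fill_value),
          true = ifelse(gr$mask[r, off], gr$targets[r, off], fill_value))
        names(v) <- paste0(reg$chrom, ":", reg$seq_start + off - 1L)
        v
      })
      do.call(c, vals)
    }))
  })
  M <- do.call(rbind, rows)
  rownames(M) <- names(graphs_by_cell)
  M
}

#' Cluster cells from predicted methylation and score against true types
#'
#' K-means (10 restarts) with `n_clusters` centers on the full matrix gives
#' `ari_all_data`; t-SNE to two components followed by K-means on those
#' coordinates gives `ari_two_components`. All stochastic steps are seeded.
#'
#' @param predicted_matrix cells x positions numeric matrix.
#' @param true_types vector of known types (same order as rows), or NULL to
#'   skip ARI scoring.
#' @param n_clusters number of K-means clusters (default 4).
#' @param seed RNG seed.
#' @param perplexity t-SNE perplexity; reduced automatically when the cell
#'   count is small.
#' @return a `cluster_report` list: `kmeans_labels`, `tsne_xy`,
#'   `ari_all_data`, `ari_two_components`.
#' @export
cluster_cells <- function(predicted_matrix, true_types = NULL, n_clusters = 4,
                          seed = 1, perplexity = 30) {
  n <- nrow(predicted_matrix)
  if (n < n_clusters)
    stop("need at least ", n_clusters, " cells, got ", n)
  set.seed(seed)
  km <- safe_kmeans(predicted_matrix, n_clusters)
  perp <- min(perplexity, floor((n - 1) / 3))
  set.seed(seed)
  ts <- Rtsne::Rtsne(predicted_matrix, dims = 2, perplexity = max(perp, 1),
                     theta = if (n <= 500) 0 else 0.5,
                     check_duplicates = FALSE, pca = n > 50,
                     max_iter = 500)
  set.seed(seed)
  km2 <- safe_kmeans(ts$Y, n_clusters)
  structure(list(
    kmeans_labels = km,
    tsne_xy = ts$Y,
    ari_all_data = if (is.null(true_types)) NA_real_ else ari(km, true_types),
    ari_two_components = if (is.null(true_types)) NA_real_
                         else ari(km2, true_types)),
    class = "cluster_report")
}

## kmeans that tolerates fewer distinct rows than centers
safe_kmeans <- function(X, k, nstart = 10) {
  X <- X + stats::rnorm(length(X), sd = 1e-9)  # break exact duplicates
  stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50)$cluster
}

#' Rank promoters by their single-promoter clustering power
#'
#' Clusters cells using each promoter's predicted CpG levels alone, ranks
#' promoters by that ARI (descending), and reports the ARI obtained from the
#' concatenated top-k promoters for increasing k.
#'
#' @param promoter_matrices named list of cells x positions matrices, one per
#'   promoter.
#' @param true_types known cell types.
#' @param n_clusters K-means centers (default 4).
#' @param seed RNG seed.
#' @return list with `ranking` (data.frame promoter, ari) and `cumulative`
#'   (data.frame top_k, ari).
#' @export
rank_promoters_by_ari <- function(promoter_matrices, true_types,
                                  n_clusters = 4, seed = 1) {
  scores <- vapply(promoter_matrices, function(M) {
    set.seed(seed)
    ari(safe_kmeans(M, n_clusters), true_types)
  }, 0)
  ord <- order(-scores, names(promoter_matrices))
  ranking <- data.frame(promoter = names(promoter_matrices)[ord],
                        ari = scores[ord], row.names = NULL)
  cumulative <- do.call(rbind, lapply(seq_along(ord), function(k) {
    M <- do.call(cbind, promoter_matrices[ord[seq_len(k)]])
    set.seed(seed)
    data.frame(top_k = k, ari = ari(safe_kmeans(M, n_clusters), true_types))
  }))
  list(ranking = ranking, cumulative = cumulative)
}
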