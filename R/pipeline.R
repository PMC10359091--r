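## High-level orchestration: meta-cells and graphs for a set of cells, and
## the end-to-end synthetic benchmark used for acceptance checking.

#' Build meta-cells and promoter graphs for a set of target cells
#'
#' Per-cell promoter contact matrices and the Hi-C similarity matrix are
#' computed once and shared across targets.
#'
#' @param targets list of `cell`s to build graphs for.
#' @param pool list of `cell`s that may serve as neighbours (typically a
#'   superset of `targets`).
#' @param regions_by_chrom named list of per-chromosome region data.frames.
#' @param genome named character vector of sequences.
#' @param k meta-cell neighbour count (default 20).
#' @param restrict_to_type restrict neighbours to the target's type (used for
#'   training/validation cells; blind-test cells use the full pool).
#' @param bin_size Hi-C similarity bin width in bp.
#' @param encoder node sequence encoder.
#' @param occurrence edge-feature occurrence definition.
#' @return named list (by cell id) of lists of `promoter_graph`s (by
#'   chromosome).
#' @export
build_graphs <- function(targets, pool, regions_by_chrom, genome, k = 20,
                         restrict_to_type = FALSE, bin_size = 1e6,
                         encoder = make_kmer_encoder(), occurrence = "count") {
  all_cells <- pool
  pool_ids <- vapply(pool, `[[`, "", "cell_id")
  for (tc in targets)
    if (!tc$cell_id %in% pool_ids) all_cells <- c(all_cells, list(tc))
  sims <- hic_similarity_matrix(all_cells, bin_size)
  matrices <- lapply(all_cells, function(cl) {
    ms <- lapply(regions_by_chrom, function(reg)
      build_promoter_contact_matrix(cl, reg))
    names(ms) <- names(regions_by_chrom)
    ms
  })
  names(matrices) <- vapply(all_cells, `[[`, "", "cell_id")
  out <- lapply(targets, function(tc) {
    hic_meta <- select_hic_neighbors(tc, all_cells, regions_by_chrom, k = k,
                                     restrict_to_type = restrict_to_type,
                                     bin_size = bin_size, sims = sims,
                                     matrices = matrices)
    meth_meta <- aggregate_methylation(tc, all_cells, k = k,
                                       restrict_to_type = restrict_to_type)
    gs <- lapply(names(regions_by_chrom), function(chrom)
      assemble_graph(hic_meta, meth_meta, chrom, regions_by_chrom, genome,
                     encoder, occurrence))
    names(gs) <- names(regions_by_chrom)
    gs
  })
  names(out) <- vapply(targets, `[[`, "", "cell_id")
  out
}

#' Split cells into train/validation/test sets within each type
#'
#' @param cells list of `cell`s with type labels.
#' @param frac numeric length-3 vector of train/val/test fractions.
#' @param seed RNG seed for the shuffle.
#' @return list of three character vectors of cell ids.
#' @export
split_cells <- function(cells, frac = c(0.6, 0.2, 0.2), seed = 1) {
  stopifnot(abs(sum(frac) - 1) < 1e-8)
  ids <- vapply(cells, `[[`, "", "cell_id")
  types <- vapply(cells, `[[`, "", "cell_type")
  set.seed(seed)
  train <- character(); val <- character(); test <- character()
  for (t in unique(types)) {
    tid <- sample(ids[types == t])
    n <- length(tid)
    n_tr <- round(frac[1] * n)
    n_va <- round(frac[2] * n)
    train <- c(train, tid[seq_len(n_tr)])
    val <- c(val, tid[n_tr + seq_len(n_va)])
    test <- c(test, tid[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  assert_disjoint_splits(list(train = train, val = val, test = test))
}

#' @keywords internal
assert_disjoint_splits <- function(splits) {
  all_ids <- unlist(splits)
  if (anyDuplicated(all_ids))
    stop("split leakage: cell id(s) in more than one split: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  splits
}

#' End-to-end synthetic benchmark
#'
#' Simulates the strong-signal dataset, splits cells within each type, builds
#' meta-cells and graphs (type-restricted neighbours for train/validation,
#' full pool for test), trains the graph transformer, and evaluates held-out
#' prediction metrics, both naive baselines, cell clustering of the held-out
#' cells, and the zero-signal control (the trained model applied to a dataset
#' simulated with no topology signal).
#'
#' @param seed integer seed driving every stochastic step.
#' @param config a [sim_config()]; the default is the benchmark condition.
#' @param mconfig a [model_config()]; NULL uses the benchmark model
#'   (5 blocks, 1 head, hidden size 32, 4-mer node encoder).
#' @param kmer_k node-encoder k-mer size.
#' @param k meta-cell neighbours.
#' @param bin_size Hi-C similarity bin width (10 kb suits the synthetic
#'   chromosome scale).
#' @param run_zero_signal include the zero-signal control.
#' @param verbose print training progress.
#' @return list of metric results (see the acceptance script for the fields).
#' @export
run_benchmark <- function(seed = 1, config = sim_config(), mconfig = NULL,
                          kmer_k = 4, k = 20, bin_size = 1e4,
                          run_zero_signal = TRUE, verbose = FALSE) {
  genome_obj <- simulate_genome(config, seed = seed)
  sim <- simulate_cells(config, genome_obj, seed = seed)
  cells <- sim$cells
  ids <- vapply(cells, `[[`, "", "cell_id")
  types <- stats::setNames(vapply(cells, `[[`, "", "cell_type"), ids)
  splits <- split_cells(cells, seed = seed)
  encoder <- make_kmer_encoder(kmer_k)

  by_id <- function(sel) cells[ids %in% sel]
  trainval_pool <- by_id(c(splits$train, splits$val))
  graphs_tr <- build_graphs(by_id(splits$train), trainval_pool,
                            genome_obj$regions_by_chrom, genome_obj$genome,
                            k = k, restrict_to_type = TRUE,
                            bin_size = bin_size, encoder = encoder)
  graphs_va <- build_graphs(by_id(splits$val), trainval_pool,
                            genome_obj$regions_by_chrom, genome_obj$genome,
                            k = k, restrict_to_type = TRUE,
                            bin_size = bin_size, encoder = encoder)
  graphs_te <- build_graphs(by_id(splits$test), cells,
                            genome_obj$regions_by_chrom, genome_obj$genome,
                            k = k, restrict_to_type = FALSE,
                            bin_size = bin_size, encoder = encoder)

  if (is.null(mconfig))
    mconfig <- model_config(n_blocks = 5, n_heads = 1, d = 32,
                            edge_in_dim = k + 3, learning_rate = 2e-3,
                            max_epochs = 20, patience = 5, seed = seed)
  fit <- train_model(unlist(graphs_tr, recursive = FALSE),
                     unlist(graphs_va, recursive = FALSE),
                     mconfig, verbose = verbose)

  preds_te <- lapply(graphs_te, function(gs)
    lapply(gs, function(g) predict_graph(fit$params, g, fit$config)))

  ## pooled held-out metrics on masked positions
  pool_vec <- function(extract) unlist(lapply(names(graphs_te), function(cid)
    lapply(names(graphs_te[[cid]]), function(ch)
      extract(graphs_te[[cid]][[ch]], preds_te[[cid]][[ch]]))))
  pred_v <- pool_vec(function(g, p) p[g$mask])
  true_v <- pool_vec(function(g, p) g$targets[g$mask])
  metrics <- compute_metrics(pred_v, true_v)

  ## naive baselines on the same graphs
  naive_auc <- function(variant) {
    pv <- c(); tv <- c()
    for (cid in names(graphs_te)) for (ch in names(graphs_te[[cid]])) {
      g <- graphs_te[[cid]][[ch]]
      np <- naive_predictor(g, variant)
      m <- np$mask & g$mask
      pv <- c(pv, np$pred[m]); tv <- c(tv, g$targets[m])
    }
    compute_metrics(pv, tv)
  }
  naive1 <- naive_auc(1)
  naive2 <- naive_auc(2)

  ## clustering of held-out cells on predictions at all CpG positions
  pm <- prediction_matrix(graphs_te, preds_te, use = "pred_all",
                          genome = genome_obj$genome)
  clus <- cluster_cells(pm, true_types = types[rownames(pm)],
                        n_clusters = config$n_cell_types, seed = seed)

  tdist <- true_level_distribution(true_v)

  out <- list(metrics = metrics, naive1 = naive1, naive2 = naive2,
              cluster = clus, true_level_dist = tdist, fit = fit,
              splits = splits,
              n_eval = metrics$n_evaluated_positions,
              n_cells_test = nrow(pm))

  if (run_zero_signal) {
    zcfg <- config
    zcfg$beta_topo <- 0
    zcfg$contact_boost <- 0
    zgenome <- simulate_genome(zcfg, seed = seed + 1000L)
    zsim <- simulate_cells(zcfg, zgenome, seed = seed + 1000L)
    zids <- vapply(zsim$cells, `[[`, "", "cell_id")
    ztypes <- stats::setNames(vapply(zsim$cells, `[[`, "", "cell_type"), zids)
    zsplits <- split_cells(zsim$cells, seed = seed)
    ztargets <- zsim$cells[zids %in% zsplits$test]
    zgraphs <- build_graphs(ztargets, zsim$cells, zgenome$regions_by_chrom,
                            zgenome$genome, k = k, restrict_to_type = FALSE,
                            bin_size = bin_size, encoder = encoder)
    zpreds <- lapply(zgraphs, function(gs)
      lapply(gs, function(g) predict_graph(fit$params, g, fit$config)))
    zpm <- prediction_matrix(zgraphs, zpreds, use = "pred_all",
                             genome = zgenome$genome)
    zclus <- cluster_cells(zpm, true_types = ztypes[rownames(zpm)],
                           n_clusters = zcfg$n_cell_types, seed = seed)
    out$zero_signal_ari <- zclus$ari_all_data
  }
  out
}
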