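## Evaluation: PCC, MCC, average precision, ROC AUC and mean absolute error,
## restricted to base pairs with true methylation levels available, plus the
## stratified analyses (true-level bins, node degree) and naive baselines.

#' Prediction metrics on masked base pairs
#'
#' PCC and MAE are computed on the continuous levels. For MCC, AP and AUC the
#' truth is binarized at `threshold` (level >= threshold is class 1);
#' predictions serve as scores for AP/AUC and are thresholded at `threshold`
#' for MCC. When the binarized truth has a single class those three metrics
#' are NA and `single_class` is TRUE.
#'
#' @param pred,true numeric vectors/matrices of predictions and true levels.
#' @param mask logical of the same shape selecting evaluated positions; NULL
#'   evaluates everything non-NA.
#' @param threshold binarization threshold (default 0.5).
#' @return a `metric_report` list: `pcc`, `mcc`, `average_precision`, `auc`,
#'   `mean_abs_error`, `n_evaluated_positions`, `single_class`.
#' @export
compute_metrics <- function(pred, true, mask = NULL, threshold = 0.5) {
  if (is.null(mask)) mask <- !is.na(true)
  p <- as.numeric(pred)[as.logical(mask)]
  t_ <- as.numeric(true)[as.logical(mask)]
  if (length(p) < 2) stop("need at least 2 evaluated positions")
  lab <- as.integer(t_ >= threshold)
  single <- length(unique(lab)) < 2
  rep_ <- list(
    pcc = if (stats::sd(p) == 0 || stats::sd(t_) == 0) NA_real_
          else stats::cor(p, t_),
    mcc = if (single) NA_real_ else mcc_score(p >= threshold, lab == 1),
    average_precision = if (single) NA_real_ else average_precision(p, lab),
    auc = if (single) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(lab, p, quiet = TRUE,
                                     direction = "<", levels = c(0, 1)))),
    mean_abs_error = mean(abs(p - t_)),
    n_evaluated_positions = length(p),
    single_class = single)
  class(rep_) <- "metric_report"
  rep_
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("PCC %.3f  MCC %.3f  AP %.3f  AUC %.3f  MAE %.3f  (n = %d)\n",
              x$pcc, x$mcc, x$average_precision, x$auc, x$mean_abs_error,
              x$n_evaluated_positions))
  invisible(x)
}

#' Matthews correlation coefficient from binary predictions and labels
#' @param pred_bin,lab_bin logical vectors.
#' @return MCC in `[-1, 1]`; 0 when a confusion-matrix margin is empty.
#' @export
mcc_score <- function(pred_bin, lab_bin) {
  tp <- as.numeric(sum(pred_bin & lab_bin))
  tn <- as.numeric(sum(!pred_bin & !lab_bin))
  fp <- as.numeric(sum(pred_bin & !lab_bin))
  fn <- as.numeric(sum(!pred_bin & lab_bin))
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Average precision (step-wise integral of the precision-recall curve)
#'
#' AP = sum over threshold steps of (recall increment) x precision, with tied
#' scores grouped into a single step.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  ord <- order(-scores)
  s <- scores[ord]; l <- labels[ord]
  cum_tp <- cumsum(l == 1)
  cum_n <- seq_along(l)
  ## evaluate only at the last index of each tied-score group
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cum_tp[last_of_group]
  n <- cum_n[last_of_group]
  prec <- tp / n
  rec <- tp / npos
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Absolute error stratified by true methylation level
#'
#' Exact 0 and exact 1 get their own bins; the open interval is split into
#' (0, 0.1], ..., (0.9, 1).
#'
#' @param pred,true,mask as in [compute_metrics()].
#' @return data.frame with `bin`, `n`, `mean_abs_error`.
#' @export
error_by_true_level <- function(pred, true, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(true)
  p <- as.numeric(pred)[as.logical(mask)]
  t_ <- as.numeric(true)[as.logical(mask)]
  bins <- level_bins(t_)
  err <- abs(p - t_)
  agg <- tapply(err, bins, mean)
  cnt <- tapply(err, bins, length)
  data.frame(bin = names(agg), n = as.integer(cnt),
             mean_abs_error = as.numeric(agg), row.names = NULL)
}

level_bins <- function(x) {
  lab <- character(length(x))
  lab[x == 0] <- "0"
  lab[x == 1] <- "1"
  mid <- x > 0 & x < 1
  if (any(mid)) {
    idx <- pmin(floor(x[mid] * 10 - 1e-12), 9)
    lab[mid] <- sprintf("(%.1f,%.1f]", idx / 10, idx / 10 + 0.1)
  }
  lv <- c("0", sprintf("(%.1f,%.1f]", 0:9 / 10, 0:9 / 10 + 0.1), "1")
  factor(lab, levels = lv[lv %in% lab])
}

#' Distribution of true methylation levels over bins
#'
#' @param true numeric levels.
#' @param mask logical mask; NULL uses non-NA values.
#' @return data.frame `bin`, `n`, `fraction` (fractions sum to 1; exact 0 and
#'   exact 1 are separate bins).
#' @export
true_level_distribution <- function(true, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(true)
  t_ <- as.numeric(true)[as.logical(mask)]
  bins <- level_bins(t_)
  cnt <- table(bins)
  data.frame(bin = names(cnt), n = as.integer(cnt),
             fraction = as.integer(cnt) / length(t_), row.names = NULL)
}

#' Naive neighbour-based predictors
#'
#' Baselines that predict a promoter's base-pair methylation directly from
#' the true levels of its graph neighbours at the same window offsets.
#' Variant 1 copies the single most-connected neighbour (highest aggregated
#' contact count for the incident edge, ties to the lowest node index).
#' Variant 2 takes the contact-count-weighted mean over all neighbours.
#' Offsets where the used neighbours carry no value, and isolated nodes, stay
#' NA and are excluded from evaluation.
#'
#' @param graph a `promoter_graph` (its `targets`/`mask` supply the
#'   neighbours' true levels).
#' @param variant 1 or 2.
#' @return list with `pred` (n x 1000, NA where undefined) and `mask`
#'   (logical; defined positions).
#' @export
naive_predictor <- function(graph, variant = c(1, 2)) {
  variant <- match.arg(as.character(variant[1]), c("1", "2"))
  n <- nrow(graph$node_features)
  pred <- matrix(NA_real_, n, ncol(graph$targets))
  counts <- edge_aggregated_counts(graph)
  tg0 <- graph$targets; tg0[!graph$mask] <- 0
  for (i in seq_len(n)) {
    inc <- which(graph$edges[, 1] == i | graph$edges[, 2] == i)
    if (length(inc) == 0) next
    nb <- ifelse(graph$edges[inc, 1] == i, graph$edges[inc, 2],
                 graph$edges[inc, 1])
    w <- counts[inc]
    if (variant == "1") {
      best <- nb[order(-w, nb)][1]
      pred[i, graph$mask[best, ]] <- graph$targets[best, graph$mask[best, ]]
    } else {
      wsum <- colSums(graph$mask[nb, , drop = FALSE] * w)
      vsum <- colSums(tg0[nb, , drop = FALSE] * w)
      ok <- wsum > 0
      pred[i, ok] <- vsum[ok] / wsum[ok]
    }
  }
  list(pred = pred, mask = !is.na(pred))
}

## aggregated (summed over meta-cell members) contact count per edge
edge_aggregated_counts <- function(graph) {
  k1 <- ncol(graph$edge_features) - 2L
  if (nrow(graph$edge_features) == 0) return(numeric())
  rowSums(graph$edge_features[, seq_len(k1), drop = FALSE])
}

#' Metrics stratified by promoter node degree
#'
#' Pools evaluated positions across graphs by the degree of the node they
#' belong to and recomputes the metric set per degree value; also returns the
#' distribution of per-promoter average degree across graphs.
#'
#' @param graphs list of `promoter_graph`s.
#' @param preds list of prediction matrices matching `graphs`.
#' @param threshold binarization threshold.
#' @return list with `per_degree` (data.frame) and `avg_degree` (numeric, one
#'   value per promoter of each chromosome, averaged over graphs).
#' @export
degree_analysis <- function(graphs, preds, threshold = 0.5) {
  stopifnot(length(graphs) == length(preds))
  rows <- list()
  deg_acc <- list()
  for (g in seq_along(graphs)) {
    gr <- graphs[[g]]
    deg <- graph_degrees(gr)
    key <- gr$chrom
    deg_acc[[key]] <- rbind(deg_acc[[key]] %||% NULL, deg)
    for (i in which(deg > 0)) {
      msk <- gr$mask[i, ]
      if (!any(msk)) next
      rows[[length(rows) + 1]] <- data.frame(
        degree = deg[i], pred = preds[[g]][i, msk], true = gr$targets[i, msk])
    }
  }
  if (length(rows) == 0)
    return(list(per_degree = data.frame(), avg_degree = numeric()))
  df <- do.call(rbind, rows)
  per_degree <- do.call(rbind, lapply(sort(unique(df$degree)), function(d) {
    sub <- df[df$degree == d, ]
    if (nrow(sub) < 2) return(NULL)
    m <- compute_metrics(sub$pred, sub$true, threshold = threshold)
    data.frame(degree = d, n = m$n_evaluated_positions, pcc = m$pcc,
               mcc = m$mcc, average_precision = m$average_precision,
               auc = m$auc, mean_abs_error = m$mean_abs_error)
  }))
  avg_degree <- unlist(lapply(deg_acc, colMeans), use.names = FALSE)
  list(per_degree = per_degree, avg_degree = avg_degree)
}
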