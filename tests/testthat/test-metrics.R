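test_that("perfect and inverted predictors hit the metric extremes", {
  true <- c(0, 0, 0, 1, 1, 0, 1, 0, 1, 1)
  m <- compute_metrics(true, true)
  expect_equal(m$pcc, 1)
  expect_equal(m$mcc, 1)
  expect_equal(m$average_precision, 1)
  expect_equal(m$auc, 1)
  expect_equal(m$mean_abs_error, 0)
  expect_equal(m$n_evaluated_positions, 10L)

  anti <- compute_metrics(1 - true, true)
  expect_equal(anti$pcc, -1)
  expect_equal(anti$auc, 0)
})

test_that("metrics match hand-computed confusion/rank statistics on 8 points", {
  pred <- c(0.9, 0.8, 0.3, 0.6, 0.2, 0.7, 0.1, 0.4)
  true <- c(1.0, 1.0, 0.0, 0.0, 0.0, 1.0, 0.0, 1.0)
  m <- compute_metrics(pred, true)
  ## confusion at 0.5: TP {0.9,0.8,0.7}, FN {0.4}, FP {0.6}, TN {0.3,0.2,0.1}
  expect_equal(m$mcc, (3 * 3 - 1 * 1) / sqrt(4 * 4 * 4 * 4))
  ## AUC: positives {0.9,0.8,0.7,0.4} vs negatives {0.6,0.3,0.2,0.1};
  ## 0.4 beats 3 of 4 negatives -> (4+4+4+3)/16
  expect_equal(m$auc, 15 / 16)
  ## AP by descending threshold: precisions at the 4 positives:
  ## 1/1, 2/2, 3/4 (0.6 intervenes), 4/6 (0.6,0.3... 0.4 is 6th? ordered:
  ## .9 .8 .7 .6 .4 -> positives at ranks 1,2,3,5
  expect_equal(m$average_precision,
               (1 / 1 + 2 / 2 + 3 / 3 + 4 / 5) / 4 * c(1, 1, 1, 1)[1] *
                 1)  # recall increments are 1/4 each
  expect_equal(m$pcc, stats::cor(pred, true))
  expect_equal(m$mean_abs_error, mean(abs(pred - true)))
})

test_that("metric implementations agree with brute-force oracles", {
  set.seed(42)
  for (rep in 1:5) {
    pred <- round(stats::runif(20), 3)
    true <- round(stats::runif(20))
    m <- compute_metrics(pred, true)
    lab <- as.integer(true >= 0.5)
    expect_equal(m$mcc, ref_mcc(pred >= 0.5, lab == 1))
    expect_equal(m$auc, ref_auc(pred, lab))
    expect_equal(m$average_precision, ref_ap(pred, lab))
  }
  ## ties in scores are handled like the threshold definition
  pred <- c(0.8, 0.8, 0.8, 0.2, 0.2)
  true <- c(1, 0, 1, 0, 1)
  m <- compute_metrics(pred, true)
  expect_equal(m$auc, ref_auc(pred, true))
  expect_equal(m$average_precision, ref_ap(pred, true))
})

test_that("single-class truth flags MCC/AUC/AP but keeps PCC and MAE", {
  pred <- c(0.1, 0.2, 0.3)
  true <- c(0, 0, 0.2)
  m <- compute_metrics(pred, true)
  expect_true(m$single_class)
  expect_true(is.na(m$auc))
  expect_false(is.na(m$mean_abs_error))
  expect_false(is.na(m$pcc))
})

test_that("mask filtering commutes with metric computation", {
  set.seed(8)
  pred <- stats::runif(50)
  true <- round(stats::runif(50))
  mask <- stats::runif(50) > 0.4
  m1 <- compute_metrics(pred, true, mask)
  m2 <- compute_metrics(pred[mask], true[mask])
  expect_equal(m1[names(m1) != "n_evaluated_positions"],
               m2[names(m2) != "n_evaluated_positions"])
})

test_that("error stratification by true level uses exact 0/1 bins", {
  pred <- c(0.3, 0.2, 0.9, 0.55, 0.8)
  true <- c(0.0, 0.0, 1.0, 0.52, 0.95)
  tb <- error_by_true_level(pred, true)
  expect_equal(tb$mean_abs_error[tb$bin == "0"], 0.25)
  expect_equal(tb$mean_abs_error[tb$bin == "1"], 0.1)
  expect_equal(tb$mean_abs_error[tb$bin == "(0.5,0.6]"], 0.03)
  expect_equal(tb$mean_abs_error[tb$bin == "(0.9,1.0]"], 0.15)
  expect_equal(sum(tb$n), 5L)

  ## perfect predictions -> all bin means zero
  tb0 <- error_by_true_level(true, true)
  expect_true(all(tb0$mean_abs_error == 0))

  dist <- true_level_distribution(c(0, 0, 0, 1, 0.5))
  expect_equal(dist$fraction[dist$bin == "0"], 0.6)
  expect_equal(dist$fraction[dist$bin == "1"], 0.2)
  expect_equal(sum(dist$fraction), 1)
})

test_that("naive predictors copy or average neighbours by contact weight", {
  ## 4-node toy graph with known edge counts and targets
  n <- 4; L <- 10
  targets <- matrix(NA_real_, n, L)
  mask <- matrix(FALSE, n, L)
  targets[2, 1:4] <- c(1, 0, 1, 1); mask[2, 1:4] <- TRUE
  targets[3, c(1, 2, 5)] <- c(0, 1, 1); mask[3, c(1, 2, 5)] <- TRUE
  targets[4, 2] <- 1; mask[4, 2] <- TRUE
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4))
  ## edge features: 2 members + occurrence + distance; aggregated counts are
  ## the rowSums of the member columns: 3, 1, 5, 1
  ef <- cbind(c(2, 1, 4, 1), c(1, 0, 1, 0), c(2, 1, 2, 1), c(100, 200, 300, 150))
  g <- structure(list(node_features = matrix(0, n, 2), edges = edges,
                      edge_features = ef, targets = targets, mask = mask),
                 class = "promoter_graph")
  v1 <- naive_predictor(g, 1)
  ## node 1's neighbours: 2 (count 3), 3 (count 1), 4 (count 1) -> copy node 2
  expect_equal(v1$pred[1, 1:4], targets[2, 1:4])
  expect_false(any(v1$mask[1, 5:10]))
  v2 <- naive_predictor(g, 2)
  ## position 1: nodes 2 (w 3) and 3 (w 1) have values 1, 0 -> 0.75
  expect_equal(v2$pred[1, 1], 0.75)
  ## position 2: values 0 (w3), 1 (w1), 1 (w1) -> 2/5
  expect_equal(v2$pred[1, 2], 2 / 5)
  ## position 5: only node 3 covers it
  expect_equal(v2$pred[1, 5], 1)

  ## equal-count neighbours with levels 0 and 1 average to 0.5
  gg <- g
  gg$edge_features[1, 1:2] <- c(1, 0)  # counts now 1 and 1 for node 1's nbrs
  gg$targets[2, 1] <- 1; gg$targets[3, 1] <- 0
  v2b <- naive_predictor(gg, 2)
  expect_equal(v2b$pred[1, 1], 0.5)

  ## isolated node gets no prediction; single-neighbour node copies it
  g2 <- structure(list(node_features = matrix(0, 3, 2),
                       edges = rbind(c(1, 2)),
                       edge_features = matrix(c(1, 0, 1, 50), 1, 4),
                       targets = targets[1:3, ], mask = mask[1:3, ]),
                  class = "promoter_graph")
  v1b <- naive_predictor(g2, 1)
  v2c <- naive_predictor(g2, 2)
  expect_equal(v1b$pred[1, ], v2c$pred[1, ])
  expect_false(any(v1b$mask[3, ]))
})

test_that("degree-stratified metrics equal recomputation on degree subsets", {
  bm_graphs <- get_fixture_graphs()
  fx <- get_fixture()
  cfg <- model_config(n_blocks = 2, n_heads = 1, d = 4, node_in_dim = 64,
                      edge_in_dim = 23, seed = 2)
  par <- init_model_params(cfg)
  graphs <- lapply(bm_graphs, `[[`, 1)
  preds <- lapply(graphs, function(g) predict_graph(par, g, cfg))
  da <- degree_analysis(graphs, preds)
  expect_true(nrow(da$per_degree) >= 1)
  ## recompute one degree value directly
  d0 <- da$per_degree$degree[1]
  pv <- c(); tv <- c()
  for (k in seq_along(graphs)) {
    deg <- graph_degrees(graphs[[k]])
    for (i in which(deg == d0)) {
      msk <- graphs[[k]]$mask[i, ]
      pv <- c(pv, preds[[k]][i, msk])
      tv <- c(tv, graphs[[k]]$targets[i, msk])
    }
  }
  m <- compute_metrics(pv, tv)
  expect_equal(da$per_degree$pcc[1], m$pcc)
  expect_equal(da$per_degree$auc[1], m$auc)
  ## star-graph center degree sanity
  star <- structure(list(node_features = matrix(0, 5, 2),
                         edges = cbind(1L, 2:5),
                         edge_features = matrix(1, 4, 4),
                         targets = matrix(0.5, 5, 3),
                         mask = matrix(TRUE, 5, 3)),
                    class = "promoter_graph")
  expect_equal(graph_degrees(star), c(4L, 1L, 1L, 1L, 1L))
})
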