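## small deterministic graphs for model tests
make_toy_graph <- function(n = 4, edges = rbind(c(1, 2), c(2, 3), c(1, 3)),
                           node_dim = 3, edge_dim = 4, seed = 11,
                           out_dim = 6) {
  set.seed(seed)
  n_cpg <- out_dim %/% 2
  targets <- matrix(NA_real_, n, out_dim)
  mask <- matrix(FALSE, n, out_dim)
  for (i in seq_len(n)) {
    sel <- sample(out_dim, n_cpg)
    mask[i, sel] <- TRUE
    targets[i, sel] <- round(stats::runif(n_cpg))
  }
  structure(list(
    cell_id = "toy", chrom = "chrT",
    node_features = matrix(stats::runif(n * node_dim), n, node_dim),
    edges = matrix(as.integer(edges), ncol = 2),
    edge_features = matrix(stats::rpois(nrow(edges) * edge_dim, 2),
                           nrow(edges), edge_dim),
    targets = targets, mask = mask,
    regions = NULL), class = "promoter_graph")
}

toy_config <- function(graph, ...) {
  args <- list(...)
  defaults <- list(n_blocks = 2, n_heads = 1, d = 2,
                   node_in_dim = ncol(graph$node_features),
                   edge_in_dim = ncol(graph$edge_features),
                   out_dim = ncol(graph$targets), seed = 7)
  do.call(model_config, utils::modifyList(defaults, args))
}

test_that("attention is a proper distribution with trivial cases exact", {
  g <- make_toy_graph()
  cfg <- toy_config(g, n_blocks = 3, n_heads = 2)
  par <- init_model_params(cfg)
  for (b in 1:3) for (h in 1:2) {
    a <- attention_coefficients(par, g, cfg, block = b, head = h)
    expect_true(all(a$alpha > 0))
    sums <- tapply(a$alpha, a$i, sum)
    expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-6)
  }
  ## node 3 has a single neighbourhood entry from nodes 2 and 1; node 4 is
  ## isolated. A path graph gives a one-neighbour node:
  g2 <- make_toy_graph(n = 3, edges = rbind(c(1, 2), c(2, 3)))
  cfg2 <- toy_config(g2)
  a2 <- attention_coefficients(init_model_params(cfg2), g2, cfg2)
  expect_equal(a2$alpha[a2$i == 1], 1)  # node 1's only neighbour is node 2
  expect_equal(a2$alpha[a2$i == 3], 1)
})

test_that("two neighbours with identical keys and edges split attention equally", {
  ## star: node 1 connected to 2 and 3; make nodes 2,3 and both edges identical
  g <- make_toy_graph(n = 3, edges = rbind(c(1, 2), c(1, 3)))
  g$node_features[3, ] <- g$node_features[2, ]
  g$edge_features[2, ] <- g$edge_features[1, ]
  cfg <- toy_config(g)
  a <- attention_coefficients(init_model_params(cfg), g, cfg)
  expect_equal(a$alpha[a$i == 1], c(0.5, 0.5))
})

test_that("forward pass matches the independent scalar implementation", {
  for (H in 1:2) {
    g <- make_toy_graph(seed = 20 + H)
    cfg <- toy_config(g, n_blocks = 3, n_heads = H, d = 2)
    ## fixed small-integer-scale weights
    par <- init_model_params(cfg, seed = 100 + H)
    impl <- predict_graph(par, g, cfg)
    ref <- ref_forward(par, g, cfg)
    expect_equal(impl, ref$pred, tolerance = 1e-6)
    ## attention coefficients agree too
    a <- attention_coefficients(par, g, cfg, block = 2, head = H)
    expect_equal(a$alpha, ref$alphas[[2]][[H]], tolerance = 1e-6)
  }
})

test_that("deterministic, sigmoid-bounded, and equivariant to node relabeling", {
  g <- make_toy_graph()
  cfg <- toy_config(g)
  par <- init_model_params(cfg)
  p1 <- predict_graph(par, g, cfg)
  expect_identical(p1, predict_graph(par, g, cfg))
  expect_true(all(p1 > 0 & p1 < 1))

  ## permute node labels: relabel i -> perm[i]
  perm <- c(3L, 1L, 4L, 2L)
  g2 <- g
  g2$node_features[perm, ] <- g$node_features
  g2$targets[perm, ] <- g$targets
  g2$mask[perm, ] <- g$mask
  e2 <- cbind(perm[g$edges[, 1]], perm[g$edges[, 2]])
  flip <- e2[, 1] > e2[, 2]
  e2[flip, ] <- e2[flip, 2:1]
  ord <- order(e2[, 1], e2[, 2])
  g2$edges <- e2[ord, , drop = FALSE]
  g2$edge_features <- g$edge_features[ord, , drop = FALSE]
  p2 <- predict_graph(par, g2, cfg)
  expect_equal(p2[perm, ], p1, tolerance = 1e-5)
})

test_that("isolated nodes still receive predictions via the bias path", {
  g <- make_toy_graph(n = 4, edges = rbind(c(1, 2)))
  cfg <- toy_config(g)
  par <- init_model_params(cfg)
  p <- predict_graph(par, g, cfg)
  expect_true(all(is.finite(p[3, ])))
  ## isolated nodes share the zero-aggregation path, so rows 3 and 4 agree
  expect_equal(p[3, ], p[4, ])
})

test_that("H=1 final-block head average equals the single head aggregation", {
  ## one block, one head: output is sigmoid(W_out agg + b) with agg the plain
  ## alpha-weighted sum (no LayerNorm/ReLU in the final block)
  g <- make_toy_graph(n = 2, edges = rbind(c(1, 2)))
  cfg <- toy_config(g, n_blocks = 1, n_heads = 1, d = 2)
  par <- init_model_params(cfg)
  hp <- par$blocks[[1]]$heads[[1]]
  ef <- cfg$edge_transform(g$edge_features[1, ])
  eh <- as.numeric(hp$W_e %*% ef + hp$b_e)
  v2 <- as.numeric(hp$W_v %*% g$node_features[2, ] + hp$b_v)
  agg1 <- v2 + eh  # alpha = 1 for a single neighbour
  expected <- 1 / (1 + exp(-(as.numeric(par$W_out %*% agg1 + par$b_out))))
  p <- predict_graph(par, g, cfg)
  expect_equal(p[1, ], expected, tolerance = 1e-8)
})

test_that("masked loss follows its definition", {
  pred <- matrix(c(0.5, 0.2), 1, 2)
  targ <- matrix(c(1.0, 0.9), 1, 2)
  mask <- matrix(c(TRUE, FALSE), 1, 2)
  expect_equal(masked_loss(pred, targ, mask), 0.25)
  expect_equal(masked_loss(targ, targ, mask), 0)
  ## 3-position hand computation
  p3 <- matrix(c(0.1, 0.6, 0.9), 1, 3)
  t3 <- matrix(c(0.0, 1.0, 1.0), 1, 3)
  m3 <- matrix(TRUE, 1, 3)
  expect_equal(masked_loss(p3, t3, m3), (0.01 + 0.16 + 0.01) / 3)
  expect_error(masked_loss(p3, t3, matrix(FALSE, 1, 3)), "empty mask")
})

test_that("tape gradients match central finite differences", {
  g <- make_toy_graph()
  cfg <- toy_config(g, n_blocks = 2, n_heads = 2, d = 2)
  par <- init_model_params(cfg)
  inputs <- hicmeth:::graph_inputs(g, cfg)
  tg <- inputs$targets; tg[!inputs$mask] <- 0

  loss_at <- function(par) {
    fw <- hicmeth:::forward_tape(par, inputs, cfg)
    hicmeth:::ad_value(hicmeth:::ad_masked_mse(fw$pred, tg, inputs$mask))
  }
  fw <- hicmeth:::forward_tape(par, inputs, cfg)
  l <- hicmeth:::ad_masked_mse(fw$pred, tg, inputs$mask)
  grads_by_id <- hicmeth:::ad_backward(fw$tape, l)
  flat <- hicmeth:::flatten_params(par)
  grads <- lapply(fw$param_ids, function(id) grads_by_id[[id]])

  eps <- 1e-6
  set.seed(99)
  for (nm in c("b1.h1.W_q", "b1.h2.W_e", "b1.ln_node_gamma", "b1.ln_edge_beta",
               "b2.h1.W_v", "b2.h1.b_k", "W_out", "b_out")) {
    x <- flat[[nm]]
    idx <- sample(length(x), min(3, length(x)))
    for (ii in idx) {
      pp <- hicmeth:::unflatten_params(flat, par)
      fplus <- flat; fplus[[nm]][ii] <- fplus[[nm]][ii] + eps
      fminus <- flat; fminus[[nm]][ii] <- fminus[[nm]][ii] - eps
      num <- (loss_at(hicmeth:::unflatten_params(fplus, par)) -
              loss_at(hicmeth:::unflatten_params(fminus, par))) / (2 * eps)
      expect_equal(grads[[nm]][ii], num, tolerance = 1e-4)
    }
  }
})

test_that("all-zero parameters give 0.5 predictions", {
  g <- make_toy_graph()
  cfg <- toy_config(g)
  par <- init_model_params(cfg)
  flat <- hicmeth:::flatten_params(par)
  for (nm in names(flat)) flat[[nm]] <- flat[[nm]] * 0
  par0 <- hicmeth:::unflatten_params(flat, par)
  ## zero weights and biases: final node state is zero, sigmoid(0) = 0.5
  expect_equal(unname(predict_graph(par0, g, cfg)),
               matrix(0.5, 4, ncol(g$targets)))
})

test_that("training reduces loss on a single graph and is seed-reproducible", {
  g <- make_toy_graph(n = 4, node_dim = 4, edge_dim = 4, seed = 31,
                      out_dim = 8)
  cfg <- toy_config(g, n_blocks = 2, d = 4, learning_rate = 5e-3,
                    max_epochs = 50, patience = 50)
  fit <- train_model(list(g), list(g), cfg)
  expect_lt(utils::tail(fit$history$train_loss, 1),
            fit$history$train_loss[1])
  fit2 <- train_model(list(g), list(g), cfg)
  expect_identical(fit$best_val_loss, fit2$best_val_loss)
  expect_identical(fit$params, fit2$params)
})
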