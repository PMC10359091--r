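## Edge-aware graph transformer.
##
## Per block o and head h, with node states p and edge states e:
##   q_i = W_q p_i + b_q,  k_j = W_k p_j + b_k,  v_j = W_v p_j + b_v,
##   e_hij = W_e e_ij + b_e,
##   alpha_hij = exp(q_i'(k_j + e_hij)/sqrt(d)) / sum_{u in N(i)} exp(...),
##   phat_i = ||_h sum_{j in N(i)} alpha_hij (v_hj + e_hij),
##   p_i <- ReLU(LayerNorm(phat_i)),
##   ehat_ij = ||_h (alpha_hij, e_ij),  e_ij <- ReLU(LayerNorm(ehat_ij)).
## In the final block the head concatenation is replaced by the head average
## and no LayerNorm/ReLU is applied. A sigmoid-activated affine head maps the
## final node state to 1000 per-base methylation levels.

#' Model configuration for the graph transformer
#'
#' Defaults follow the selected architecture: 5 blocks, 1 attention head,
#' hidden size 64 per head, 23 raw edge features, 1000 outputs per node.
#'
#' @param n_blocks number of transformer blocks.
#' @param n_heads attention heads per block.
#' @param d hidden size of each head.
#' @param node_in_dim input node-feature dimension (set from data when NULL).
#' @param edge_in_dim raw edge-feature dimension (k + 3; 23 for k = 20).
#' @param out_dim outputs per node (the 1000-bp target window).
#' @param learning_rate Adam step size.
#' @param max_epochs,patience training length and early-stopping patience.
#' @param edge_mode "carry" feeds each block the previous block's updated edge
#'   states (default); "raw" re-projects the original 23-value features in
#'   every block.
#' @param edge_transform function applied to raw edge features before the
#'   first block; defaults to `log1p` so contact counts and bp distances share
#'   a numeric scale.
#' @param seed RNG seed for parameter initialization and epoch shuffling.
#' @return a `model_config` list.
#' @export
model_config <- function(n_blocks = 5, n_heads = 1, d = 64,
                         node_in_dim = NULL, edge_in_dim = 23,
                         out_dim = 1000, learning_rate = 1e-3,
                         max_epochs = 100, patience = 10,
                         edge_mode = c("carry", "raw"),
                         edge_transform = log1p, seed = 1) {
  stopifnot(n_blocks >= 1, n_heads >= 1, d >= 1)
  structure(list(n_blocks = n_blocks, n_heads = n_heads, d = d,
                 node_in_dim = node_in_dim, edge_in_dim = edge_in_dim,
                 out_dim = out_dim, learning_rate = learning_rate,
                 max_epochs = max_epochs, patience = patience,
                 edge_mode = match.arg(edge_mode),
                 edge_transform = edge_transform, seed = seed),
            class = "model_config")
}

## per-block input dimensions implied by the architecture
block_dims <- function(config) {
  H <- config$n_heads; d <- config$d
  node_in <- config$node_in_dim
  edge_in <- config$edge_in_dim
  dims <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    dims[[b]] <- list(node_in = node_in, edge_in = edge_in)
    node_in <- if (b == config$n_blocks) d else H * d
    edge_in <- if (config$edge_mode == "carry") H * (1L + edge_in)
               else config$edge_in_dim
  }
  dims
}

#' Initialize graph-transformer parameters
#'
#' @param config a [model_config()] with `node_in_dim` set.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return a `model_params` list of per-block weight matrices plus the output
#'   head.
#' @export
init_model_params <- function(config, seed = config$seed) {
  stopifnot(!is.null(config$node_in_dim))
  set.seed(seed)
  H <- config$n_heads; d <- config$d
  dims <- block_dims(config)
  mat <- function(q, p) matrix(stats::rnorm(q * p, sd = sqrt(1 / p)), q, p)
  blocks <- lapply(seq_len(config$n_blocks), function(b) {
    nd <- dims[[b]]$node_in; ed <- dims[[b]]$edge_in
    heads <- lapply(seq_len(H), function(h)
      list(W_q = mat(d, nd), b_q = numeric(d),
           W_k = mat(d, nd), b_k = numeric(d),
           W_v = mat(d, nd), b_v = numeric(d),
           W_e = mat(d, ed), b_e = numeric(d)))
    is_final <- b == config$n_blocks
    out <- list(heads = heads)
    if (!is_final) {
      out$ln_node_gamma <- rep(1, H * d)
      out$ln_node_beta <- numeric(H * d)
      out$ln_edge_gamma <- rep(1, H * (1L + ed))
      out$ln_edge_beta <- numeric(H * (1L + ed))
    }
    out
  })
  structure(list(blocks = blocks,
                 W_out = mat(config$out_dim, d),
                 b_out = numeric(config$out_dim),
                 config_dims = dims),
            class = "model_params")
}

## flatten params to a named list of numeric arrays (for the optimizer)
flatten_params <- function(params) {
  out <- list()
  for (b in seq_along(params$blocks)) {
    blk <- params$blocks[[b]]
    for (h in seq_along(blk$heads))
      for (nm in names(blk$heads[[h]]))
        out[[sprintf("b%d.h%d.%s", b, h, nm)]] <- blk$heads[[h]][[nm]]
    for (nm in grep("^ln_", names(blk), value = TRUE))
      out[[sprintf("b%d.%s", b, nm)]] <- blk[[nm]]
  }
  out$W_out <- params$W_out
  out$b_out <- params$b_out
  out
}

unflatten_params <- function(flat, template) {
  for (b in seq_along(template$blocks)) {
    blk <- template$blocks[[b]]
    for (h in seq_along(blk$heads))
      for (nm in names(blk$heads[[h]]))
        template$blocks[[b]]$heads[[h]][[nm]] <-
          flat[[sprintf("b%d.h%d.%s", b, h, nm)]]
    for (nm in grep("^ln_", names(blk), value = TRUE))
      template$blocks[[b]][[nm]] <- flat[[sprintf("b%d.%s", b, nm)]]
  }
  template$W_out <- flat$W_out
  template$b_out <- flat$b_out
  template
}

## precompute the static tensors of a graph for the forward pass
graph_inputs <- function(graph, config) {
  m <- nrow(graph$edges)
  if (m > 0) {
    src <- c(graph$edges[, 1], graph$edges[, 2])
    dst <- c(graph$edges[, 2], graph$edges[, 1])
    ef <- config$edge_transform(graph$edge_features)
    ef <- rbind(ef, ef)  # identical features in both directions
  } else {
    src <- integer(); dst <- integer()
    ef <- matrix(0, 0, config$edge_in_dim)
  }
  list(X = graph$node_features, src = src, dst = dst, E = ef,
       n = nrow(graph$node_features),
       targets = graph$targets, mask = graph$mask)
}

## Forward pass on a tape. Returns list(pred, alphas, tape, param_ids).
forward_tape <- function(params, inputs, config) {
  tape <- ad_tape()
  H <- config$n_heads
  d <- config$d
  n <- inputs$n
  param_ids <- list()
  getp <- function(name, val) {
    nd <- ad_input(tape, val)
    param_ids[[name]] <<- nd$id
    nd
  }
  X <- ad_input(tape, inputs$X)
  E <- ad_input(tape, inputs$E)
  has_edges <- length(inputs$src) > 0
  alphas <- list()
  for (b in seq_along(params$blocks)) {
    blk <- params$blocks[[b]]
    is_final <- b == length(params$blocks)
    aggs <- vector("list", H)
    alpha_h <- vector("list", H)
    for (h in seq_len(H)) {
      hp <- blk$heads[[h]]
      pn <- function(nm) sprintf("b%d.h%d.%s", b, h, nm)
      Q <- ad_linear(X, getp(pn("W_q"), hp$W_q), getp(pn("b_q"), hp$b_q))
      K <- ad_linear(X, getp(pn("W_k"), hp$W_k), getp(pn("b_k"), hp$b_k))
      V <- ad_linear(X, getp(pn("W_v"), hp$W_v), getp(pn("b_v"), hp$b_v))
      if (has_edges) {
        Eh <- ad_linear(E, getp(pn("W_e"), hp$W_e), getp(pn("b_e"), hp$b_e))
        qi <- ad_gather_rows(Q, inputs$dst)
        kj <- ad_gather_rows(K, inputs$src)
        ke <- ad_add(kj, Eh)
        score <- ad_scale(ad_dotrows(qi, ke), 1 / sqrt(d))
        alpha <- ad_segment_softmax(score, inputs$dst)
        vj <- ad_gather_rows(V, inputs$src)
        msg <- ad_rowscale(ad_add(vj, Eh), alpha)
        aggs[[h]] <- ad_scatter_add(msg, inputs$dst, n)
        alpha_h[[h]] <- alpha
      } else {
        ## isolated nodes: zero aggregation
        getp(pn("W_e"), hp$W_e); getp(pn("b_e"), hp$b_e)
        aggs[[h]] <- ad_scale(V, 0)
        alpha_h[[h]] <- NULL
      }
    }
    alphas[[b]] <- alpha_h
    if (is_final) {
      X <- Reduce(ad_add, aggs)
      if (H > 1) X <- ad_scale(X, 1 / H)
    } else {
      cat_nodes <- if (H > 1) ad_cbind(aggs) else aggs[[1]]
      X <- ad_relu(ad_layernorm(cat_nodes,
                                getp(sprintf("b%d.ln_node_gamma", b),
                                     blk$ln_node_gamma),
                                getp(sprintf("b%d.ln_node_beta", b),
                                     blk$ln_node_beta)))
      if (config$edge_mode == "carry" && has_edges) {
        parts <- unlist(lapply(seq_len(H), function(h)
          list(alpha_h[[h]], E)), recursive = FALSE)
        cat_edges <- ad_cbind(parts)
        E <- ad_relu(ad_layernorm(cat_edges,
                                  getp(sprintf("b%d.ln_edge_gamma", b),
                                       blk$ln_edge_gamma),
                                  getp(sprintf("b%d.ln_edge_beta", b),
                                       blk$ln_edge_beta)))
      } else if (!has_edges) {
        getp(sprintf("b%d.ln_edge_gamma", b), blk$ln_edge_gamma)
        getp(sprintf("b%d.ln_edge_beta", b), blk$ln_edge_beta)
      }
    }
  }
  pred <- ad_sigmoid(ad_linear(X, getp("W_out", params$W_out),
                               getp("b_out", params$b_out)))
  if (any(!is.finite(ad_value(pred))))
    stop("non-finite values in forward pass")
  list(pred = pred, alphas = alphas, tape = tape, param_ids = param_ids)
}

#' Attention coefficients of one block/head for inspection
#'
#' Runs the forward pass and extracts the softmax-normalized attention
#' coefficients, as a data.frame over directed edges (message j -> i).
#'
#' @param params `model_params`.
#' @param graph a `promoter_graph`.
#' @param config the `model_config` used with `params`.
#' @param block,head indices.
#' @return data.frame with columns `i` (receiver), `j` (sender), `alpha`.
#' @export
attention_coefficients <- function(params, graph, config, block = 1, head = 1) {
  inputs <- graph_inputs(graph, config)
  fw <- forward_tape(params, inputs, config)
  a <- fw$alphas[[block]][[head]]
  if (is.null(a)) return(data.frame(i = integer(), j = integer(),
                                    alpha = numeric()))
  data.frame(i = inputs$dst, j = inputs$src, alpha = as.numeric(ad_value(a)))
}

#' Forward pass: per-node 1000-bp methylation predictions
#'
#' @param params `model_params`.
#' @param graph a `promoter_graph`.
#' @param config the matching `model_config`.
#' @return numeric matrix (nodes x 1000) of predictions in (0, 1).
#' @export
predict_graph <- function(params, graph, config) {
  inputs <- graph_inputs(graph, config)
  fw <- forward_tape(params, inputs, config)
  ad_value(fw$pred)
}

#' Masked mean-squared-error loss
#'
#' @param pred,targets numeric matrices of equal shape.
#' @param mask logical matrix; loss is averaged over mask-true positions.
#' @return non-negative scalar.
#' @export
masked_loss <- function(pred, targets, mask) {
  stopifnot(all(dim(pred) == dim(targets)), all(dim(pred) == dim(mask)))
  if (sum(mask) == 0) stop("masked loss undefined: empty mask")
  d <- (pred - targets)[mask]
  mean(d^2)
}

## one Adam step on flattened params
adam_step <- function(flat, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(flat)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

#' Train the graph transformer with early stopping
#'
#' Each graph is one training example; optimization is Adam on the masked MSE,
#' one gradient step per graph, and the returned parameters are those with the
#' best validation loss. Fully reproducible given `config$seed`.
#'
#' @param train_graphs,val_graphs lists of `promoter_graph`s; graphs with an
#'   empty target mask are skipped with a warning.
#' @param config a [model_config()]; `node_in_dim`/`edge_in_dim` are filled
#'   from the data when NULL.
#' @param verbose print per-epoch losses.
#' @return list with `params`, `config` and `history` (data.frame epoch,
#'   train_loss, val_loss).
#' @export
train_model <- function(train_graphs, val_graphs, config, verbose = FALSE) {
  stopifnot(length(train_graphs) >= 1, length(val_graphs) >= 1)
  if (is.null(config$node_in_dim))
    config$node_in_dim <- ncol(train_graphs[[1]]$node_features)
  config$edge_in_dim <- ncol(train_graphs[[1]]$edge_features)
  keep <- vapply(train_graphs, function(g) sum(g$mask) > 0, TRUE)
  if (!all(keep)) {
    warning(sum(!keep), " training graph(s) without masked targets skipped")
    train_graphs <- train_graphs[keep]
  }
  train_in <- lapply(train_graphs, graph_inputs, config = config)
  val_in <- lapply(val_graphs, graph_inputs, config = config)
  val_in <- val_in[vapply(val_in, function(x) sum(x$mask) > 0, TRUE)]
  stopifnot(length(train_in) >= 1, length(val_in) >= 1)

  params <- init_model_params(config)
  flat <- flatten_params(params)
  state <- new.env(parent = emptyenv())
  state$t <- 0; state$m <- list(); state$v <- list()

  val_loss <- function(flat) {
    p <- unflatten_params(flat, params)
    mean(vapply(val_in, function(inp) {
      fw <- forward_tape(p, inp, config)
      tg <- inp$targets; tg[!inp$mask] <- 0
      masked_loss(ad_value(fw$pred), tg, inp$mask)
    }, 0))
  }

  set.seed(config$seed + 1L)
  best <- list(flat = flat, val = val_loss(flat), epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  wait <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(train_in))
    tl <- 0
    for (gi in ord) {
      inp <- train_in[[gi]]
      p <- unflatten_params(flat, params)
      fw <- forward_tape(p, inp, config)
      tg <- inp$targets; tg[!inp$mask] <- 0
      loss_nd <- ad_masked_mse(fw$pred, tg, inp$mask)
      lv <- ad_value(loss_nd)
      if (!is.finite(lv)) stop("training diverged: non-finite loss at epoch ",
                               epoch, "; last good checkpoint is from epoch ",
                               best$epoch)
      tl <- tl + lv
      grads_by_id <- ad_backward(fw$tape, loss_nd)
      grads <- lapply(fw$param_ids, function(id) grads_by_id[[id]])
      upd <- adam_step(flat, grads, state, config$learning_rate)
      flat <- upd$flat
    }
    vl <- val_loss(flat)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tl / length(train_in),
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                      tl / length(train_in), vl))
    if (vl < best$val - 1e-7) {
      best <- list(flat = flat, val = vl, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(params = unflatten_params(best$flat, params), config = config,
       history = history, best_epoch = best$epoch,
       best_val_loss = best$val)
}
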