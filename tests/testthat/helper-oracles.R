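## Independent brute-force oracles. These deliberately share no code with the
## package: straight-line loops and textbook formulas only.

## --- graph transformer reference: scalar implementation of the equations ---

ref_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- mean(x)
  va <- mean((x - mu)^2)
  gamma * (x - mu) / sqrt(va + eps) + beta
}

## params/config as produced by the package; graph: promoter_graph.
## Returns list(pred, alphas[[block]][[head]] = matrix over directed edges).
ref_forward <- function(params, graph, config) {
  n <- nrow(graph$node_features)
  m <- nrow(graph$edges)
  H <- config$n_heads
  d <- config$d
  B <- config$n_blocks
  ## directed edges in the same order as the implementation:
  ## rows 1..m are src=i, dst=j; rows m+1..2m are src=j, dst=i
  src <- c(graph$edges[, 1], graph$edges[, 2])
  dst <- c(graph$edges[, 2], graph$edges[, 1])
  e_state <- lapply(seq_len(2 * m), function(r)
    as.numeric(config$edge_transform(graph$edge_features[(r - 1) %% m + 1, ])))
  p_state <- lapply(seq_len(n), function(i) as.numeric(graph$node_features[i, ]))
  alphas <- vector("list", B)
  for (b in seq_len(B)) {
    blk <- params$blocks[[b]]
    is_final <- b == B
    agg <- matrix(0, n, 0)
    alpha_blk <- vector("list", H)
    head_aggs <- vector("list", H)
    for (h in seq_len(H)) {
      hp <- blk$heads[[h]]
      q <- lapply(p_state, function(p) as.numeric(hp$W_q %*% p + hp$b_q))
      k <- lapply(p_state, function(p) as.numeric(hp$W_k %*% p + hp$b_k))
      v <- lapply(p_state, function(p) as.numeric(hp$W_v %*% p + hp$b_v))
      eh <- lapply(e_state, function(e) as.numeric(hp$W_e %*% e + hp$b_e))
      ## attention over incoming directed edges per receiver
      expterm <- numeric(2 * m)
      for (r in seq_len(2 * m))
        expterm[r] <- exp(sum(q[[dst[r]]] * (k[[src[r]]] + eh[[r]])) / sqrt(d))
      alpha <- numeric(2 * m)
      for (i in seq_len(n)) {
        inc <- which(dst == i)
        if (length(inc)) alpha[inc] <- expterm[inc] / sum(expterm[inc])
      }
      alpha_blk[[h]] <- alpha
      agg_h <- vector("list", n)
      for (i in seq_len(n)) {
        acc <- numeric(d)
        for (r in which(dst == i))
          acc <- acc + alpha[r] * (v[[src[r]]] + eh[[r]])
        agg_h[[i]] <- acc
      }
      head_aggs[[h]] <- agg_h
    }
    alphas[[b]] <- alpha_blk
    if (is_final) {
      p_state <- lapply(seq_len(n), function(i) {
        acc <- numeric(d)
        for (h in seq_len(H)) acc <- acc + head_aggs[[h]][[i]]
        acc / H
      })
    } else {
      p_state <- lapply(seq_len(n), function(i) {
        cat_ <- unlist(lapply(seq_len(H), function(h) head_aggs[[h]][[i]]))
        pmax(ref_layernorm(cat_, blk$ln_node_gamma, blk$ln_node_beta), 0)
      })
      e_state <- lapply(seq_len(2 * m), function(r) {
        cat_ <- unlist(lapply(seq_len(H), function(h)
          c(alpha_blk[[h]][r], e_state[[r]])))
        pmax(ref_layernorm(cat_, blk$ln_edge_gamma, blk$ln_edge_beta), 0)
      })
    }
  }
  pred <- t(vapply(p_state, function(p)
    1 / (1 + exp(-(as.numeric(params$W_out %*% p + params$b_out)))),
    numeric(length(params$b_out))))
  list(pred = pred, alphas = alphas)
}

## --- metric oracles ---

ref_mcc <- function(pred_bin, lab_bin) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_along(pred_bin)) {
    if (pred_bin[i] && lab_bin[i]) tp <- tp + 1
    if (!pred_bin[i] && !lab_bin[i]) tn <- tn + 1
    if (pred_bin[i] && !lab_bin[i]) fp <- fp + 1
    if (!pred_bin[i] && lab_bin[i]) fn <- fn + 1
  }
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

## AUC as the Mann-Whitney U statistic (pairwise comparisons, ties = 1/2)
ref_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

## AP as the recall-increment sum over descending-score thresholds
ref_ap <- function(scores, labels) {
  npos <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_rec <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

## ARI from the pair-counting contingency table
ref_ari <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

## brute-force promoter-pair contact counting from the defining formula
ref_contact_matrix <- function(contacts, regions) {
  n <- nrow(regions)
  counts <- matrix(0L, n, n)
  inside <- function(pos, r)
    pos >= regions$contact_start[r] && pos < regions$contact_end[r]
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (c in seq_len(nrow(contacts))) {
      if (contacts$chrom1[c] != regions$chrom[1] ||
          contacts$chrom2[c] != regions$chrom[1]) next
      a <- contacts$pos1[c]; b <- contacts$pos2[c]
      if ((inside(a, i) && inside(b, j)) || (inside(a, j) && inside(b, i)))
        counts[i, j] <- counts[i, j] + 1L
    }
  }
  counts
}
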