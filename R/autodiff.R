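## Minimal reverse-mode automatic differentiation on a tape of matrix ops.
## Only the operations the graph transformer needs are provided; gradients
## are checked against finite differences in the test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$parents <- list()
  tp$vjps <- list()
  tp$n <- 0L
  tp
}

ad_push <- function(tape, val, parents = integer(), vjp = NULL) {
  tape$n <- tape$n + 1L
  tape$vals[[tape$n]] <- val
  tape$parents[[tape$n]] <- parents
  tape$vjps[[tape$n]] <- vjp
  list(id = tape$n, tape = tape)
}

ad_value <- function(x) x$tape$vals[[x$id]]

ad_input <- function(tape, val) ad_push(tape, val)

## y = X %*% t(W) + rep(b) ; X: n x p, W: q x p, b: length q
ad_linear <- function(X, W, b) {
  tp <- X$tape
  Xv <- ad_value(X); Wv <- ad_value(W); bv <- ad_value(b)
  val <- Xv %*% t(Wv)
  val <- sweep(val, 2, bv, `+`)
  ad_push(tp, val, c(X$id, W$id, b$id), function(g)
    list(g %*% Wv, crossprod(g, Xv), colSums(g)))
}

ad_add <- function(A, B) {
  tp <- A$tape
  ad_push(tp, ad_value(A) + ad_value(B), c(A$id, B$id),
          function(g) list(g, g))
}

ad_scale <- function(A, s) {  # s: plain numeric scalar
  ad_push(A$tape, ad_value(A) * s, A$id, function(g) list(g * s))
}

ad_relu <- function(A) {
  v <- ad_value(A)
  out <- pmax(v, 0)
  ad_push(A$tape, out, A$id, function(g) list(g * (v > 0)))
}

ad_sigmoid <- function(A) {
  s <- 1 / (1 + exp(-ad_value(A)))
  ad_push(A$tape, s, A$id, function(g) list(g * s * (1 - s)))
}

ad_gather_rows <- function(A, idx) {
  v <- ad_value(A)
  nr <- nrow(v)
  ad_push(A$tape, v[idx, , drop = FALSE], A$id, function(g) {
    out <- matrix(0, nr, ncol(v))
    for (c in seq_len(ncol(g)))
      out[, c] <- rowsum_safe(g[, c], idx, nr)
    list(out)
  })
}

ad_scatter_add <- function(A, idx, n_out) {
  v <- ad_value(A)
  out <- matrix(0, n_out, ncol(v))
  for (c in seq_len(ncol(v)))
    out[, c] <- rowsum_safe(v[, c], idx, n_out)
  ad_push(A$tape, out, A$id, function(g) list(g[idx, , drop = FALSE]))
}

rowsum_safe <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

## rowSums(A * B): n x d, n x d -> length-n vector (kept as n x 1 matrix)
ad_dotrows <- function(A, B) {
  Av <- ad_value(A); Bv <- ad_value(B)
  val <- matrix(rowSums(Av * Bv), ncol = 1)
  ad_push(A$tape, val, c(A$id, B$id), function(g) {
    gv <- as.numeric(g)
    list(Av * 0 + gv * Bv, Bv * 0 + gv * Av)
  })
}

## scale rows of M (m x d) by s (m x 1)
ad_rowscale <- function(M, s) {
  Mv <- ad_value(M); sv <- as.numeric(ad_value(s))
  ad_push(M$tape, Mv * sv, c(M$id, s$id), function(g)
    list(g * sv, matrix(rowSums(g * Mv), ncol = 1)))
}

## numerically stable softmax of scores (m x 1) within segments seg (ints)
ad_segment_softmax <- function(scores, seg) {
  sv <- as.numeric(ad_value(scores))
  mx <- tapply(sv, seg, max)
  ex <- exp(sv - mx[as.character(seg)])
  den <- tapply(ex, seg, sum)
  a <- ex / den[as.character(seg)]
  ad_push(scores$tape, matrix(a, ncol = 1), scores$id, function(g) {
    gv <- as.numeric(g)
    dot <- tapply(a * gv, seg, sum)
    list(matrix(a * (gv - dot[as.character(seg)]), ncol = 1))
  })
}

## row-wise LayerNorm with per-column gamma/beta (length ncol)
ad_layernorm <- function(X, gamma, beta, eps = 1e-5) {
  Xv <- ad_value(X); gv <- ad_value(gamma); bv <- ad_value(beta)
  D <- ncol(Xv)
  mu <- rowMeans(Xv)
  xc <- Xv - mu
  va <- rowMeans(xc^2)
  sd_ <- sqrt(va + eps)
  xhat <- xc / sd_
  val <- sweep(xhat * rep(1, nrow(Xv)) %o% gv, 2, bv, `+`)
  ad_push(X$tape, val, c(X$id, gamma$id, beta$id), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2, gv, `*`)
    dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd_
    list(dX, dgamma, dbeta)
  })
}

ad_cbind <- function(parts) {
  tp <- parts[[1]]$tape
  vals <- lapply(parts, ad_value)
  widths <- vapply(vals, ncol, 0L)
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  ad_push(tp, do.call(cbind, vals), vapply(parts, `[[`, 0L, "id"),
          function(g) lapply(seq_along(parts), function(p)
            g[, starts[p]:ends[p], drop = FALSE]))
}

## mean squared error over mask-true positions; pred n x 1000, target/mask same
ad_masked_mse <- function(pred, target, mask) {
  pv <- ad_value(pred)
  nm <- sum(mask)
  if (nm == 0) stop("masked loss undefined: empty mask")
  diff <- (pv - target)
  diff[!mask] <- 0
  val <- sum(diff^2) / nm
  ad_push(pred$tape, val, pred$id, function(g)
    list(g * 2 * diff / nm))
}

## backprop from a scalar node; returns list of gradients indexed by node id
ad_backward <- function(tape, loss) {
  grads <- vector("list", tape$n)
  grads[[loss$id]] <- 1
  for (i in seq(loss$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    vjp <- tape$vjps[[i]]
    if (is.null(vjp)) next
    pg <- vjp(g)
    ps <- tape$parents[[i]]
    for (p in seq_along(ps)) {
      id <- ps[p]
      grads[[id]] <- if (is.null(grads[[id]])) pg[[p]]
                     else grads[[id]] + pg[[p]]
    }
  }
  grads
}
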