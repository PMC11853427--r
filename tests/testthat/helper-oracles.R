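# Brute-force oracles, deliberately written as plain loops so they stay
# independent of the vectorized implementations they check.

oracle_contact_adjacency <- function(xyz, cutoff) {
  n <- nrow(xyz)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) adj[i, j] <- 1L
  }
  adj
}

oracle_conv1d <- function(X, W, b, k) {
  L <- nrow(X); din <- ncol(X); dout <- length(b)
  p <- (k - 1L) %/% 2L
  out <- matrix(0, L, dout)
  for (t in seq_len(L)) for (o in seq_len(dout)) {
    acc <- b[o]
    for (u in seq_len(k)) {
      src <- t + u - 1L - p
      if (src >= 1L && src <= L) {
        for (c in seq_len(din)) {
          acc <- acc + X[src, c] * W[(u - 1L) * din + c, o]
        }
      }
    }
    out[t, o] <- acc
  }
  out
}

oracle_local_encode <- function(tokens, params) {
  e <- params$emb[tokens + 1L, , drop = FALSE]
  relu <- function(x) pmax(x, 0)
  a <- relu(oracle_conv1d(e, params$conv3$W, params$conv3$b, 3L))
  b <- relu(oracle_conv1d(a, params$conv5$W, params$conv5$b, 5L)) + e
  relu(oracle_conv1d(b, params$conv7$W, params$conv7$b, 7L)) + b
}

# direct per-head, per-vertex implementation of the attention equations
oracle_gt_block <- function(hbar, ebar, edges, params, heads) {
  n <- nrow(hbar); d <- ncol(hbar); dk <- d %/% heads
  E <- nrow(edges)
  h_out <- hbar
  e_out <- ebar
  agg_cat <- matrix(0, n, d)
  shat_cat <- matrix(0, E, d)
  for (h in seq_len(heads)) {
    rows <- ((h - 1) * dk + 1):(h * dk)
    Wq <- params$Wq[rows, , drop = FALSE]; Wk <- params$Wk[rows, , drop = FALSE]
    Wv <- params$Wv[rows, , drop = FALSE]; We <- params$We[rows, , drop = FALSE]
    for (i in seq_len(n)) {
      nbr_edges <- which(edges[, 1] == i)
      if (length(nbr_edges) == 0L) next
      scores <- matrix(0, length(nbr_edges), dk)
      for (m in seq_along(nbr_edges)) {
        e_ix <- nbr_edges[m]; j <- edges[e_ix, 2]
        s <- sum((Wq %*% hbar[i, ]) * (Wk %*% hbar[j, ])) / sqrt(dk)
        gate <- as.vector(We %*% ebar[e_ix, ])
        scores[m, ] <- s * gate
        shat_cat[e_ix, rows] <- s * gate
      }
      w <- exp(pmin(pmax(scores, -5), 5))
      w <- sweep(w, 2, colSums(w), "/")
      acc <- numeric(dk)
      for (m in seq_along(nbr_edges)) {
        j <- edges[nbr_edges[m], 2]
        acc <- acc + w[m, ] * as.vector(Wv %*% hbar[j, ])
      }
      agg_cat[i, rows] <- acc
    }
  }
  h_out <- hbar + agg_cat %*% t(params$Oh)
  e_out <- ebar + shat_cat %*% t(params$Oe)
  list(h = h_out, e = e_out)
}

oracle_gcn <- function(h, e, adjacency, edges, rev_index, params) {
  n <- nrow(h)
  Ahat <- diag(n)
  if (nrow(edges) > 0) {
    for (m in seq_len(nrow(edges))) {
      z1 <- sum(e[m, ] * params$wr) + params$br
      z2 <- sum(e[rev_index[m], ] * params$wr) + params$br
      Ahat[edges[m, 1], edges[m, 2]] <-
        (1 / (1 + exp(-z1)) + 1 / (1 + exp(-z2))) / 2
    }
  }
  deg <- rowSums(Ahat)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    S[i, j] <- Ahat[i, j] / sqrt(deg[i] * deg[j])
  relu <- function(x) pmax(x, 0)
  mlp <- relu(sweep(h %*% t(params$Wm1), 2, params$bm1, "+")) %*% t(params$Wm2)
  mlp <- sweep(mlp, 2, params$bm2, "+")
  relu(S %*% h %*% params$Wx) + mlp
}

oracle_ffn_row <- function(row, params) {
  mu <- mean(row)
  va <- mean((row - mu)^2)
  xhat <- (row - mu) / sqrt(va + 1e-5)
  nrm <- xhat * params$gamma + params$beta
  z <- as.vector(params$W2 %*% nrm) + params$b2
  r <- pmax(z, 0)
  row + as.vector(params$W1 %*% r) + params$b1
}

oracle_classify_row <- function(row, params) {
  sg <- function(x) 1 / (1 + exp(-x))
  l1 <- sg(as.vector(params$Wc1 %*% row) + params$bc1)
  l2 <- sg(as.vector(params$Wc2 %*% l1) + params$bc2)
  sg(sum(params$Wc3 * l2) + params$bc3)
}

# random small attention instance shared by oracle tests
random_gt_instance <- function(n, d, heads, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < 0.5) { adj[i, j] <- 1L; adj[j, i] <- 1L }
  }
  graph <- list(n_vertices = n, adjacency = adj,
                edge_list = which(upper.tri(adj) & adj == 1, arr.ind = TRUE))
  de <- rgtsite:::directed_edges(graph)
  list(hbar = matrix(rnorm(n * d), n, d),
       ebar = matrix(rnorm(nrow(de$edges) * d), nrow(de$edges), d),
       edges = de$edges, rev_index = de$rev_index, adjacency = adj)
}

random_block_params <- function(d, d_ff, seed) {
  set.seed(seed)
  rm_ <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.3), nr, nc)
  list(Wq = rm_(d, d), Wk = rm_(d, d), Wv = rm_(d, d), We = rm_(d, d),
       Oh = rm_(d, d), Oe = rm_(d, d),
       wr = rm_(d, 1), br = rnorm(1), Wx = rm_(d, d),
       Wm1 = rm_(d, d), bm1 = rnorm(d), Wm2 = rm_(d, d), bm2 = rnorm(d),
       gamma = runif(d, 0.5, 1.5), beta = rnorm(d),
       W2 = rm_(d_ff, d), b2 = rnorm(d_ff), W1 = rm_(d, d_ff), b1 = rnorm(d))
}
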