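#' Model configuration for the residual graph transformer
#'
#' @param d Width of the transformer block (divisible by `heads`); the final
#'   block emits `d`-dimensional vertex features consumed by the classifier.
#' @param heads Number of attention heads.
#' @param k_pe Number of Laplacian positional-encoding eigenvectors.
#' @param n_blocks Number of transformer/GCN/FFN blocks.
#' @param d_ff Feed-forward inner width (default `2 * d`).
#' @param local_dim Channel width of the local convolutional encoder.
#' @param global_dim Width of the global embedding block.
#' @param use_local,use_global,use_physchem Ablation switches for the three
#'   vertex-feature blocks (full model: 1024 + 1024 + 36 = 2084).
#' @param gate_order `"pre"` (default) gates attention scores with projected
#'   edge features before the softmax so weights remain a distribution;
#'   `"post"` multiplies after the softmax.
#' @param dropout Dropout rate used in training mode.
#' @param classifier_dims Hidden sizes of the classifier head.
#' @return Config list.
#' @export
rgt_config <- function(d = 256L, heads = 8L, k_pe = 8L, n_blocks = 1L,
                       d_ff = NULL, local_dim = 1024L, global_dim = 1024L,
                       use_local = TRUE, use_global = TRUE, use_physchem = TRUE,
                       gate_order = c("pre", "post"), dropout = 0.3,
                       classifier_dims = c(64L, 16L, 1L)) {
  gate_order <- match.arg(gate_order)
  stopifnot(d %% heads == 0L)
  dn <- (if (use_local) local_dim else 0L) +
    (if (use_global) global_dim else 0L) + (if (use_physchem) 36L else 0L)
  if (dn == 0L) stop("at least one vertex feature block must be enabled")
  list(d = as.integer(d), heads = as.integer(heads), k_pe = as.integer(k_pe),
       n_blocks = as.integer(n_blocks),
       d_ff = as.integer(if (is.null(d_ff)) 2L * d else d_ff),
       local_dim = as.integer(local_dim), global_dim = as.integer(global_dim),
       use_local = use_local, use_global = use_global,
       use_physchem = use_physchem, gate_order = gate_order,
       dropout = dropout, de = 6L, dn = as.integer(dn),
       classifier_dims = as.integer(classifier_dims))
}

xavier <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(1 / nc)), nr, nc)

#' Initialize all learnable tensors of the network
#'
#' @param config Output of [rgt_config()].
#' @param seed Integer seed for reproducible initialization.
#' @return Model object: list with `config` and `params`.
#' @export
rgt_init <- function(config, seed = 1L) {
  set.seed(seed)
  d <- config$d
  mk_block <- function() {
    list(
      Wq = xavier(d, d), Wk = xavier(d, d), Wv = xavier(d, d),
      We = xavier(d, d), Oh = xavier(d, d), Oe = xavier(d, d),
      wr = matrix(rnorm(d, sd = sqrt(1 / d)), d, 1), br = 0,
      Wx = xavier(d, d),
      Wm1 = xavier(d, d), bm1 = numeric(d),
      Wm2 = xavier(d, d), bm2 = numeric(d),
      gamma = rep(1, d), beta = numeric(d),
      W2 = xavier(config$d_ff, d), b2 = numeric(config$d_ff),
      W1 = xavier(d, config$d_ff), b1 = numeric(d)
    )
  }
  cd <- config$classifier_dims
  params <- list(
    A0 = xavier(d, config$dn), a0 = numeric(d),
    B0 = xavier(d, config$de), b0 = numeric(d),
    C0 = xavier(d, config$k_pe), c0 = numeric(d),
    blocks = lapply(seq_len(config$n_blocks), function(i) mk_block()),
    Wc1 = xavier(cd[1], d), bc1 = numeric(cd[1]),
    Wc2 = xavier(cd[2], cd[1]), bc2 = numeric(cd[2]),
    # output bias starts at the logit of a ~1:20 positive rate so the head
    # begins near the class prior instead of p = 0.5
    Wc3 = xavier(cd[3], cd[2]), bc3 = rep(-3, cd[3])
  )
  if (config$use_local) {
    params$local <- local_encoder_init(config$local_dim, seed = seed + 1L)
  }
  structure(list(config = config, params = params), class = "rgt_model")
}

# --- Laplacian positional encoding -----------------------------------------

#' Laplacian positional encoding of a graph
#'
#' Eigendecomposition of the symmetric normalized Laplacian
#' `L = I - D^{-1/2} A D^{-1/2}` (isolated vertices contribute identity
#' rows). Eigenvectors of zero eigenvalues (one per connected component) are
#' trivial and excluded; the `k` eigenvectors of the smallest non-trivial
#' eigenvalues form the encoding, zero-padded when the graph is too small.
#' Each vector's sign is fixed so its first entry of non-negligible magnitude
#' is positive.
#'
#' @param graph A `chain_graph`.
#' @param k Number of encoding dimensions.
#' @return List with `vectors` (N x k), `eigenvalues` (length k, padded with
#'   zeros), and `all_eigenvalues` of the Laplacian.
#' @export
laplacian_pe <- function(graph, k) {
  A <- graph$adjacency
  n <- graph$n_vertices
  deg <- rowSums(A)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - A * outer(dinv, dinv)
  ee <- eigen(L, symmetric = TRUE)
  vals <- rev(ee$values)            # ascending
  vecs <- ee$vectors[, rev(seq_len(n)), drop = FALSE]
  nontriv <- which(vals > 1e-8)
  take <- nontriv[seq_len(min(k, length(nontriv)))]
  pe <- matrix(0, n, k)
  ev <- numeric(k)
  if (length(take) > 0) {
    V <- vecs[, take, drop = FALSE]
    for (c in seq_len(ncol(V))) {
      nz <- which(abs(V[, c]) > 1e-8)
      if (length(nz) > 0 && V[nz[1], c] < 0) V[, c] <- -V[, c]
    }
    pe[, seq_along(take)] <- V
    ev[seq_along(take)] <- vals[take]
  }
  list(vectors = pe, eigenvalues = ev, all_eigenvalues = vals)
}

add_bias <- function(x, v) x + rep(v, each = nrow(x))

# scatter-add rows of X into an N-row accumulator by integer group
agg_by <- function(group, X, n) {
  out <- matrix(0, n, ncol(X))
  if (length(group) == 0L) return(out)
  tmp <- rowsum(X, group = group)
  out[as.integer(rownames(tmp)), ] <- tmp
  out
}

# --- input projections ------------------------------------------------------

#' Project raw vertex/edge features and add positional encodings
#'
#' `h0 = A0 alpha + a0`, `e0 = B0 beta + b0`, `pe0 = C0 lambda + c0`,
#' `hbar0 = h0 + pe0`.
#'
#' @param vertex_feats N x dn matrix.
#' @param edge_feats E x 6 matrix (directed edges).
#' @param pe N x k positional-encoding matrix.
#' @param params List with `A0`, `a0`, `B0`, `b0`, `C0`, `c0`.
#' @return List with `hbar` (N x d) and `ebar` (E x d).
#' @export
project_inputs <- function(vertex_feats, edge_feats, pe, params) {
  h0 <- add_bias(vertex_feats %*% t(params$A0), params$a0)
  pe0 <- add_bias(pe %*% t(params$C0), params$c0)
  ebar <- if (nrow(edge_feats) > 0)
    add_bias(edge_feats %*% t(params$B0), params$b0)
  else matrix(0, 0, nrow(params$B0))
  list(hbar = h0 + pe0, ebar = ebar)
}

# --- graph transformer block ------------------------------------------------

#' Edge-gated multi-head attention update (one graph-transformer block)
#'
#' Per head: raw score `s_ij = (Q h_i . K h_j)/sqrt(d_k)` for each directed
#' edge j -> attending vertex i, gated componentwise with the projected edge
#' feature `E e_ij`, exponent clamped to `[-5, 5]`, softmax-normalized over
#' the neighborhood. Vertex and edge updates are residual; an isolated vertex
#' passes through unchanged.
#'
#' @param hbar N x d vertex features.
#' @param ebar E x d edge features (directed).
#' @param edges E x 2 directed edge index (attending vertex, neighbor).
#' @param params Block parameter list.
#' @param heads Number of heads.
#' @param gate_order `"pre"` or `"post"` softmax gating.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List with `h` (N x d), `e` (E x d), and optionally `cache`.
#' @export
gt_block <- function(hbar, ebar, edges, params, heads, gate_order = "pre",
                     keep_cache = FALSE) {
  n <- nrow(hbar); d <- ncol(hbar)
  dk <- d %/% heads
  E <- nrow(edges)
  if (E == 0L) {
    out <- list(h = hbar, e = ebar)
    if (keep_cache) out$cache <- list(empty = TRUE, hbar = hbar, ebar = ebar)
    return(out)
  }
  res <- gt_block_fwd_cpp(hbar, ebar, as.integer(edges[, 1]),
                          as.integer(edges[, 2]), params$Wq, params$Wk,
                          params$Wv, params$We, params$Oh, params$Oe,
                          as.integer(heads), gate_order == "pre",
                          full = keep_cache)
  out <- list(h = res$h, e = res$e)
  if (keep_cache) {
    out$cache <- c(list(empty = FALSE, hbar = hbar, ebar = ebar,
                        src = as.integer(edges[, 1]),
                        dst = as.integer(edges[, 2]),
                        heads = as.integer(heads), n = n,
                        gate_order = gate_order),
                   res[c("Qt", "Kt", "Vt", "Gt", "st", "wt", "aggt")])
  }
  out
}

gt_block_backward <- function(dh, de, cache, params) {
  if (cache$empty) {
    zero <- function(p) array(0, dim = if (is.matrix(p)) dim(p) else length(p))
    return(list(dh = dh, de = de,
                grads = list(Wq = zero(params$Wq), Wk = zero(params$Wk),
                             Wv = zero(params$Wv), We = zero(params$We),
                             Oh = zero(params$Oh), Oe = zero(params$Oe))))
  }
  res <- gt_block_bwd_cpp(dh, de, cache$hbar, cache$ebar, cache$src,
                          cache$dst, cache$Qt, cache$Kt, cache$Vt, cache$Gt,
                          cache$st, cache$wt, cache$aggt,
                          params$Wq, params$Wk, params$Wv,
                          params$We, params$Oh, params$Oe, cache$heads)
  list(dh = res$dh, de = res$de,
       grads = list(Wq = res$Wq, Wk = res$Wk, Wv = res$Wv, We = res$We,
                    Oh = res$Oh, Oe = res$Oe))
}

# --- edge-weighted residual graph convolution -------------------------------

#' Edge-weighted residual graph convolution
#'
#' Each updated edge feature is reduced to a scalar weight (linear map +
#' logistic squash), symmetrized, and masked onto the adjacency with unit
#' self-loops: `Ahat = A * W + I`. The symmetrically normalized
#' `S = D^{-1/2} Ahat D^{-1/2}` drives `relu(S H Wx) + MLP(H)` where the MLP
#' (one hidden ReLU layer) carries the residual path.
#'
#' @param h N x d vertex features (transformer output).
#' @param e E x d edge features.
#' @param adjacency N x N 0/1 matrix.
#' @param edges,rev_index Directed edge index and reverse-edge lookup.
#' @param params Block parameter list.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List with `h` (N x d) and optionally `cache`.
#' @export
residual_gcn_update <- function(h, e, adjacency, edges, rev_index, params,
                                keep_cache = FALSE) {
  src <- as.integer(edges[, 1]); dst <- as.integer(edges[, 2])
  rev <- as.integer(rev_index)
  h_out <- gcn_fwd_cpp(h, e, src, dst, rev, params$wr, params$br, params$Wx,
                       params$Wm1, params$bm1, params$Wm2, params$bm2)
  out <- list(h = h_out)
  if (keep_cache) {
    # the backward kernel recomputes intermediates from these inputs
    out$cache <- list(h = h, e = e, src = src, dst = dst, rev = rev)
  }
  out
}

residual_gcn_backward <- function(dout, cache, params) {
  res <- gcn_bwd_cpp(dout, cache$h, cache$e, cache$src, cache$dst, cache$rev,
                     params$wr, params$br, params$Wx, params$Wm1, params$bm1,
                     params$Wm2, params$bm2)
  list(dh = res$dh, de = res$de,
       grads = list(wr = res$wr, br = res$br, Wx = res$Wx,
                    Wm1 = res$Wm1, bm1 = as.vector(res$bm1),
                    Wm2 = res$Wm2, bm2 = as.vector(res$bm2)))
}

# normalized edge-weighted adjacency of one block, for inspection
gcn_normalized_adjacency <- function(h, e, edges, rev_index, params) {
  gcn_norm_adj_cpp(h, e, as.integer(edges[, 1]), as.integer(edges[, 2]),
                   as.integer(rev_index), params$wr, params$br)
}

# --- feed-forward stage -----------------------------------------------------

#' Residual feed-forward update with layer normalization
#'
#' `h_out = h + W1 relu(W2 Norm(h))` applied row-wise; `Norm` is
#' feature-dimension layer normalization with learnable scale and shift.
#' Dropout (training mode) acts on the ReLU activations.
#'
#' @param h N x d matrix.
#' @param params Block parameter list (uses `gamma`, `beta`, `W1`, `b1`,
#'   `W2`, `b2`).
#' @param drop_mask Optional dropout mask for the inner activations.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List with `h` and optionally `cache`.
#' @export
ffn_update <- function(h, params, drop_mask = NULL, keep_cache = FALSE) {
  mask <- if (is.null(drop_mask)) matrix(0, 0, 0) else drop_mask
  out <- list(h = ffn_fwd_cpp(h, params$gamma, params$beta, params$W1,
                              params$b1, params$W2, params$b2, mask))
  if (keep_cache) out$cache <- list(h = h, mask = mask)
  out
}

ffn_backward <- function(dout, cache, params) {
  res <- ffn_bwd_cpp(dout, cache$h, params$gamma, params$beta, params$W1,
                     params$b1, params$W2, params$b2, cache$mask)
  list(dh = res$dh,
       grads = list(gamma = as.vector(res$gamma), beta = as.vector(res$beta),
                    W1 = res$W1, b1 = as.vector(res$b1),
                    W2 = res$W2, b2 = as.vector(res$b2)))
}

# --- classifier head --------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Classifier head: three sigmoid layers to a per-vertex probability
#'
#' @param h N x d vertex feature matrix.
#' @param params Model parameter list (uses `Wc1..Wc3`, `bc1..bc3`).
#' @param keep_cache Keep intermediates for the backward pass.
#' @return List with `p` (probabilities strictly in (0,1)) and optionally
#'   `cache`.
#' @export
classify <- function(h, params, keep_cache = FALSE) {
  L1 <- sigmoid(add_bias(h %*% t(params$Wc1), params$bc1))
  L2 <- sigmoid(add_bias(L1 %*% t(params$Wc2), params$bc2))
  p <- as.vector(sigmoid(add_bias(L2 %*% t(params$Wc3), params$bc3)))
  out <- list(p = p)
  if (keep_cache) out$cache <- list(h = h, L1 = L1, L2 = L2, p = p)
  out
}

classify_backward <- function(dp, cache, params) {
  dz3 <- matrix(dp * cache$p * (1 - cache$p), ncol = 1)
  dWc3 <- crossprod(dz3, cache$L2)
  dbc3 <- colSums(dz3)
  dL2 <- dz3 %*% params$Wc3
  dz2 <- dL2 * cache$L2 * (1 - cache$L2)
  dWc2 <- crossprod(dz2, cache$L1)
  dbc2 <- colSums(dz2)
  dL1 <- dz2 %*% params$Wc2
  dz1 <- dL1 * cache$L1 * (1 - cache$L1)
  dWc1 <- crossprod(dz1, cache$h)
  dbc1 <- colSums(dz1)
  dh <- dz1 %*% params$Wc1
  list(dh = dh, grads = list(Wc1 = dWc1, bc1 = dbc1, Wc2 = dWc2, bc2 = dbc2,
                             Wc3 = dWc3, bc3 = dbc3))
}

# --- full forward / backward ------------------------------------------------

bundle_vertex_blocks <- function(bundle, model, keep_cache = FALSE) {
  cfg <- model$config
  local <- NULL
  if (cfg$use_local) {
    local <- local_encode(bundle$tokens, model$params$local,
                          keep_cache = keep_cache)
  }
  glob <- if (cfg$use_global) bundle$global else NULL
  if (cfg$use_global && is.null(glob))
    stop("global block: bundle has no embeddings but config requires them")
  phys <- if (cfg$use_physchem) bundle$physchem else NULL
  list(local = local, glob = glob, phys = phys)
}

#' Full network forward pass on one feature bundle
#'
#' Pipeline: Laplacian positional encoding, input projections, then
#' `n_blocks` of (edge-gated attention, edge-weighted graph convolution,
#' dropout, residual feed-forward), then the classifier head. Dropout is
#' active only in training mode; evaluation-mode forwards are deterministic.
#'
#' @param bundle A `feature_bundle` (already scaled if the model carries
#'   scaling statistics — see [predict_chain()]).
#' @param model An `rgt_model`.
#' @param training Logical; enables dropout and random PE sign flips.
#' @param pe Optional precomputed positional encoding (N x k matrix).
#' @param keep_cache Keep all intermediates for the backward pass.
#' @return List with `p` (per-residue probabilities) and optionally `cache`.
#' @export
rgt_forward <- function(bundle, model, training = FALSE, pe = NULL,
                        keep_cache = FALSE) {
  cfg <- model$config
  pp <- model$params
  n <- bundle$graph$n_vertices
  if (is.null(pe)) {
    pe <- if (!is.null(bundle$pe) && ncol(bundle$pe) == cfg$k_pe) bundle$pe
    else laplacian_pe(bundle$graph, cfg$k_pe)$vectors
    if (training) {
      flips <- sample(c(-1, 1), cfg$k_pe, replace = TRUE)
      pe <- pe * rep(flips, each = n)
    }
  }
  blocks_in <- bundle_vertex_blocks(bundle, model, keep_cache = keep_cache)
  alpha <- assemble_vertex_features(blocks_in$local, blocks_in$glob,
                                    blocks_in$phys)
  if (ncol(alpha) != cfg$dn)
    stop("vertex block: assembled dim ", ncol(alpha), " != config dn ", cfg$dn)
  proj <- project_inputs(alpha, bundle$edge_feats, pe, pp)
  h <- proj$hbar; e <- proj$ebar
  caches <- vector("list", cfg$n_blocks)
  for (l in seq_len(cfg$n_blocks)) {
    bp <- pp$blocks[[l]]
    gt <- gt_block(h, e, bundle$edges, bp, cfg$heads, cfg$gate_order,
                   keep_cache = keep_cache)
    gc_ <- residual_gcn_update(gt$h, gt$e, bundle$graph$adjacency,
                               bundle$edges, bundle$rev_index, bp,
                               keep_cache = keep_cache)
    if (training && cfg$dropout > 0) {
      m_gcn <- (matrix(runif(n * cfg$d), n, cfg$d) >= cfg$dropout) /
        (1 - cfg$dropout)
      m_ffn <- (matrix(runif(n * cfg$d_ff), n, cfg$d_ff) >= cfg$dropout) /
        (1 - cfg$dropout)
    } else {
      m_gcn <- NULL; m_ffn <- NULL
    }
    hd <- if (!is.null(m_gcn)) gc_$h * m_gcn else gc_$h
    ff <- ffn_update(hd, bp, drop_mask = m_ffn, keep_cache = keep_cache)
    caches[[l]] <- list(gt = gt$cache, gcn = gc_$cache, m_gcn = m_gcn,
                        ffn = ff$cache)
    h <- ff$h
    e <- gt$e
  }
  cls <- classify(h, pp, keep_cache = keep_cache)
  out <- list(p = cls$p)
  if (keep_cache) {
    out$cache <- list(pe = pe, alpha = alpha, local_cache =
                        if (cfg$use_local) attr(blocks_in$local, "cache") else NULL,
                      edge_feats = bundle$edge_feats, blocks = caches,
                      cls = cls$cache, proj_in = list(alpha = alpha, pe = pe))
  }
  out
}

#' Backward pass: gradients of the per-chain loss w.r.t. all parameters
#'
#' @param dp Gradient of the loss w.r.t. the output probabilities.
#' @param cache Cache from [rgt_forward()] with `keep_cache = TRUE`.
#' @param model The `rgt_model` used in the forward pass.
#' @return Gradient list mirroring `model$params`.
#' @export
rgt_backward <- function(dp, cache, model) {
  cfg <- model$config
  pp <- model$params
  if (cfg$gate_order != "pre")
    stop("training requires gate_order = 'pre'; the post-softmax variant ",
         "is provided for inference-time comparison only")
  cb <- classify_backward(dp, cache$cls, pp)
  dh <- cb$dh
  de <- NULL
  grads <- list(Wc1 = cb$grads$Wc1, bc1 = cb$grads$bc1,
                Wc2 = cb$grads$Wc2, bc2 = cb$grads$bc2,
                Wc3 = cb$grads$Wc3, bc3 = cb$grads$bc3)
  grads$blocks <- vector("list", cfg$n_blocks)
  de <- matrix(0, nrow(cache$edge_feats), cfg$d)
  for (l in rev(seq_len(cfg$n_blocks))) {
    bc <- cache$blocks[[l]]
    bp <- pp$blocks[[l]]
    fb <- ffn_backward(dh, bc$ffn, bp)
    dhd <- fb$dh
    if (!is.null(bc$m_gcn)) dhd <- dhd * bc$m_gcn
    gb <- residual_gcn_backward(dhd, bc$gcn, bp)
    dh_gt <- gb$dh
    de_gt <- de + gb$de
    tb <- gt_block_backward(dh_gt, de_gt, bc$gt, bp)
    dh <- tb$dh
    de <- tb$de
    grads$blocks[[l]] <- c(tb$grads, gb$grads, fb$grads)
  }
  # input projections
  alpha <- cache$alpha
  grads$A0 <- crossprod(dh, alpha)
  grads$a0 <- colSums(dh)
  grads$C0 <- crossprod(dh, cache$pe)
  grads$c0 <- colSums(dh)
  if (nrow(cache$edge_feats) > 0) {
    grads$B0 <- crossprod(de, cache$edge_feats)
    grads$b0 <- colSums(de)
  } else {
    grads$B0 <- matrix(0, cfg$d, cfg$de)
    grads$b0 <- numeric(cfg$d)
  }
  if (cfg$use_local) {
    dalpha <- dh %*% pp$A0
    dlocal <- dalpha[, seq_len(cfg$local_dim), drop = FALSE]
    grads$local <- local_encode_backward(dlocal, cache$local_cache, pp$local)
  }
  grads
}
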