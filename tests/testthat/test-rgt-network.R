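test_that("normalized Laplacian spectra stay in [0, 2]", {
  for (seed in 1:5) {
    set.seed(seed)
    xyz <- matrix(rnorm(12 * 3, sd = 5), 12, 3)
    g <- build_contact_graph(xyz)
    pe <- laplacian_pe(g, 4)
    expect_true(all(pe$all_eigenvalues >= -1e-9))
    expect_true(all(pe$all_eigenvalues <= 2 + 1e-9))
  }
})

test_that("zero-eigenvalue multiplicity equals the number of components", {
  # two disjoint triangles
  tri <- matrix(1L, 3, 3); diag(tri) <- 0L
  adj <- rbind(cbind(tri, matrix(0L, 3, 3)), cbind(matrix(0L, 3, 3), tri))
  g <- list(n_vertices = 6L, adjacency = adj,
            edge_list = which(upper.tri(adj) & adj == 1, arr.ind = TRUE))
  pe <- laplacian_pe(g, 3)
  expect_equal(sum(abs(pe$all_eigenvalues) < 1e-8), 2L)
  # a connected path has exactly one
  padj <- matrix(0L, 4, 4); padj[cbind(1:3, 2:4)] <- 1L; padj <- padj + t(padj)
  gp <- list(n_vertices = 4L, adjacency = padj,
             edge_list = which(upper.tri(padj) & padj == 1, arr.ind = TRUE))
  expect_equal(sum(abs(laplacian_pe(gp, 2)$all_eigenvalues) < 1e-8), 1L)
})

test_that("the complete graph K4 has all non-trivial eigenvalues 4/3", {
  adj <- matrix(1L, 4, 4); diag(adj) <- 0L
  g <- list(n_vertices = 4L, adjacency = adj,
            edge_list = which(upper.tri(adj) & adj == 1, arr.ind = TRUE))
  pe <- laplacian_pe(g, 3)
  expect_equal(pe$eigenvalues, rep(4 / 3, 3), tolerance = 1e-10)
})

test_that("the two-vertex path has spectrum {0, 2} and a sign-fixed vector", {
  adj <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  g <- list(n_vertices = 2L, adjacency = adj,
            edge_list = matrix(c(1L, 2L), 1, 2))
  pe <- laplacian_pe(g, 1)
  expect_equal(sort(pe$all_eigenvalues), c(0, 2), tolerance = 1e-12)
  expect_equal(pe$vectors[, 1], c(1, -1) / sqrt(2), tolerance = 1e-12)
})

test_that("small graphs zero-pad missing encoding columns", {
  adj <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  g <- list(n_vertices = 2L, adjacency = adj,
            edge_list = matrix(c(1L, 2L), 1, 2))
  pe <- laplacian_pe(g, 5)
  expect_equal(dim(pe$vectors), c(2L, 5L))
  expect_true(all(pe$vectors[, 2:5] == 0))
})

test_that("input projections follow the affine contract", {
  d <- 6L
  vf <- matrix(rnorm(12), 3, 4)
  ef <- matrix(rnorm(12), 2, 6)
  pe <- matrix(rnorm(6), 3, 2)
  params <- list(A0 = matrix(0, d, 4), a0 = rnorm(d),
                 B0 = matrix(rnorm(d * 6), d, 6), b0 = rnorm(d),
                 C0 = matrix(0, d, 2), c0 = rnorm(d))
  out <- project_inputs(vf, ef, pe, params)
  # zero weights collapse every vertex to the summed biases
  expect_equal(out$hbar, matrix(params$a0 + params$c0, 3, d, byrow = TRUE),
               ignore_attr = TRUE)
  # random instance against an explicit per-element loop
  params$A0 <- matrix(rnorm(d * 4), d, 4)
  params$C0 <- matrix(rnorm(d * 2), d, 2)
  out <- project_inputs(vf, ef, pe, params)
  for (i in 1:3) {
    expect_equal(out$hbar[i, ],
                 as.vector(params$A0 %*% vf[i, ]) + params$a0 +
                   as.vector(params$C0 %*% pe[i, ]) + params$c0,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_equal(out$ebar[2, ],
               as.vector(params$B0 %*% ef[2, ]) + params$b0,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("attention weights form a distribution over each neighborhood", {
  inst <- random_gt_instance(n = 6, d = 8, heads = 2, seed = 9)
  params <- random_block_params(8, 12, seed = 10)
  res <- rgtsite:::gt_block_fwd_cpp(
    inst$hbar, inst$ebar, as.integer(inst$edges[, 1]),
    as.integer(inst$edges[, 2]), params$Wq, params$Wk, params$Wv, params$We,
    params$Oh, params$Oe, 2L, TRUE, full = TRUE)
  w <- t(res$wt)   # per-edge attention weights, one row per edge
  sums <- rowsum(w, group = inst$edges[, 1])
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("isolated vertices pass through the attention block unchanged", {
  set.seed(11)
  hbar <- matrix(rnorm(32), 4, 8)
  # vertex 4 has no edges
  edges <- rbind(c(1L, 2L), c(2L, 1L), c(2L, 3L), c(3L, 2L))
  ebar <- matrix(rnorm(32), 4, 8)
  params <- random_block_params(8, 12, seed = 12)
  out <- gt_block(hbar, ebar, edges, params, heads = 2)
  expect_equal(out$h[4, ], hbar[4, ], tolerance = 1e-12)
})

test_that("gt_block matches a per-head per-pair brute-force oracle", {
  for (seed in c(21, 22)) {
    inst <- random_gt_instance(n = 5, d = 8, heads = 2, seed = seed)
    params <- random_block_params(8, 12, seed = seed + 100)
    out <- gt_block(inst$hbar, inst$ebar, inst$edges, params, heads = 2)
    ora <- oracle_gt_block(inst$hbar, inst$ebar, inst$edges, params, heads = 2)
    expect_equal(out$h, ora$h, tolerance = 1e-5)
    expect_equal(out$e, ora$e, tolerance = 1e-5)
  }
})

test_that("zeroing the output maps makes attention the identity (residual)", {
  inst <- random_gt_instance(n = 5, d = 8, heads = 2, seed = 13)
  params <- random_block_params(8, 12, seed = 14)
  params$Oh[] <- 0; params$Oe[] <- 0
  out <- gt_block(inst$hbar, inst$ebar, inst$edges, params, heads = 2)
  expect_equal(out$h, inst$hbar)
  expect_equal(out$e, inst$ebar)
})

test_that("the graph convolution handles a single self-looped vertex", {
  set.seed(15)
  h <- matrix(rnorm(8), 1, 8)
  params <- random_block_params(8, 12, seed = 16)
  out <- residual_gcn_update(h, matrix(0, 0, 8), matrix(0L, 1, 1),
                             matrix(integer(0), 0, 2), integer(0), params,
                             keep_cache = TRUE)
  S <- rgtsite:::gcn_normalized_adjacency(h, matrix(0, 0, 8),
                                          matrix(integer(0), 0, 2),
                                          integer(0), params)
  expect_equal(S, matrix(1, 1, 1))
  mlp <- pmax(h %*% t(params$Wm1) + matrix(params$bm1, 1, 8, byrow = TRUE), 0) %*%
    t(params$Wm2) + matrix(params$bm2, 1, 8, byrow = TRUE)
  expect_equal(out$h, pmax(h %*% params$Wx, 0) + mlp, tolerance = 1e-10)
})

test_that("the normalized edge-weighted adjacency is symmetric and exact on a path", {
  set.seed(17)
  adj <- matrix(0L, 3, 3); adj[cbind(1:2, 2:3)] <- 1L; adj <- adj + t(adj)
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(2L, 1L), c(3L, 2L))
  rev_index <- c(3L, 4L, 1L, 2L)
  params <- random_block_params(8, 12, seed = 18)
  params$wr[] <- 0; params$br <- 0   # every edge weight is exactly 1/2
  e <- matrix(rnorm(32), 4, 8)
  h <- matrix(rnorm(24), 3, 8)
  out <- residual_gcn_update(h, e, adj, edges, rev_index, params,
                             keep_cache = TRUE)
  S <- rgtsite:::gcn_normalized_adjacency(h, e, edges, rev_index, params)
  Ahat <- diag(3); Ahat[1, 2] <- Ahat[2, 1] <- 0.5
  Ahat[2, 3] <- Ahat[3, 2] <- 0.5
  D <- diag(1 / sqrt(rowSums(Ahat)))
  expect_equal(S, D %*% Ahat %*% D, tolerance = 1e-12)
  expect_equal(S, t(S), tolerance = 1e-12)
})

test_that("the graph convolution matches its loop oracle", {
  inst <- random_gt_instance(n = 6, d = 8, heads = 2, seed = 19)
  params <- random_block_params(8, 12, seed = 20)
  set.seed(23)
  h <- matrix(rnorm(48), 6, 8)
  out <- residual_gcn_update(h, inst$ebar, inst$adjacency, inst$edges,
                             inst$rev_index, params)
  expect_equal(out$h,
               oracle_gcn(h, inst$ebar, inst$adjacency, inst$edges,
                          inst$rev_index, params),
               tolerance = 1e-5)
})

test_that("the feed-forward stage is residual and matches a scalar oracle", {
  params <- random_block_params(8, 12, seed = 24)
  set.seed(25)
  h <- matrix(rnorm(40), 5, 8)
  out <- ffn_update(h, params)
  expect_equal(dim(out$h), dim(h))
  for (i in 1:5) {
    expect_equal(out$h[i, ], oracle_ffn_row(h[i, ], params), tolerance = 1e-6)
  }
  params$W1[] <- 0; params$b1[] <- 0
  expect_equal(ffn_update(h, params)$h, h, tolerance = 1e-12)
})

test_that("the classifier emits probabilities strictly inside (0, 1)", {
  params <- rgt_init(tiny_config(), seed = 26)$params
  set.seed(27)
  h <- matrix(rnorm(4 * 8, sd = 3), 4, 8)
  out <- classify(h, params)
  expect_true(all(out$p > 0 & out$p < 1))
  for (i in 1:4) {
    expect_equal(out$p[i], oracle_classify_row(h[i, ], params),
                 tolerance = 1e-6)
  }
  zero <- params
  for (nm in c("Wc1", "Wc2", "Wc3")) zero[[nm]][] <- 0
  for (nm in c("bc1", "bc2", "bc3")) zero[[nm]][] <- 0
  expect_equal(classify(h, zero)$p, rep(0.5, 4))
})

test_that("evaluation-mode forwards are deterministic", {
  b <- tiny_bundle()
  model <- rgt_init(tiny_config(), seed = 28)
  p1 <- rgt_forward(b, model)$p
  p2 <- rgt_forward(b, model)$p
  expect_identical(p1, p2)
  expect_length(p1, chain_length_from_bundle <- b$graph$n_vertices)
})

test_that("the graph pipeline is equivariant under vertex permutation", {
  # the local sequence encoder is order-dependent by design, so the
  # equivariance property belongs to the graph stages: ablate the local
  # block and permute the per-vertex inputs
  b <- tiny_bundle()
  model <- rgt_init(tiny_config(use_local = FALSE), seed = 29)
  n <- b$graph$n_vertices
  pe <- laplacian_pe(b$graph, model$config$k_pe)$vectors
  p_ref <- rgt_forward(b, model, pe = pe)$p
  set.seed(30)
  perm <- sample(n)
  bp <- b
  bp$graph$adjacency <- b$graph$adjacency[perm, perm]
  inv <- order(perm)
  bp$edges <- cbind(inv[b$edges[, 1]], inv[b$edges[, 2]])
  bp$physchem <- b$physchem[perm, , drop = FALSE]
  bp$global <- b$global[perm, , drop = FALSE]
  bp$tokens <- b$tokens[perm]
  # the same eigenvectors, consistently permuted, to pin the PE sign freedom
  p_perm <- rgt_forward(bp, model, pe = pe[perm, , drop = FALSE])$p
  expect_equal(p_perm, p_ref[perm], tolerance = 1e-8)
})

test_that("a single-residue chain flows through the whole network", {
  mk <- rgtsite:::new_residue_record("ALA", "1", data.frame(
    name = c("N", "CA", "C", "O"), x = c(-1.2, 0, 1.3, 1.3),
    y = c(0.5, 0, 0, 1.2), z = 0, element = c("N", "C", "C", "O")))
  chain <- rgtsite:::new_chain_structure("A", list(mk))
  b <- featurize_chain(chain, 0L, stub_embedding_provider(1, 12))
  model <- rgt_init(tiny_config(use_local = FALSE), seed = 31)
  out <- rgt_forward(b, model)
  expect_length(out$p, 1)
  expect_true(out$p > 0 && out$p < 1)
})

test_that("analytic gradients agree with central finite differences", {
  b <- tiny_bundle()
  cfg <- tiny_config(n_blocks = 2L)   # covers the inter-block wiring too
  model <- rgt_init(cfg, seed = 32)
  asl <- asl_config(gamma_pos = 1, gamma_neg = 4, margin = 0.05)
  pe <- laplacian_pe(b$graph, cfg$k_pe)$vectors
  loss_fn <- function(m) asl_loss(rgt_forward(b, m, pe = pe)$p, b$labels, asl)
  out <- rgt_forward(b, model, pe = pe, keep_cache = TRUE)
  grads <- rgt_backward(rgtsite:::asl_grad(out$p, b$labels, asl),
                        out$cache, model)
  eps <- 1e-5
  check <- function(get, set, g) {
    set.seed(33)
    for (i in sample(length(g), min(3, length(g)))) {
      m2 <- model; m2$params <- set(model$params, i, eps)
      m3 <- model; m3$params <- set(model$params, i, -eps)
      num <- (loss_fn(m2) - loss_fn(m3)) / (2 * eps)
      if (abs(num) > 1e-9 || abs(g[i]) > 1e-9) {
        expect_equal(g[i], num, tolerance = 1e-3)
      }
    }
  }
  check(NULL, function(p, i, d) { p$A0[i] <- p$A0[i] + d; p }, grads$A0)
  check(NULL, function(p, i, d) { p$blocks[[1]]$Wq[i] <- p$blocks[[1]]$Wq[i] + d; p },
        grads$blocks[[1]]$Wq)
  check(NULL, function(p, i, d) { p$blocks[[1]]$wr[i] <- p$blocks[[1]]$wr[i] + d; p },
        grads$blocks[[1]]$wr)
  check(NULL, function(p, i, d) { p$blocks[[1]]$gamma[i] <- p$blocks[[1]]$gamma[i] + d; p },
        grads$blocks[[1]]$gamma)
  check(NULL, function(p, i, d) { p$blocks[[2]]$We[i] <- p$blocks[[2]]$We[i] + d; p },
        grads$blocks[[2]]$We)
  check(NULL, function(p, i, d) { p$blocks[[2]]$Oe[i] <- p$blocks[[2]]$Oe[i] + d; p },
        grads$blocks[[2]]$Oe)
  check(NULL, function(p, i, d) { p$local$emb[i] <- p$local$emb[i] + d; p },
        grads$local$emb)
  check(NULL, function(p, i, d) { p$local$conv5$W[i] <- p$local$conv5$W[i] + d; p },
        grads$local$conv5$W)
})

test_that("gradients reach the input projection and the embedding table", {
  b <- tiny_bundle()
  model <- rgt_init(tiny_config(), seed = 34)
  out <- rgt_forward(b, model, keep_cache = TRUE)
  grads <- rgt_backward(rgtsite:::asl_grad(out$p, b$labels, asl_config()),
                        out$cache, model)
  expect_true(all(is.finite(grads$A0)))
  expect_gt(sum(abs(grads$A0)), 0)
  used <- sort(unique(b$tokens)) + 1L
  expect_gt(sum(abs(grads$local$emb[used, ])), 0)
  expect_true(all(is.finite(grads$local$emb)))
})
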