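test_that("contact graph uses an inclusive 8 Angstrom boundary", {
  xyz <- rbind(c(0, 0, 0), c(8, 0, 0))
  g <- build_contact_graph(xyz)
  expect_equal(g$adjacency[1, 2], 1L)
  g2 <- build_contact_graph(rbind(c(0, 0, 0), c(8.001, 0, 0)))
  expect_equal(g2$adjacency[1, 2], 0L)
})

test_that("degenerate and small graphs are handled", {
  g1 <- build_contact_graph(matrix(c(1, 2, 3), 1, 3))
  expect_equal(g1$n_vertices, 1L)
  expect_equal(nrow(g1$edge_list), 0L)
  g3 <- build_contact_graph(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  expect_equal(g3$edge_list[, 1], c(1L, 2L), ignore_attr = TRUE)
  expect_equal(g3$edge_list[, 2], c(2L, 3L), ignore_attr = TRUE)
  expect_equal(rowSums(g3$adjacency), c(1, 2, 1))
})

test_that("contact graph matches a brute-force distance check", {
  for (seed in 1:3) {
    set.seed(seed)
    xyz <- matrix(rnorm(30 * 3, sd = 6), 30, 3)
    g <- build_contact_graph(xyz, cutoff = 8)
    expect_identical(g$adjacency, oracle_contact_adjacency(xyz, 8))
    expect_true(all(g$adjacency == t(g$adjacency)))
    expect_true(all(diag(g$adjacency) == 0))
  }
})

test_that("dihedral angles follow the right-handed convention", {
  p1 <- c(0, 1, 0); p2 <- c(0, 0, 0); p3 <- c(1, 0, 0)
  expect_equal(as.numeric(compute_dihedral(p1, p2, p3, c(1, 1, 0))), 0)
  expect_equal(abs(as.numeric(compute_dihedral(p1, p2, p3, c(1, -1, 0)))), 180)
  expect_equal(as.numeric(compute_dihedral(p1, p2, p3, c(1, 0, 1))), 90)
})

test_that("mirroring four points flips the dihedral sign", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- lapply(1:4, function(i) rnorm(3))
    a <- as.numeric(do.call(compute_dihedral, pts))
    mirrored <- lapply(pts, function(p) c(p[1], p[2], -p[3]))
    b <- as.numeric(do.call(compute_dihedral, mirrored))
    expect_equal(a, -b, tolerance = 1e-9)
  }
})

test_that("degenerate dihedral geometry returns 0 with a flag", {
  out <- compute_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_equal(as.numeric(out), 0)
  expect_false(attr(out, "defined"))
})

test_that("physicochemical vectors have the documented layout", {
  chain <- generate_chain(10, seed = 21)
  v <- physchem_vector(chain, 3)
  expect_length(v, 36)
  one_letter <- strsplit(chain$sequence, "")[[1]][3]
  onehot <- v[1:21]
  expect_equal(sum(onehot), 1)
  expect_equal(names(which(onehot == 1)), paste0("aa_", one_letter))
  # terminal torsions are zero-filled
  expect_equal(unname(physchem_vector(chain, 1)["phi"]), 0)
  expect_equal(unname(physchem_vector(chain, 1)["omega"]), 0)
  expect_equal(unname(physchem_vector(chain, 10)["psi"]), 0)
  expect_true(all(v[c("intra_max_dist", "intra_min_dist")] >= 0))
  expect_true(all(abs(v[c("phi", "psi", "omega", "chi1")]) <= 180))
})

test_that("glycine has no chi1 torsion", {
  chain <- generate_chain(30, seed = 5)
  gly <- which(strsplit(chain$sequence, "")[[1]] == "G")
  skip_if(length(gly) == 0, "no glycine drawn at this seed")
  expect_equal(unname(physchem_vector(chain, gly[1])["chi1"]), 0)
})

test_that("edge features match exhaustive atom-pair oracles", {
  chain <- generate_chain(8, seed = 41)
  g <- build_contact_graph(chain)
  ef <- edge_features(chain, 2, 5, g)
  expect_length(ef, 6)
  ri <- chain$residues[[2]]; rj <- chain$residues[[5]]
  dists <- c()
  for (a in seq_len(nrow(ri$atoms))) for (b in seq_len(nrow(rj$atoms))) {
    dists <- c(dists, sqrt(sum((c(ri$atoms$x[a], ri$atoms$y[a], ri$atoms$z[a]) -
                                c(rj$atoms$x[b], rj$atoms$y[b], rj$atoms$z[b]))^2)))
  }
  expect_equal(unname(ef["dist_min"]), min(dists), tolerance = 1e-12)
  expect_equal(unname(ef["dist_max"]), max(dists), tolerance = 1e-12)
  expect_equal(unname(ef["edge_connection"]), g$adjacency[2, 5])
  expect_true(abs(ef["orient_cosine"]) <= 1)
})

test_that("parallel orientation vectors give cosine one", {
  mk_res <- function(origin) {
    new_res <- rgtsite:::new_residue_record
    new_res("ALA", "1", data.frame(
      name = c("N", "CA", "C", "O", "CB"),
      x = origin[1] + c(-1.2, 0, 1.3, 1.3, 0),
      y = origin[2] + c(0.5, 0, 0, 1.2, 2),
      z = origin[3] + c(0, 0, 0, 0, 0),
      element = c("N", "C", "C", "O", "C")))
  }
  chain <- rgtsite:::new_chain_structure("A", list(mk_res(c(0, 0, 0)),
                                                  mk_res(c(5, 0, 0))))
  g <- build_contact_graph(chain)
  ef <- edge_features(chain, 1, 2, g)
  expect_equal(unname(ef["orient_cosine"]), 1, tolerance = 1e-12)
})

test_that("featurized bundles are complete, symmetric, and deterministic", {
  chain <- generate_chain(10, seed = 51)
  labels <- rep(c(0L, 1L), 5)
  prov <- stub_embedding_provider(seed = 3, dim = 16)
  b1 <- featurize_chain(chain, labels, prov)
  b2 <- featurize_chain(chain, labels, prov)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$physchem), 10)
  expect_equal(ncol(b1$global), 16)
  # edge tensor is stored for both directions and is symmetric under (i,j)<->(j,i)
  E <- nrow(b1$edges)
  expect_equal(b1$edges[b1$rev_index, c(2, 1)], b1$edges, ignore_attr = TRUE)
  expect_equal(b1$edge_feats[b1$rev_index, "dist_ca"],
               b1$edge_feats[, "dist_ca"], ignore_attr = TRUE)
  # serialization round trip
  path <- tempfile(fileext = ".rds")
  save_bundle(b1, path)
  expect_identical(load_bundle(path), b1)
})

test_that("chains with no contacts yield valid empty-edge bundles", {
  xyz <- 20 * diag(3)
  mk <- function(i) rgtsite:::new_residue_record("GLY", as.character(i),
    data.frame(name = "CA", x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3],
               element = "C"))
  chain <- rgtsite:::new_chain_structure("A", lapply(1:3, mk))
  b <- featurize_chain(chain, c(0L, 0L, 0L), stub_embedding_provider(1, 8))
  expect_equal(nrow(b$edge_feats), 0L)
  expect_equal(nrow(b$edges), 0L)
  cfg <- rgt_config(d = 8, heads = 2, k_pe = 2, local_dim = 8, global_dim = 8,
                    use_local = FALSE, d_ff = 8, classifier_dims = c(4L, 2L, 1L))
  model <- rgt_init(cfg, seed = 1)
  out <- rgt_forward(b, model)
  expect_length(out$p, 3)
  expect_true(all(out$p > 0 & out$p < 1))
})

test_that("mismatched label lengths are rejected with the block named", {
  chain <- generate_chain(6, seed = 61)
  expect_error(featurize_chain(chain, rep(0L, 5)), "labels block")
})

test_that("feature scaling centers the scaled columns and round-trips", {
  b <- tiny_bundle()
  expect_equal(mean(b$physchem[, 22]), 0, tolerance = 1e-9)
  expect_true(all(abs(colMeans(b$edge_feats[, 2:6])) < 1e-9))
  # one-hot block untouched
  expect_true(all(b$physchem[, 1:21] %in% c(0, 1)))
})
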