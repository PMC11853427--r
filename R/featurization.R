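#' Build the residue contact graph of a chain
#'
#' Vertices are residues (their C-alpha atoms); an edge connects two residues
#' whose C-alpha distance is less than or equal to `cutoff` Angstrom
#' (inclusive comparison).
#'
#' @param chain A `chain_structure`, or an N x 3 matrix of C-alpha coordinates.
#' @param cutoff Contact cutoff in Angstrom (default 8).
#' @return A `chain_graph`: list with `n_vertices`, symmetric 0/1 `adjacency`
#'   with zero diagonal, and `edge_list` (matrix of undirected pairs, i < j).
#' @export
build_contact_graph <- function(chain, cutoff = 8.0) {
  stopifnot(cutoff > 0)
  xyz <- if (inherits(chain, "chain_structure")) ca_coords(chain) else as.matrix(chain)
  n <- nrow(xyz)
  if (n == 1L) {
    adj <- matrix(0L, 1, 1)
  } else {
    d <- as.matrix(dist(xyz))
    adj <- (d <= cutoff) * 1L
    diag(adj) <- 0L
    dimnames(adj) <- NULL
  }
  storage.mode(adj) <- "integer"
  el <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  colnames(el) <- c("i", "j")
  structure(list(n_vertices = n, adjacency = adj,
                 edge_list = el[order(el[, 1], el[, 2]), , drop = FALSE]),
            class = "chain_graph")
}

# directed edge index (both directions) plus the position of each edge's
# reverse, needed for symmetrizing learned edge weights
directed_edges <- function(graph) {
  el <- graph$edge_list
  if (nrow(el) == 0L) {
    return(list(edges = matrix(integer(0), 0, 2), rev_index = integer(0)))
  }
  edges <- rbind(el, el[, c(2, 1), drop = FALSE])
  colnames(edges) <- c("i", "j")
  m <- nrow(el)
  rev_index <- c(seq_len(m) + m, seq_len(m))
  list(edges = edges, rev_index = rev_index)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed torsion angle of four points
#'
#' Right-handed (IUPAC) convention, degrees in `[-180, 180]`. Degenerate
#' geometry (collinear triples, coincident points) yields 0 with attribute
#' `defined = FALSE`.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees; attribute `defined` is `FALSE` when undefined.
#' @export
compute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-9 || sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    return(structure(0, defined = FALSE))
  }
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * (b2 / nb2))
  structure(atan2(y, x) * 180 / pi, defined = TRUE)
}

side_chain_atoms <- function(residue) {
  backbone <- c("N", "CA", "C", "O", "OXT")
  residue$atoms[!(residue$atoms$name %in% backbone), , drop = FALSE]
}

orientation_vector <- function(residue) {
  ca <- atom_xyz(residue, "CA")
  sc <- side_chain_atoms(residue)
  if (nrow(sc) > 0L) {
    v <- c(mean(sc$x), mean(sc$y), mean(sc$z)) - ca
  } else {
    cc <- atom_xyz(residue, "C")
    if (is.null(cc)) return(c(0, 0, 0))
    v <- cc - ca
  }
  v
}

# first side-chain gamma-position atom for the chi1 torsion
gamma_atom <- function(residue) {
  for (nm in c("CG", "CG1", "OG", "OG1", "SG", "CB2", "SD")) {
    v <- atom_xyz(residue, nm)
    if (!is.null(v)) return(v)
  }
  NULL
}

dihedral_or_zero <- function(p1, p2, p3, p4) {
  if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4)) return(0)
  as.numeric(compute_dihedral(p1, p2, p3, p4))
}

#' Physicochemical feature vector of one residue
#'
#' The 36 components, in fixed order: one-hot residue type over the 21-letter
#' alphabet (A C D E F G H I K L M N P Q R S T V W Y X), molecular weight,
#' pKa, pKb, pKx, hydrophobicity at pH 2 and pH 7, intra-residue max and min
#' atom distances, CA-O, O-N and N-C backbone distances, and the phi, psi,
#' omega, chi1 torsions (degrees; exactly 0 where geometrically undefined).
#'
#' @param chain A `chain_structure`.
#' @param i Vertex (residue) index, 1-based.
#' @return Named numeric vector of length 36.
#' @export
physchem_vector <- function(chain, i) {
  stopifnot(i >= 1L, i <= chain_length(chain))
  r <- chain$residues[[i]]
  tab <- aa_constant_table()
  onehot <- as.numeric(RESIDUE_ALPHABET == r$one_letter)
  row <- tab[match(r$one_letter, tab$one), ]
  xyz <- residue_coord_matrix(r)
  if (nrow(xyz) >= 2L) {
    dd <- dist(xyz)
    max_d <- max(dd); min_d <- min(dd)
  } else {
    max_d <- 0; min_d <- 0
  }
  pair_dist <- function(a, b) {
    va <- atom_xyz(r, a); vb <- atom_xyz(r, b)
    if (is.null(va) || is.null(vb)) 0 else sqrt(sum((va - vb)^2))
  }
  prev <- if (i > 1L) chain$residues[[i - 1L]] else NULL
  nxt <- if (i < chain_length(chain)) chain$residues[[i + 1L]] else NULL
  phi <- if (is.null(prev)) 0 else
    dihedral_or_zero(atom_xyz(prev, "C"), atom_xyz(r, "N"),
                     atom_xyz(r, "CA"), atom_xyz(r, "C"))
  psi <- if (is.null(nxt)) 0 else
    dihedral_or_zero(atom_xyz(r, "N"), atom_xyz(r, "CA"),
                     atom_xyz(r, "C"), atom_xyz(nxt, "N"))
  omega <- if (is.null(prev)) 0 else
    dihedral_or_zero(atom_xyz(prev, "CA"), atom_xyz(prev, "C"),
                     atom_xyz(r, "N"), atom_xyz(r, "CA"))
  ga <- gamma_atom(r)
  chi1 <- if (is.null(ga)) 0 else
    dihedral_or_zero(atom_xyz(r, "N"), atom_xyz(r, "CA"),
                     atom_xyz(r, "CB"), ga)
  out <- c(onehot, row$mw, row$pka, row$pkb, row$pkx,
           row$hphob_ph2, row$hphob_ph7,
           max_d, min_d,
           pair_dist("CA", "O"), pair_dist("O", "N"), pair_dist("N", "C"),
           phi, psi, omega, chi1)
  names(out) <- c(paste0("aa_", RESIDUE_ALPHABET),
                  "mw", "pka", "pkb", "pkx", "hphob_ph2", "hphob_ph7",
                  "intra_max_dist", "intra_min_dist", "dist_ca_o",
                  "dist_o_n", "dist_n_c", "phi", "psi", "omega", "chi1")
  out
}

#' Physicochemical feature matrix of a chain
#' @param chain A `chain_structure`.
#' @return N x 36 matrix, rows in residue order.
#' @export
physchem_matrix <- function(chain) {
  t(vapply(seq_len(chain_length(chain)),
           function(i) physchem_vector(chain, i), numeric(36)))
}

#' Edge feature vector for a residue pair
#'
#' Six components: edge indicator from the contact graph, C-alpha distance,
#' all-atom centroid distance, minimum and maximum cross-residue atom-pair
#' distances, and the cosine between the two residues' orientation vectors
#' (C-alpha to side-chain centroid; C-alpha to C for glycine-like residues;
#' 0 when either vector has zero norm).
#'
#' @param chain A `chain_structure`.
#' @param i,j Distinct vertex indices (1-based).
#' @param graph The chain's `chain_graph`.
#' @return Named numeric vector of length 6.
#' @export
edge_features <- function(chain, i, j, graph) {
  stopifnot(i != j)
  ri <- chain$residues[[i]]; rj <- chain$residues[[j]]
  cai <- atom_xyz(ri, "CA"); caj <- atom_xyz(rj, "CA")
  xi <- residue_coord_matrix(ri); xj <- residue_coord_matrix(rj)
  ci <- colMeans(xi); cj <- colMeans(xj)
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj)
  d2[d2 < 0] <- 0
  dd <- sqrt(d2)
  vi <- orientation_vector(ri); vj <- orientation_vector(rj)
  ni <- sqrt(sum(vi^2)); nj <- sqrt(sum(vj^2))
  cosv <- if (ni < 1e-9 || nj < 1e-9) 0 else sum(vi * vj) / (ni * nj)
  out <- c(graph$adjacency[i, j],
           sqrt(sum((cai - caj)^2)),
           sqrt(sum((ci - cj)^2)),
           min(dd), max(dd), cosv)
  names(out) <- c("edge_connection", "dist_ca", "dist_centroid",
                  "dist_min", "dist_max", "orient_cosine")
  out
}

edge_feature_matrix <- function(chain, graph, edges) {
  if (nrow(edges) == 0L) {
    return(matrix(numeric(0), 0, 6,
                  dimnames = list(NULL, c("edge_connection", "dist_ca",
                                          "dist_centroid", "dist_min",
                                          "dist_max", "orient_cosine"))))
  }
  t(vapply(seq_len(nrow(edges)), function(e) {
    edge_features(chain, edges[e, 1], edges[e, 2], graph)
  }, numeric(6)))
}

#' Featurize a chain into a model-ready bundle
#'
#' Assembles everything the network consumes for one chain: the contact
#' graph, the integer token sequence for the local encoder, the global
#' embedding block from `provider`, the 36-dim physicochemical block, the
#' 6-dim edge features (stored for both edge directions), and labels.
#' If `encoder` (local-encoder parameters) is supplied, the full assembled
#' vertex feature matrix is materialized into `$vertex_features`
#' (N x 2084 with the default 1024-dim blocks).
#'
#' @param chain A `chain_structure`.
#' @param labels Integer 0/1 vector (one per residue), or `NULL`.
#' @param provider An embedding provider (see [stub_embedding_provider()]).
#' @param encoder Optional local-encoder parameter list.
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `feature_bundle` list.
#' @export
featurize_chain <- function(chain, labels = NULL, provider = NULL,
                            encoder = NULL, cutoff = 8.0) {
  n <- chain_length(chain)
  if (!is.null(labels) && length(labels) != n)
    stop("labels block: length ", length(labels), " != ", n, " residues")
  graph <- build_contact_graph(chain, cutoff)
  de <- directed_edges(graph)
  phys <- physchem_matrix(chain)
  tokens <- label_encode(chain$sequence)
  glob <- if (!is.null(provider)) provider$embed(chain$sequence) else NULL
  if (!is.null(glob) && nrow(glob) != n)
    stop("global block: ", nrow(glob), " rows != ", n, " residues")
  bundle <- structure(list(
    format_version = "rgtsite-bundle-1",
    chain_id = chain$chain_id,
    sequence = chain$sequence,
    author_ids = vapply(chain$residues, function(r) r$author_seq_id, character(1)),
    graph = graph,
    edges = de$edges,
    rev_index = de$rev_index,
    edge_feats = edge_feature_matrix(chain, graph, de$edges),
    tokens = tokens,
    global = glob,
    physchem = phys,
    labels = labels
  ), class = "feature_bundle")
  if (!is.null(encoder)) {
    local <- local_encode(tokens, encoder)
    bundle$vertex_features <- assemble_vertex_features(local, glob, phys)
  }
  bundle
}

#' Save / load a feature bundle container
#' @param bundle A `feature_bundle`.
#' @param path File path.
#' @export
save_bundle <- function(bundle, path) {
  saveRDS(bundle, path, version = 2)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  b <- readRDS(path)
  if (!identical(b$format_version, "rgtsite-bundle-1"))
    stop("unrecognized bundle format: ", b$format_version)
  b
}

# --- feature scaling -------------------------------------------------------
# Non-one-hot physicochemical columns (22:36) and the non-indicator edge
# columns (2:6) are z-scored with statistics from the training split; the
# statistics travel with the model checkpoint.

PHYS_SCALE_COLS <- 22:36
EDGE_SCALE_COLS <- 2:6

#' Compute feature-scaling statistics over training bundles
#' @param bundles List of `feature_bundle`s (the training split).
#' @return Scaling statistics list, to be stored with the model.
#' @export
compute_feature_scaling <- function(bundles) {
  phys <- do.call(rbind, lapply(bundles, `[[`, "physchem"))
  edge <- do.call(rbind, lapply(bundles, `[[`, "edge_feats"))
  safe_sd <- function(x) {
    s <- apply(x, 2, stats::sd)
    s[!is.finite(s) | s < 1e-8] <- 1
    s
  }
  list(
    phys_mean = colMeans(phys[, PHYS_SCALE_COLS, drop = FALSE]),
    phys_sd = safe_sd(phys[, PHYS_SCALE_COLS, drop = FALSE]),
    edge_mean = if (nrow(edge) > 0)
      colMeans(edge[, EDGE_SCALE_COLS, drop = FALSE]) else rep(0, 5),
    edge_sd = if (nrow(edge) > 1)
      safe_sd(edge[, EDGE_SCALE_COLS, drop = FALSE]) else rep(1, 5)
  )
}

#' Apply stored scaling statistics to a bundle
#' @param bundle A `feature_bundle`.
#' @param scaling Output of [compute_feature_scaling()].
#' @return The bundle with scaled `physchem` and `edge_feats`.
#' @export
apply_feature_scaling <- function(bundle, scaling) {
  p <- bundle$physchem
  p[, PHYS_SCALE_COLS] <- sweep(sweep(p[, PHYS_SCALE_COLS, drop = FALSE], 2,
                                      scaling$phys_mean), 2, scaling$phys_sd, "/")
  bundle$physchem <- p
  if (nrow(bundle$edge_feats) > 0) {
    e <- bundle$edge_feats
    e[, EDGE_SCALE_COLS] <- sweep(sweep(e[, EDGE_SCALE_COLS, drop = FALSE], 2,
                                        scaling$edge_mean), 2, scaling$edge_sd, "/")
    bundle$edge_feats <- e
  }
  bundle
}
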