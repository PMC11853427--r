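ONE_TO_THREE <- setNames(names(THREE_TO_ONE), unname(THREE_TO_ONE))

default_confine_radius <- function(n) 3.1 * n^(1 / 3) + 2

rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-6) return(v / nv)
  }
}

normalize3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) c(1, 0, 0) else v / nv
}

# self-avoiding biased step: feasible = >= 3.0 A from all previous CAs
propose_step <- function(x, prev_dir, bias, coords_so_far, step = 3.8,
                         min_sep = 3.0) {
  best <- NULL; best_min <- -Inf
  for (try in 1:60) {
    noise_scale <- 0.8 + 0.1 * try
    dir <- normalize3(0.6 * prev_dir + bias + noise_scale * rnorm(3))
    cand <- x + step * dir
    d2 <- colSums((t(coords_so_far) - cand)^2)
    mind <- sqrt(min(d2))
    if (mind >= min_sep) return(cand)
    if (mind > best_min) { best_min <- mind; best <- cand }
  }
  # guided proposals failed; fall back to uniform directions
  for (try in 1:400) {
    dir <- rand_unit()
    cand <- x + step * dir
    d2 <- colSums((t(coords_so_far) - cand)^2)
    if (sqrt(min(d2)) >= min_sep) return(cand)
  }
  best
}

#' Generate a synthetic protein chain
#'
#' Builds a self-avoiding C-alpha trace with the standard 3.8 Angstrom
#' trans-peptide virtual bond length, confined to a globule-sized sphere, and
#' decorates every residue with idealized backbone atoms (N, C, O) plus a
#' pseudo side chain (CB, and CG for larger residues) so all geometric
#' features are computable. Residue identities are drawn uniformly from the
#' 20 standard amino acids.
#'
#' When a `pocket_center` is supplied the trace revisits the pocket shell in
#' several episodes — emulating how real binding clefts gather distal chain
#' segments — and residues inside the pocket orient their side chains toward
#' the pocket center, as binding-site side chains orient toward the ligand
#' cavity.
#'
#' @param n Number of residues.
#' @param seed Integer seed; same seed reproduces identical coordinates.
#' @param pocket_center Optional 3-vector.
#' @param pocket_radius Pocket radius in Angstrom.
#' @param confine_radius Confinement sphere radius (default scales with
#'   `n^(1/3)`).
#' @return A `chain_structure` (chain id `"A"`).
#' @export
generate_chain <- function(n, seed = 1L, pocket_center = NULL,
                           pocket_radius = 4.5, confine_radius = NULL) {
  stopifnot(n >= 1L)
  set.seed(seed)
  R <- if (is.null(confine_radius)) default_confine_radius(n) else confine_radius
  letters1 <- sample(RESIDUE_ALPHABET[1:20], n, replace = TRUE)
  coords <- matrix(0, n, 3)
  coords[1, ] <- if (is.null(pocket_center)) rand_unit() * R * 0.5 else
    pocket_center + rand_unit() * min(R * 0.6, pocket_radius + 5)
  prev_dir <- rand_unit()
  # pocket visit schedule: a few episodes spread along the sequence
  mode <- "wander"; dwell_left <- 0L; leave_left <- 0L
  visit_at <- integer(0)
  if (!is.null(pocket_center) && n >= 12L) {
    n_visits <- max(2L, min(3L, n %/% 45L))
    visit_at <- sort(unique(pmax(2L, pmin(n - 2L, round(
      (seq_len(n_visits) - 0.5) / n_visits * n + sample(-4:4, n_visits, TRUE))))))
  }
  if (n >= 2L) {
    for (i in 2:n) {
      x <- coords[i - 1L, ]
      if (i %in% visit_at) mode <- "approach"
      bias <- c(0, 0, 0)
      if (mode == "approach") {
        dvec <- pocket_center - x
        if (sqrt(sum(dvec^2)) <= pocket_radius * 0.6) {
          mode <- "dwell"; dwell_left <- 3L
        } else bias <- normalize3(dvec) * 2.5
      }
      if (mode == "dwell") {
        # stay deep in the pocket so all residues of a visit are mutual
        # contact-graph neighbors
        dvec <- pocket_center - x
        dd <- sqrt(sum(dvec^2))
        bias <- if (dd > pocket_radius * 0.7) normalize3(dvec) * 2 else c(0, 0, 0)
        dwell_left <- dwell_left - 1L
        if (dwell_left <= 0L) { mode <- "leave"; leave_left <- 3L }
      } else if (mode == "leave") {
        bias <- bias + normalize3(x - pocket_center) * 1.5
        leave_left <- leave_left - 1L
        if (leave_left <= 0L) mode <- "wander"
      }
      if (mode == "wander") {
        if (sqrt(sum(x^2)) > R) bias <- bias + normalize3(-x) * 2
        else bias <- bias + normalize3(-x) * 0.1
      }
      cand <- propose_step(x, prev_dir, bias, coords[seq_len(i - 1L), , drop = FALSE])
      prev_dir <- normalize3(cand - x)
      coords[i, ] <- cand
    }
  }
  residues <- vector("list", n)
  for (i in seq_len(n)) {
    ca <- coords[i, ]
    e1 <- if (i < n) normalize3(coords[i + 1L, ] - ca)
    else if (n > 1L) normalize3(ca - coords[i - 1L, ]) else c(1, 0, 0)
    ref <- if (i > 1L) normalize3(ca - coords[i - 1L, ]) else c(0, 0, 1)
    e2 <- cross3(e1, ref)
    if (sqrt(sum(e2^2)) < 1e-6) e2 <- cross3(e1, c(0, 1, 0))
    if (sqrt(sum(e2^2)) < 1e-6) e2 <- cross3(e1, c(1, 0, 0))
    e2 <- normalize3(e2)
    e3 <- normalize3(cross3(e1, e2))
    in_pocket <- !is.null(pocket_center) &&
      sqrt(sum((ca - pocket_center)^2)) <= pocket_radius
    sc_dir <- if (in_pocket) normalize3(pocket_center - ca) else rand_unit()
    # pocket-lining side chains converge on the cavity: their tips sit on a
    # tight shell around the pocket center, as around a bound ligand
    sc_tip <- if (in_pocket) pocket_center + 1.1 * normalize3(ca - pocket_center)
    else NULL
    aa1 <- letters1[i]
    atoms <- data.frame(
      name = c("N", "CA", "C", "O"),
      x = c(ca[1] - 1.2 * e1[1] + 0.5 * e2[1], ca[1],
            ca[1] + 1.25 * e1[1] + 0.45 * e2[1],
            ca[1] + 1.25 * e1[1] + 0.45 * e2[1] + 1.23 * e3[1]),
      y = c(ca[2] - 1.2 * e1[2] + 0.5 * e2[2], ca[2],
            ca[2] + 1.25 * e1[2] + 0.45 * e2[2],
            ca[2] + 1.25 * e1[2] + 0.45 * e2[2] + 1.23 * e3[2]),
      z = c(ca[3] - 1.2 * e1[3] + 0.5 * e2[3], ca[3],
            ca[3] + 1.25 * e1[3] + 0.45 * e2[3],
            ca[3] + 1.25 * e1[3] + 0.45 * e2[3] + 1.23 * e3[3]),
      element = c("N", "C", "C", "O"),
      stringsAsFactors = FALSE
    )
    if (aa1 != "G") {
      if (in_pocket) {
        cb <- (ca + sc_tip) / 2
      } else {
        cb <- ca + 2.3 * sc_dir
      }
      atoms <- rbind(atoms, data.frame(name = "CB", x = cb[1], y = cb[2],
                                       z = cb[3], element = "C"))
      if (in_pocket) {
        atoms <- rbind(atoms, data.frame(name = "CG", x = sc_tip[1],
                                         y = sc_tip[2], z = sc_tip[3],
                                         element = "C"))
      } else if (!aa1 %in% c("A", "S", "C")) {
        v2 <- normalize3(sc_dir + 0.7 * e2)
        cg <- cb + 1.52 * v2
        atoms <- rbind(atoms, data.frame(name = "CG", x = cg[1], y = cg[2],
                                         z = cg[3], element = "C"))
      }
    }
    residues[[i]] <- new_residue_record(ONE_TO_THREE[[aa1]], as.character(i), atoms)
  }
  new_chain_structure("A", residues)
}

#' Plant a binding pocket: label residues around a pocket center
#'
#' Labels 1 every residue whose C-alpha lies within `radius` Angstrom of the
#' pocket center. Without an explicit center, a surface point is chosen near
#' a random residue (offset shrinks with the radius so that radius 0 labels
#' exactly the seeding residue).
#'
#' @param chain A `chain_structure`.
#' @param seed Integer seed.
#' @param center Optional 3-vector pocket center.
#' @param radius Pocket radius in Angstrom.
#' @return List with `labels` (0/1 per residue), `center`, and
#'   `seed_residue` (index or NA).
#' @export
plant_pocket <- function(chain, seed = 1L, center = NULL, radius = 4.5) {
  set.seed(seed)
  xyz <- ca_coords(chain)
  seed_res <- NA_integer_
  if (is.null(center)) {
    seed_res <- sample(nrow(xyz), 1L)
    center <- xyz[seed_res, ] + rand_unit() * min(3, radius * 0.5)
  }
  d <- sqrt(colSums((t(xyz) - center)^2))
  labels <- as.integer(d <= radius + 1e-9)
  frac <- mean(labels)
  if (frac > 0.25)
    warning(sprintf("pocket radius %.1f labels %.0f%% of residues; the ",
                    radius, 100 * frac),
            "intended class imbalance is unreachable")
  list(labels = labels, center = center, seed_residue = seed_res)
}

#' Synthetic dataset specification
#'
#' Defaults emulate the desk-scale study conditions: 50 chains of 100-140
#' residues with one planted pocket each, an overall positive fraction of a
#' few percent (bracketing the ~1:22 to ~1:27 imbalance of real
#' binding-site data), and a fixed seed controlling everything.
#'
#' @param n_chains Number of chains.
#' @param length_range Integer range of chain lengths.
#' @param pocket_radius Pocket radius in Angstrom.
#' @param test_fraction Fraction of chains held out as the test split.
#' @param embed_dim Stub embedding dimension.
#' @param seed Integer master seed.
#' @export
synthetic_dataset_spec <- function(n_chains = 50L, length_range = c(100L, 140L),
                                   pocket_radius = 4.5, test_fraction = 0.2,
                                   embed_dim = 1024L, seed = 1L) {
  stopifnot(n_chains >= 2L, length_range[1] >= 12L,
            length_range[2] >= length_range[1], pocket_radius >= 0)
  list(n_chains = as.integer(n_chains),
       length_range = as.integer(length_range),
       pocket_radius = pocket_radius, test_fraction = test_fraction,
       embed_dim = as.integer(embed_dim), seed = as.integer(seed))
}

#' Generate and featurize a synthetic pocket dataset
#'
#' Generates `n_chains` synthetic chains with planted pockets, featurizes
#' each with the deterministic stub embedding provider, and splits chains
#' (disjointly) into train and test sets. When `out_dir` is given, writes
#' per-chain PDB files, label TSVs, feature-bundle containers, and a
#' manifest TSV.
#'
#' @param spec A [synthetic_dataset_spec()].
#' @param out_dir Optional output directory.
#' @return List with `manifest` (data frame), named `bundles`, `train_ids`,
#'   `test_ids`, and the `provider`.
#' @export
make_dataset <- function(spec = synthetic_dataset_spec(), out_dir = NULL) {
  set.seed(spec$seed)
  ns <- sample(spec$length_range[1]:spec$length_range[2], spec$n_chains,
               replace = TRUE)
  provider <- stub_embedding_provider(seed = spec$seed, dim = spec$embed_dim)
  ids <- sprintf("S%03d", seq_len(spec$n_chains))
  bundles <- vector("list", spec$n_chains)
  rows <- vector("list", spec$n_chains)
  for (c in seq_len(spec$n_chains)) {
    seed_c <- (spec$seed * 1009 + c * 7717) %% 2147483000
    set.seed(seed_c)
    R <- default_confine_radius(ns[c])
    center <- rand_unit() * stats::runif(1, 0.1, 0.4) * R
    chain <- generate_chain(ns[c], seed = seed_c + 1L, pocket_center = center,
                            pocket_radius = spec$pocket_radius)
    pk <- plant_pocket(chain, seed = seed_c + 2L, center = center,
                       radius = spec$pocket_radius)
    bundles[[c]] <- featurize_chain(chain, pk$labels, provider)
    rows[[c]] <- data.frame(id = ids[c], chain_id = chain$chain_id,
                            n_residues = ns[c],
                            n_positive = sum(pk$labels),
                            stringsAsFactors = FALSE)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_pdb_chain(chain, file.path(out_dir, paste0(ids[c], ".pdb")))
      write_labels(pk$labels, chain$chain_id,
                   file.path(out_dir, paste0(ids[c], ".labels.tsv")))
      save_bundle(bundles[[c]], file.path(out_dir, paste0(ids[c], ".bundle.rds")))
    }
  }
  names(bundles) <- ids
  set.seed(spec$seed + 2L)
  n_test <- max(1L, round(spec$test_fraction * spec$n_chains))
  test_ix <- sort(sample(spec$n_chains, n_test))
  manifest <- do.call(rbind, rows)
  manifest$split <- ifelse(seq_len(spec$n_chains) %in% test_ix, "test", "train")
  if (!is.null(out_dir)) {
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(manifest = manifest, bundles = bundles,
       train_ids = ids[-test_ix], test_ids = ids[test_ix],
       provider = provider)
}
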