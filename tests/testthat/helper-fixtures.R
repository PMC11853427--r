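# Shared fixtures: built once per test session and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small featurized bundle with labels, low-dim stub embeddings
tiny_bundle <- function() {
  memo("tiny_bundle", {
    chain <- generate_chain(14, seed = 11)
    pk <- suppressWarnings(plant_pocket(chain, seed = 12, radius = 5))
    prov <- stub_embedding_provider(seed = 2, dim = 12)
    b <- featurize_chain(chain, pk$labels, prov)
    apply_feature_scaling(b, compute_feature_scaling(list(b)))
  })
}

tiny_config <- function(...) {
  rgt_config(d = 8, heads = 2, k_pe = 3, local_dim = 12,
             global_dim = 12, dropout = 0, d_ff = 12,
             classifier_dims = c(5L, 3L, 1L), ...)
}

# the full synthetic study dataset, shared between test files
synth_dataset <- function() {
  memo("synth_dataset",
       make_dataset(synthetic_dataset_spec(n_chains = 50, seed = 1)))
}

# hand-written PDB fixtures ------------------------------------------------

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = "C") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resn, chain, resno, x, y, z, occ, 0, element)
}

ala_residue_lines <- function(start_serial, resno, chain = "A", offset = 0) {
  c(pdb_atom_line(start_serial, "N", "ALA", chain, resno, offset, 1.2, 0,
                  element = "N"),
    pdb_atom_line(start_serial + 1, "CA", "ALA", chain, resno, offset, 0, 0),
    pdb_atom_line(start_serial + 2, "C", "ALA", chain, resno, offset + 1.3, 0, 0),
    pdb_atom_line(start_serial + 3, "O", "ALA", chain, resno, offset + 1.3, 1.2, 0,
                  element = "O"))
}

write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "TER", "END"), path)
  path
}

fixture_pdb_3ala <- function() {
  lines <- c(ala_residue_lines(1, 1, offset = 0),
             ala_residue_lines(5, 2, offset = 4),
             ala_residue_lines(9, 3, offset = 8))
  write_fixture_pdb(lines)
}
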