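#' @importFrom stats rnorm runif dist setNames
#' @importFrom utils read.delim write.table modifyList
NULL

new_residue_record <- function(three_letter, author_seq_id, atoms) {
  structure(
    list(
      three_letter = three_letter,
      one_letter = residue_to_one_letter(three_letter),
      author_seq_id = author_seq_id,
      atoms = atoms
    ),
    class = "residue_record"
  )
}

new_chain_structure <- function(chain_id, residues) {
  stopifnot(length(residues) >= 1L)
  seq <- vapply(residues, function(r) r$one_letter, character(1))
  structure(
    list(chain_id = chain_id, residues = residues,
         sequence = paste0(seq, collapse = "")),
    class = "chain_structure"
  )
}

#' @export
print.chain_structure <- function(x, ...) {
  cat(sprintf("<chain_structure> chain %s, %d residues\n  %s\n",
              x$chain_id, length(x$residues), x$sequence))
  invisible(x)
}

#' Number of residues in a chain
#' @param x A `chain_structure`.
#' @export
chain_length <- function(x) length(x$residues)

#' C-alpha coordinate matrix of a chain
#'
#' @param chain A `chain_structure`.
#' @return Numeric matrix, one row per residue, columns x/y/z in Angstrom.
#' @export
ca_coords <- function(chain) {
  out <- t(vapply(chain$residues, function(r) {
    i <- match("CA", r$atoms$name)
    c(r$atoms$x[i], r$atoms$y[i], r$atoms$z[i])
  }, numeric(3)))
  colnames(out) <- c("x", "y", "z")
  out
}

atom_xyz <- function(residue, name) {
  i <- match(name, residue$atoms$name)
  if (is.na(i)) return(NULL)
  c(residue$atoms$x[i], residue$atoms$y[i], residue$atoms$z[i])
}

residue_coord_matrix <- function(residue) {
  cbind(residue$atoms$x, residue$atoms$y, residue$atoms$z)
}

#' Parse one protein chain from a PDB file
#'
#' Reads the requested chain from the first model of a PDB-format file into a
#' validated `chain_structure`. Alternate locations are resolved to the
#' highest-occupancy copy (first occurrence on ties), water and hetero groups
#' are excluded, and residues lacking a C-alpha atom are dropped with a
#' warning since they cannot become graph vertices.
#'
#' @param path Path to a PDB file.
#' @param chain_id Single chain identifier character.
#' @return A `chain_structure` with residues in file (author) order.
#' @export
parse_pdb_chain <- function(path, chain_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.character(chain_id), nchar(chain_id) == 1L)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("parse error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L) {
    if (!any(pdb$atom$chain == chain_id, na.rm = TRUE))
      stop("chain not found: ", chain_id)
    stop("empty chain: no polymer atoms for chain ", chain_id)
  }
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  rid <- paste(at$resno, at$insert, sep = "|")
  residues <- vector("list", length(unique(rid)))
  k <- 0L
  dropped <- character(0)
  for (id in unique(rid)) {
    ra <- at[rid == id, , drop = FALSE]
    # altloc resolution: per atom name keep highest occupancy, first on ties
    keep <- unlist(lapply(split(seq_len(nrow(ra)), ra$elety), function(ix) {
      ix[which.max(ra$o[ix])]
    }), use.names = FALSE)
    ra <- ra[sort(keep), , drop = FALSE]
    author_id <- paste0(ra$resno[1], ifelse(nzchar(ra$insert[1]), ra$insert[1], ""))
    if (!"CA" %in% ra$elety) {
      dropped <- c(dropped, author_id)
      next
    }
    atoms <- data.frame(
      name = ra$elety, x = ra$x, y = ra$y, z = ra$z,
      element = ifelse(is.na(ra$elesy) | !nzchar(ra$elesy),
                       substr(gsub("[0-9]", "", ra$elety), 1, 1), ra$elesy),
      stringsAsFactors = FALSE
    )
    if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
      stop("non-finite coordinates in residue ", author_id)
    k <- k + 1L
    residues[[k]] <- new_residue_record(ra$resid[1], author_id, atoms)
  }
  if (length(dropped) > 0L)
    warning(sprintf("chain %s: dropped %d residue(s) without a CA atom: %s",
                    chain_id, length(dropped), paste(dropped, collapse = ", ")))
  residues <- residues[seq_len(k)]
  if (k == 0L) stop("empty chain: no residues with a CA atom in chain ", chain_id)
  new_chain_structure(chain_id, residues)
}

#' Write a chain to PDB format
#'
#' Minimal v3.3 coordinate-record writer used for synthetic structures and
#' round-trip tests; coordinates are written at the format's 3-decimal
#' precision.
#'
#' @param chain A `chain_structure`.
#' @param path Output file path.
#' @export
write_pdb_chain <- function(chain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (r in chain$residues) {
    resno <- suppressWarnings(as.integer(gsub("[A-Za-z]", "", r$author_seq_id)))
    icode <- gsub("[0-9-]", "", r$author_seq_id)
    if (is.na(resno)) resno <- 0L
    for (a in seq_len(nrow(r$atoms))) {
      serial <- serial + 1L
      nm <- r$atoms$name[a]
      nm_field <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm_field, r$three_letter, chain$chain_id, resno,
        ifelse(nzchar(icode), icode, " "),
        r$atoms$x[a], r$atoms$y[a], r$atoms$z[a], 1.0, 0.0,
        r$atoms$element[a]), con)
    }
  }
  writeLines("TER", con)
  writeLines("END", con)
  invisible(path)
}

#' Extract hetero (ligand) atom coordinates from a PDB file
#'
#' Companion helper for label construction: returns the coordinates of
#' non-water HETATM records, optionally restricted to one residue name
#' (e.g. `"ATP"`).
#'
#' @param path PDB file path.
#' @param resid Optional hetero residue name filter.
#' @return Matrix with columns x/y/z (possibly 0 rows).
#' @export
extract_hetero_atoms <- function(path, resid = NULL) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "HETATM" & !(at$resid %in% c("HOH", "WAT", "DOD")), ,
           drop = FALSE]
  if (!is.null(resid)) at <- at[at$resid == resid, , drop = FALSE]
  m <- cbind(x = at$x, y = at$y, z = at$z)
  m
}

#' Label residues by distance to ligand atoms
#'
#' Marks a residue positive when any of its atoms lies within `cutoff`
#' Angstrom of any ligand atom — the usual operational definition of a
#' binding residue.
#'
#' @param chain A `chain_structure`.
#' @param ligand_coords Matrix of ligand atom coordinates (columns x/y/z).
#' @param cutoff Contact distance in Angstrom.
#' @return Integer vector of 0/1 labels, one per residue.
#' @export
label_by_ligand_contact <- function(chain, ligand_coords, cutoff = 4.5) {
  if (is.null(ligand_coords) || nrow(ligand_coords) == 0L)
    return(integer(chain_length(chain)))
  vapply(chain$residues, function(r) {
    rc <- residue_coord_matrix(r)
    d2 <- outer(rowSums(rc^2), rowSums(ligand_coords^2), "+") -
      2 * rc %*% t(ligand_coords)
    as.integer(any(d2 <= cutoff^2 + 1e-12))
  }, integer(1))
}

#' Load per-residue binary labels from a TSV file
#'
#' Expects columns `chain_id`, `residue_index` (0-based position in the
#' parsed chain) and `label` (0/1). Rows for other chains are ignored.
#'
#' @param path TSV file path.
#' @param chain The `chain_structure` the labels refer to.
#' @return Integer vector of 0/1 labels of length `chain_length(chain)`
#'   (unlabeled positions are 0).
#' @export
load_labels <- function(path, chain) {
  if (!file.exists(path)) stop("labels file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chain_id", "residue_index", "label")
  if (!all(need %in% names(tab)))
    stop("labels file must have columns: ", paste(need, collapse = ", "))
  tab <- tab[tab$chain_id == chain$chain_id, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no labels for chain ", chain$chain_id)
  n <- chain_length(chain)
  bad <- which(tab$residue_index < 0 | tab$residue_index >= n)
  if (length(bad) > 0L)
    stop(sprintf("labels row %d: residue_index %d out of range [0, %d)",
                 bad[1], tab$residue_index[bad[1]], n))
  if (!all(tab$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  labels <- integer(n)
  labels[tab$residue_index + 1L] <- as.integer(tab$label)
  labels
}

#' Write a label TSV for one chain
#' @param labels Integer 0/1 vector.
#' @param chain_id Chain identifier to record.
#' @param path Output path.
#' @export
write_labels <- function(labels, chain_id, path) {
  df <- data.frame(chain_id = chain_id,
                   residue_index = seq_along(labels) - 1L,
                   label = as.integer(labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
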