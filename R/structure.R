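# Structure model: a protein complex is a tibble of atoms (one row per
# atom) with chain / residue / coordinate / radius columns, carrying the
# structure id and source dialect as attributes.

new_structure_complex <- function(atoms, id, source_format) {
  out <- as_tibble(atoms)
  attr(out, "structure_id") <- id
  attr(out, "source_format") <- source_format
  class(out) <- c("structure_complex", class(out))
  out
}

#' @export
print.structure_complex <- function(x, ...) {
  ch <- chain_summary(x)
  cat(sprintf("<structure_complex> %s [%s]: %d chain(s), %d residues, %d atoms\n",
              structure_id(x), source_format(x),
              nrow(ch), sum(ch$n_residues), nrow(x)))
  NextMethod()
}

#' Accessors for structure_complex objects
#'
#' @param x A `structure_complex`.
#' @return `structure_id()` and `source_format()` return length-1 character
#'   vectors; `chain_summary()` a tibble with one row per chain and its
#'   residue count; `chain_sequences()` a tibble of per-residue rows
#'   (`chain`, `pos` 1-based along the chain, `resno`, `icode`, `aa`) plus a
#'   `sequence` string per chain via `attr(, "sequences")`.
#' @export
structure_id <- function(x) attr(x, "structure_id")

#' @rdname structure_id
#' @export
source_format <- function(x) attr(x, "source_format")

#' @rdname structure_id
#' @export
chain_summary <- function(x) {
  x |>
    dplyr::distinct(.data$chain, .data$resno, .data$icode) |>
    dplyr::count(.data$chain, name = "n_residues")
}

#' @rdname structure_id
#' @export
chain_sequences <- function(x) {
  res <- x |>
    dplyr::distinct(.data$chain, .data$resno, .data$icode, .data$aa) |>
    dplyr::group_by(.data$chain) |>
    dplyr::mutate(pos = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("chain", "pos", "resno", "icode", "aa")
  seqs <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(sequence = paste(.data$aa, collapse = ""), .groups = "drop")
  attr(res, "sequences") <- setNames(seqs$sequence, seqs$chain)
  res
}

#' Read a protein complex structure
#'
#' Parses a PDB-format file into a tidy atom table. Only protein chains are
#' kept: waters, non-polymer heteroatoms and hydrogens are dropped. For
#' multi-model (NMR) files only the first model is used. Where alternate
#' locations exist, the highest-occupancy conformer of each atom is kept
#' (ties: first in file order). Nonstandard residues with a standard parent
#' (e.g. selenomethionine) are mapped to the parent amino acid; others are
#' dropped with a message.
#'
#' The `"bead"` format is a coarse-grained dialect of PDB used by the
#' synthetic generator: one C-alpha sphere per residue with a
#' residue-specific radius (see [bead_radii()]). It is read from standard
#' PDB records; the format flag switches the radius assignment and the rASA
#' reference used downstream.
#'
#' @param path Path to a PDB file.
#' @param format `"pdb"` (full atom) or `"bead"` (C-alpha spheres).
#' @param id Structure identifier; defaults to the file base name.
#' @param radii_set Van der Waals radii set for full-atom mode.
#' @return A `structure_complex`: a tibble with columns `chain`, `resno`,
#'   `icode`, `aa`, `atom`, `element`, `x`, `y`, `z`, `occupancy`, `radius`.
#' @export
read_structure <- function(path, format = c("pdb", "bead"), id = NULL,
                           radii_set = "chothia") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("structure file not found: ", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("cannot parse PDB file '", path, "': ",
                                     conditionMessage(e))))
  at <- as_tibble(pdb$atom)
  if (nrow(at) == 0) abort(paste0("no atoms in ", path))

  three2one <- aa_three_to_one()
  at$aa <- unname(three2one[toupper(at$resid)])
  non_protein <- is.na(at$aa)
  dropped <- unique(at$resid[non_protein])
  dropped <- setdiff(dropped, c("HOH", "DOD", "WAT"))
  if (length(dropped) > 0) {
    inform(paste0("dropping non-protein residues: ",
                  paste(dropped, collapse = ", ")))
  }
  at <- at[!non_protein, , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no protein chains in ", path))

  # element: prefer the PDB element column, fall back to first letter of name
  elem <- toupper(trimws(at$elesy %||% ""))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- substr(gsub("[^A-Za-z].*$", "", at$elety[miss]), 1, 1)
  at$element <- elem
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  if (nrow(at) == 0) abort(paste0("no heavy atoms in ", path))

  at$icode <- ifelse(is.na(at$insert) | at$insert == "", "", at$insert)
  at$occupancy <- ifelse(is.na(at$o), 1, at$o)
  at$alt <- ifelse(is.na(at$alt) | at$alt == "", "", at$alt)

  # altloc resolution: keep the highest-occupancy conformer per atom slot,
  # ties broken by file order
  at$.ord <- seq_len(nrow(at))
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$icode, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)

  if (format == "bead") {
    at <- at[at$elety == "CA", , drop = FALSE]
    if (nrow(at) == 0) abort("bead structure has no CA records")
    at$radius <- unname(bead_radii()[at$aa])
  } else {
    at$radius <- assign_vdw_radius(at$element, set = radii_set)
  }

  atoms <- tibble(
    chain = as.character(at$chain), resno = as.integer(at$resno),
    icode = at$icode, aa = at$aa,
    atom = at$elety, element = at$element,
    x = at$x, y = at$y, z = at$z,
    occupancy = at$occupancy, radius = at$radius)
  new_structure_complex(atoms, id %||% sub("\\.[^.]*$", "", basename(path)),
                        source_format = format)
}

#' Write a structure back to PDB format
#'
#' Coordinates are written at the PDB's 3-decimal precision; chain ids and
#' author residue numbering are preserved. Bead structures are serialised as
#' standard PDB files containing only CA records.
#'
#' @param x A `structure_complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  one2three <- setNames(names(aa_three_to_one())[1:20], aa_three_to_one()[1:20])
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(x[, c("x", "y", "z")]))),
    resno = x$resno, chain = x$chain, insert = ifelse(x$icode == "", NA, x$icode),
    resid = unname(one2three[x$aa]), elety = x$atom,
    o = x$occupancy, elesy = x$element)
  invisible(path)
}

#' Extract one chain as a rigid monomer
#'
#' Returns the named chain as a single-chain structure with every atom
#' coordinate unchanged (rigid extraction, no re-minimisation) so that
#' monomer-state and complex-state accessibilities are directly comparable.
#'
#' @param x A `structure_complex`.
#' @param chain_id Chain identifier present in `x`.
#' @return A single-chain `structure_complex`.
#' @export
extract_monomer <- function(x, chain_id) {
  if (!chain_id %in% x$chain) {
    abort(paste0("chain '", chain_id, "' not found; chains present: ",
                 paste(unique(x$chain), collapse = ", ")))
  }
  if (all(x$chain == chain_id)) return(x)   # already a monomer: idempotent
  new_structure_complex(x[x$chain == chain_id, , drop = FALSE],
                        id = paste0(structure_id(x), "_", chain_id),
                        source_format = source_format(x))
}
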