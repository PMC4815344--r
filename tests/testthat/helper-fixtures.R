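# Fixtures are built in code at test time; nothing binary is shipped.

# minimal structure_complex built directly from atom rows
make_bead_structure <- function(df, id = "fix", format = "bead") {
  df <- tibble::as_tibble(df)
  defaults <- list(icode = "", aa = "G", atom = "CA", element = "C",
                   occupancy = 1)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  if (!"radius" %in% names(df)) df$radius <- unname(bead_radii()[df$aa])
  snviface:::new_structure_complex(
    df[, c("chain", "resno", "icode", "aa", "atom", "element",
           "x", "y", "z", "occupancy", "radius")],
    id = id, source_format = format)
}

# a hand-written full-atom PDB exercising waters, hydrogens, altlocs,
# selenomethionine and two chains in contact
write_fullatom_pdb <- function(path) {
  lines <- c(
    "HEADER    SYNTHETIC TEST DIMER",
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  N   ALA A   2       3.300   1.500   0.000  1.00  0.00           N",
    "ATOM      6  CA AALA A   2       4.000   2.700   0.000  0.60  0.00           C",
    "ATOM      7  CA BALA A   2       4.100   2.800   0.100  0.40  0.00           C",
    "ATOM      8  C   ALA A   2       5.500   2.500   0.000  1.00  0.00           C",
    "ATOM      9  O   ALA A   2       6.100   1.500   0.400  1.00  0.00           O",
    "ATOM     10  CB  ALA A   2       3.700   3.600   1.200  1.00  0.00           C",
    "ATOM     11  HB1 ALA A   2       3.900   4.600   1.000  1.00  0.00           H",
    "HETATM   12  N   MSE A   3       6.200   3.500  -0.400  1.00  0.00           N",
    "HETATM   13  CA  MSE A   3       7.600   3.400  -0.600  1.00  0.00           C",
    "HETATM   14 SE   MSE A   3       8.500   5.000  -1.100  1.00  0.00          SE",
    "TER",
    "ATOM     15  N   VAL B   1       4.000   6.000   0.000  1.00  0.00           N",
    "ATOM     16  CA  VAL B   1       4.500   5.000   0.900  1.00  0.00           C",
    "ATOM     17  C   VAL B   1       5.900   5.400   1.400  1.00  0.00           C",
    "ATOM     18  O   VAL B   1       6.300   6.600   1.400  1.00  0.00           O",
    "ATOM     19  N   LEU B   2       6.700   4.400   1.800  1.00  0.00           N",
    "ATOM     20  CA  LEU B   2       8.100   4.600   2.200  1.00  0.00           C",
    "ATOM     21  C   LEU B   2       8.900   3.300   2.300  1.00  0.00           C",
    "ATOM     22  O   LEU B   2       8.400   2.200   2.100  1.00  0.00           O",
    "TER",
    "HETATM   23  O   HOH A 101       2.000   8.000   3.000  1.00  0.00           O",
    "HETATM   24  O   HOH B 102       9.000   8.000   3.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}

# two chains of touching beads: every bead of each 3x3 face pair loses ASA
make_contact_dimer <- function(n_side = 3, spacing = 5.5, gap = 6.0,
                               aa = "A") {
  grid <- expand.grid(x = 0:(n_side - 1), y = 0:(n_side - 1)) * spacing
  a <- tibble::tibble(chain = "A", resno = seq_len(nrow(grid)),
                      x = 0, y = grid$x, z = grid$y, aa = aa)
  b <- tibble::tibble(chain = "B", resno = seq_len(nrow(grid)),
                      x = gap, y = grid$x, z = grid$y, aa = aa)
  make_bead_structure(rbind(a, b), id = "contact")
}

# deterministic classified-sites + mapped-variants pair for stats tests
make_sites_variants <- function(seed = 7, n_complexes = 4,
                                residues_per_chain = 50,
                                base_rates = c(rare = 0.2, intermediate = 0.05,
                                               common = 0.05),
                                theta = NULL) {
  cfg <- sim_config(seed = seed, n_complexes = n_complexes,
                    residues_per_chain = residues_per_chain,
                    base_rates = base_rates, theta = theta)
  sites <- dplyr::bind_rows(lapply(seq_len(n_complexes), function(i) {
    g <- generate_complex(cfg, complex_index = i, n_points = 240)
    dplyr::mutate(g$labels, structure_id = sprintf("sim%03d", i), .before = 1)
  }))
  gv <- generate_variants(sites, cfg)
  truth_v <- gv$truth$variants
  mapped <- dplyr::mutate(gv$variants,
                          structure_id = truth_v$structure_id,
                          chain = truth_v$chain, resno = truth_v$resno,
                          icode = truth_v$icode, region = truth_v$region_true,
                          mapped = TRUE)
  list(sites = sites, variants = mapped, truth = gv$truth, config = cfg)
}
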