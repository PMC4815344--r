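# Reference tables: van der Waals radii, maximum per-residue ASA, amino acid
# codes, residue volumes (bead radii), and the standard genetic code.

#' Amino acid one/three letter code tables
#'
#' @return `aa_three_to_one()` returns a named character vector mapping
#'   three-letter residue names (upper case) to one-letter codes, including
#'   common nonstandard residues that have a standard parent (MSE -> M,
#'   SEC -> C, PYL -> K, etc.).
#' @export
aa_three_to_one <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
    # nonstandard residues with a standard parent
    MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
    TPO = "T", PTR = "Y", CSO = "C", MLY = "K", M3L = "K")
}

#' @rdname aa_three_to_one
#' @export
aa_one_letter <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Van der Waals radii
#'
#' Element-wise van der Waals radii in Angstrom. The default set follows the
#' Chothia values used by classic accessibility programs (C 1.87, N 1.65,
#' O 1.40, S 1.85); unknown elements fall back to 1.80.
#'
#' @param set Radii set name; only `"chothia"` is shipped.
#' @return Named numeric vector, Angstrom, by element symbol.
#' @export
vdw_radii <- function(set = "chothia") {
  set <- match.arg(set)
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
    SE = 1.90, FE = 1.47, ZN = 1.39, MG = 1.73, CA = 1.74)
}

# assign a radius per atom from its element symbol
assign_vdw_radius <- function(element, set = "chothia", default = 1.80) {
  tab <- vdw_radii(set)
  r <- unname(tab[toupper(element)])
  r[is.na(r)] <- default
  r
}

#' Maximum per-residue accessible surface area references
#'
#' Per-amino-acid maximum ASA used to normalise absolute ASA into relative
#' ASA (rASA). Two full-atom sets are shipped: `"naccess"`, the extended
#' Ala-X-Ala tripeptide values distributed with the NACCESS program, and
#' `"tien"`, the theoretical maxima of Tien et al. (2013). The choice shifts
#' rASA and therefore where the 0.25 buried/exposed boundary falls.
#'
#' @param set `"naccess"` (default) or `"tien"`.
#' @return Named numeric vector (Angstrom squared) over the 20 standard
#'   one-letter amino acid codes.
#' @export
max_asa_reference <- function(set = c("naccess", "tien")) {
  set <- match.arg(set)
  if (set == "naccess") {
    c(A = 107.95, R = 238.76, N = 143.94, D = 140.39, C = 134.28,
      Q = 178.50, E = 172.25, G = 80.10, H = 182.88, I = 175.12,
      L = 178.63, K = 200.81, M = 194.15, F = 199.48, P = 136.13,
      S = 116.50, T = 139.27, W = 249.36, Y = 212.76, V = 151.44)
  } else {
    c(A = 129, R = 274, N = 195, D = 193, C = 167,
      Q = 225, E = 223, G = 104, H = 224, I = 197,
      L = 201, K = 236, M = 224, F = 240, P = 159,
      S = 155, T = 172, W = 285, Y = 263, V = 174)
  }
}

#' Bead radii per amino acid
#'
#' Single-sphere residue radii for the coarse-grained "bead" structure
#' dialect (one sphere per residue at the C-alpha position). Radii are
#' volume-equivalent spheres from mean residue volumes, so bulky residues
#' get larger beads.
#'
#' @return Named numeric vector, Angstrom, over the 20 one-letter codes.
#' @export
bead_radii <- function() {
  vol <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
           Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
           L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
           S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)
  (3 * vol / (4 * pi))^(1 / 3)
}

# In bead mode the natural maximum is the isolated bead's own probe-expanded
# sphere area, so a fully exposed bead has rASA = 1 by construction.
max_asa_bead <- function(probe_radius = 1.4) {
  r <- bead_radii() + probe_radius
  4 * pi * r^2
}

#' The standard genetic code and single-nucleotide amino acid changes
#'
#' @return `genetic_code()` returns a named character vector codon -> amino
#'   acid (one letter, `*` for stop). `single_nt_substitutions()` returns a
#'   tibble of every ordered codon pair that differs at exactly one position
#'   and changes the encoded amino acid (stop codons excluded), with the
#'   nucleotide change and whether it is a transition.
#' @export
genetic_code <- function() {
  c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
}

#' @rdname genetic_code
#' @export
single_nt_substitutions <- function() {
  code <- genetic_code()
  codons <- names(code)
  nts <- c("A", "C", "G", "T")
  res <- list()
  for (from in codons) {
    aa_from <- code[[from]]
    if (aa_from == "*") next
    f <- strsplit(from, "")[[1]]
    for (pos in 1:3) {
      for (alt in setdiff(nts, f[pos])) {
        t <- f
        t[pos] <- alt
        to <- paste(t, collapse = "")
        aa_to <- code[[to]]
        if (aa_to == "*" || aa_to == aa_from) next
        res[[length(res) + 1]] <- list(
          codon_from = from, codon_to = to, pos = pos,
          nt_ref = f[pos], nt_alt = alt,
          aa_ref = aa_from, aa_alt = aa_to)
      }
    }
  }
  out <- dplyr::bind_rows(res)
  out$transition <- is_transition(out$nt_ref, out$nt_alt)
  as_tibble(out)
}

is_transition <- function(nt_ref, nt_alt) {
  purine <- c("A", "G")
  (nt_ref %in% purine) == (nt_alt %in% purine)
}

#' Typical globular-protein amino acid composition
#'
#' Default composition weights used by the synthetic generator when sampling
#' residue identities; roughly the Swiss-Prot background frequencies. An
#' arginine multiplier lets simulations emulate the arginine excess of
#' interface rims and of CpG-driven variant spectra.
#'
#' @param arg_multiplier Multiplies the arginine weight before normalisation.
#' @return Named numeric vector of weights summing to 1.
#' @export
aa_composition_default <- function(arg_multiplier = 1) {
  w <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4,
         Q = 3.9, E = 6.7, G = 7.1, H = 2.3, I = 5.9,
         L = 9.7, K = 5.8, M = 2.4, F = 3.9, P = 4.7,
         S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  w["R"] <- w["R"] * arg_multiplier
  w / sum(w)
}
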