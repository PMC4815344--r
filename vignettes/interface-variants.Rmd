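---
title: "Methods: mapping allele frequency onto protein-protein interface regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping allele frequency onto protein-protein interface regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snviface)
```

## The question the package answers

Nonsynonymous single-nucleotide variants (SNVs) change one amino acid of a
protein. Whether such a change matters often depends on *where* the residue
sits: a substitution buried in a protein-protein interface can break an
obligate dimer, while the same substitution on the solvent-exposed rim is
usually tolerated. Population allele frequency carries complementary
information: common variants have survived selection, rare variants may not
have been tested by it yet. `snviface` implements the machinery to put these
two axes together: classify every residue of a protein complex into one of
five structural regions, map a table of nonsynonymous SNVs onto those
residues, stratify by minor allele frequency (MAF), and test whether
variants avoid particular regions.

## Residue classification

For every residue we compute the accessible surface area (ASA) twice: in
the intact complex, and in its own chain extracted rigidly (the "monomer"
state; coordinates are never re-minimised, so the two states differ only by
the presence of the partner chains). ASA is normalised to relative ASA,

rASA = ASA / maxASA(amino acid),

with the extended Ala-X-Ala tripeptide maxima as the default reference
(`max_asa_reference("naccess")`; the theoretical maxima of Tien et al. 2013
are available as `"tien"`, and the choice shifts where the exposure
boundary falls). The change on binding is ΔrASA = rASA(monomer) −
rASA(complex). The five-way label follows the Levy interface taxonomy:

| label | rule |
|---|---|
| interface (any) | ΔrASA > tol |
| support | interface and rASA(monomer) < 0.25 |
| rim | interface and rASA(complex) > 0.25 |
| core | interface, exposed in monomer, buried in complex |
| interior | non-interface, rASA(complex) < 0.25 |
| surface | non-interface, otherwise |

Two numerical conventions are ours rather than forced by the definitions:
the buried/exposed cutoff is strict (rASA exactly 0.25 counts as exposed;
the published definitions state only strict inequalities), and "ΔrASA > 0"
is implemented as ΔrASA > tol with tol = 1e-6, absorbing floating-point
noise from the two ASA evaluations. With tol = 0, residues far from any
interface could flip label on the last bit of a coordinate.

For complexes of more than two chains, the complex state is all chains
together, so a chain's interface is taken against the union of its
partners.

## The ASA engine

ASA is computed by the Shrake-Rupley method: each atom's sphere is inflated
by the probe radius (default 1.4 Å, water), covered with a deterministic
golden-angle spiral of `n_points` test points, and the atom contributes the
fraction of points not occluded by any neighbouring inflated sphere, times
its inflated-sphere area. Residue ASA sums its atoms. The spiral point set
is identical for every run at a given `n_points`, so results are
reproducible to the bit; there is no Monte Carlo component.

Defaults: probe 1.4 Å, `n_points = 960`, Chothia-style van der Waals radii
(C 1.87, N 1.65, O 1.40, S 1.85 Å). An isolated atom's ASA equals the
analytic area 4π(r + 1.4)² exactly, because every point of the spiral is
accessible. At 960 points, per-residue full-atom ASA agrees with a
10,000-point evaluation to well under 2%. In the coarse-grained bead mode
(below), a residue is a single sphere, so its ASA is quantised in units of
its sphere area / n_points; per-bead agreement is then limited to a few
percent for partially buried beads, while the structure total still agrees
to well under 1%. This is a property of representing a residue by one
sphere, not of the integration scheme.

Occlusion checks use a neighbour prefilter (atoms whose inflated spheres
can intersect); the kernel is compiled (Rcpp) because the simulation
studies classify tens of thousands of residues.

## Variant tables, binning and mapping

Variant input is a TSV with protein identifier, 1-based protein position,
mutating and mutated amino acid, reference and alternate nucleotide, and
MAF. Synonymous rows and MAFs outside 0..1 are rejected and counted, never
silently dropped. MAF bins follow the usual convention: rare (MAF ≤ 1%),
intermediate (1% < MAF ≤ 5%), common (> 5%), with boundaries belonging to
the lower bin.

Mapping onto a structure chain goes through a global Needleman-Wunsch
alignment of the query protein sequence against the chain sequence
(match +1, mismatch −1, gap open 5, gap extend 1; all configurable).
Identity is identical columns over aligned non-gap columns. Chains below
95% identity are not used — at that identity regime a full dynamic
programming alignment is exact and fast, so no heuristic search is needed.
A variant maps only when its position lands in an aligned column *and* the
chain residue equals the variant's mutating amino acid; otherwise it is
retained with a reason code (`gap`, `mismatch`, `out_of_range`). The
amino-acid agreement check guards against numbering drift between sequence
databases and author residue numbering.

Protein redundancy is removed at 50% identity by greedy clustering seeded
on the longest chain (ties broken lexicographically), which makes the
retained set independent of input order. When a protein aligns to several
retained chains (homodimers), its variants are counted once per retained
chain; how duplicate subunits should be counted is genuinely open, so the
per-variant table keeps every mapping and downstream counts can be
deduplicated by the caller.

## Contingency tables and tests

`tabulate_regions()` builds the region × variant-class table: one row per
MAF bin, a derived all-variants row, and a non-variant row (sites minus
variant sites per region), with the interface margin core + support + rim.
Three Pearson χ² tests (no continuity correction, p from the upper tail at
full double precision) are wired as `stats_from_counts()`:

1. variant vs non-variant sites × {core, support, rim};
2. rare vs common variants × {core, support, rim};
3. interface vs surface sites × {rare, intermediate, common}.

The continuity correction is deliberately off: these are large 2×3 tables
where Yates' correction is both unnecessary and would change the reported
p-values. Fisher's exact test (two-sided, by summing hypergeometric
probabilities no larger than the observed table's) is provided for 2×2
substitution-class comparisons. No multiple-testing correction is applied
anywhere; the tests are reported raw.

The mutating-residue spectrum is normalised per stratum as a relative
frequency: the amino acid's percentage among a stratum's variant sites
divided by its percentage among the region group's strictly non-variant
sites (a site carrying any variant is excluded from the denominator).
Core and support are pooled into one region group because their spectra
are alike; "nonrare" pools intermediate and common. `rf_correlation()`
compares two strata by Pearson correlation across amino acids, with an
exclusion list (typically arginine, whose CpG-driven excess otherwise
dominates the correlation).

One arithmetic caveat in the published counts this package ships: the
non-rare surface fraction computes to 361/8894 = 4.06%, which rounds to
4.1% at one decimal although the source prints 4.0%; similarly the printed
"67%" of common variants on rims is 36/55 = 65.5%. The package reports the
computed values.

## The synthetic generator

Real inputs (curated complexes plus an exome-scale variant table) cannot be
shipped, so the generator builds toy data with known truth and the same
file dialects, and every stage is exercised on it.

*Structures.* A chain is a compact serpentine walk on a jittered cubic
lattice of beads, one sphere per residue at the Cα position with a
volume-equivalent radius per amino acid (2.4-3.8 Å). Lattice spacing is
5.5 Å: at tighter spacings almost every bead is buried, while at 5.5 Å
exposed and buried residues are roughly balanced, as in globular proteins.
The `contact_dimer` geometry places the second chain flush against the
first chain's face (facing layers one mean bead diameter apart), which
produces all three interface classes; `separated_dimer` puts the chains
100 Å apart and guarantees an empty interface. Region truth labels are
produced by running the package's own classifier on the generated
coordinates, so the truth cannot drift from the code path under test. Bead
structures are serialised as ordinary CA-only PDB files; in bead mode the
rASA reference is the isolated bead's inflated-sphere area, so an
unoccluded bead has rASA exactly 1.

*Variants.* Each site independently carries at most one variant: bin b
with probability base_rate(b) × θ(region, b). The defaults emulate an
exome-sequencing frequency spectrum at toy scale — base rates
(0.053, 0.0009, 0.0009) give ≈5.5% of sites carrying a variant, ≈96.7% of
variants rare — and θ ≡ 1 (no depletion); depletion studies set
θ(region, bin) < 1 explicitly. The mutating amino acid is the site's
residue; a codon is drawn uniformly among its codons and a
single-nucleotide nonsynonymous change from that codon is drawn with
transitions weighted κ against 1 per transversion (default κ = 4.9, i.e.
about 71% transitions among sampled changes; κ = ∞ restricts to
transitions where one exists). Every emitted substitution is therefore
reachable by one nucleotide change under the standard genetic code. MAF is
log-uniform on (1e-4, 0.01] for rare variants and uniform on (0.01, 0.05]
and (0.05, 0.5] for the other bins, so bin boundaries are respected
exactly. A configurable arginine multiplier in the residue composition
stands in for CpG hypermutability; explicit dinucleotide context is not
modelled.

Everything is deterministic in the configuration seed: the same
`sim_config()` yields byte-identical PDB files, variant tables and truth.

*What the generator does not emulate.* No population genetics (no
coalescent, no selection), no realistic fold geometry, no correlated
variant placement, no sequencing error. Passing tests on synthetic data
demonstrate that the pipeline measures what the generator put in — region
labels, depletion factors, substitution spectra — not that any biological
conclusion transfers to real structures.

*Parameter recovery.* `recover_depletion()` estimates, per region and bin,
the odds ratio of carrying a variant relative to surface sites, with a
Wald 95% CI on the log odds ratio. For the small per-site rates used, the
odds ratio estimates the rate ratio θ(region, b)/θ(surface, b). Empty
cells are reported as non-estimable. The calibration study in the test
suite uses 40 complexes of 2 × 250 residues (20,000 sites), a true
θ(core, common)/θ(surface, common) of 0.3, per-bin base rates
(0.05, 0.01, 0.05) — chosen for adequate counts in the rarest cell (about
17 expected core common variants per replicate) — and 20 variant
replicates over a fixed site panel; the neutral goodness-of-fit study uses
about 5,000 sites. These sizes keep the full suite in the minutes range on
one CPU while leaving enough events for the interval calibration to be
meaningful.

## Degenerate inputs and edge conventions

* Multi-model (NMR) files: first model only; alternate locations: the
  highest-occupancy conformer, ties broken by file order. Neither choice
  is dictated by the source definitions; both are stated here as package
  conventions.
* Nonstandard residues with a standard parent (MSE, SEC, ...) are mapped
  to the parent; others are dropped with a message. Waters, non-polymer
  heteroatoms and hydrogens are excluded before any ASA computation.
* Single-chain input to `classify_complex()` is an error (an interface is
  undefined), as is an all-zero margin in a χ² table at the operation
  level; the pipeline wrapper reports such a test as NA rather than
  aborting the run.
* A mapped variant always agrees with its chain residue; the invariant is
  enforced at mapping time, not assumed.
* An amino acid present among variants but absent from the non-variant
  denominator has an undefined relative frequency: the scalar operation
  errors, the per-stratum table keeps the row with `rel_freq = NA` and
  lists the amino acid in an attribute.

## Validating against a real structure

The classifier runs unchanged on any full-atom PDB complex. A documented
check on a real case: soluble epoxide hydrolase (EPHX2) is an obligate
homodimer whose common R287Q variant (MAF 10.2%) sits in the dimer
interface. With a local copy of PDB entry 4j03:

```r
x <- read_structure("4j03.pdb")
lab <- classify_complex(x)
dplyr::filter(lab, resno == 287)
```

Arg287 is expected to classify as interface core with ΔASA of roughly
60 Å² (tolerance of order 10% against values computed with other ASA
programs and radii sets). This check needs the downloaded structure and is
not part of the test suite.

## Known limitations

* No biological-assembly inference: the input file is trusted to be the
  functional complex. No structure repair, no protonation, no mmCIF input.
* ASA values differ from slice-based programs (NACCESS) at the level of a
  few percent depending on radii and integration scheme; rASA-based labels
  are robust to this for residues away from the 0.25 boundary, but
  residues near the boundary can flip between implementations.
* The mutated (post-substitution) residue spectrum is reported as raw
  counts only; normalising it properly would require the codon-level
  substitution opportunity structure, which is out of scope.
* Redundancy removal is greedy, not optimal clustering; with the 50%
  threshold and near-identical chains this matches what heavier tools do
  on such inputs.
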