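# snviface

Where do human genetic variants sit on protein–protein interfaces, and
does the answer depend on how common the variant is?

`snviface` is an R package for structural bioinformaticians and
statistical geneticists who want to relate nonsynonymous single-nucleotide
variants (SNVs) to the three-dimensional architecture of protein
complexes. It classifies every residue of a complex into one of five
structural regions from solvent accessibility, maps variant tables onto
structure chains by sequence alignment, stratifies variants by minor
allele frequency (MAF), and provides the contingency-table statistics,
relative-frequency normalisation and substitution typing needed to test
whether variants avoid functionally critical regions.

## The model

For each residue, accessible surface area (ASA) is computed by a
deterministic Shrake–Rupley method in two states: the intact complex and
the residue's own chain extracted rigidly (the *monomer* state).
Normalising by the residue type's maximum ASA gives relative ASA (rASA),
and the change on binding is ΔrASA = rASA_monomer − rASA_complex. The
five-way classification follows the Levy interface taxonomy:

- **interface** residues have ΔrASA > 0; among them
  - **support**: buried already in the monomer (rASA_monomer < 0.25),
  - **rim**: still exposed in the complex (rASA_complex > 0.25),
  - **core**: exposed in the monomer, buried in the complex;
- non-interface residues are **interior** (rASA_complex < 0.25) or
  **surface**.

Variants are binned as rare (MAF ≤ 1%), intermediate (1% < MAF ≤ 5%) or
common (MAF > 5%), mapped onto chains through global Needleman–Wunsch
alignment (≥95% identity, with the chain residue required to equal the
variant's mutating amino acid), and chains are de-duplicated at 50%
identity. Region × variant-class tables are tested by Pearson χ² (no
continuity correction); per-amino-acid substitution spectra are compared
across strata via the relative frequency, the ratio of an amino acid's
percentage among variant sites to its percentage among strictly
non-variant sites.

A fully seeded synthetic-data module generates coarse-grained bead
complexes with genuine interfaces and exome-like variant tables
(rare-dominated MAF spectrum, codon-consistent substitutions with an
elevated transition rate), with ground-truth region labels and depletion
parameters, so the entire pipeline is testable end to end and depletion
estimates can be calibrated against known truth.

## Worked example

The packaged table of published per-region variant counts (20,305 mapped
variants on 1,343 complexes) reproduces the headline statistics without
any external data:

```r
library(snviface)
tab <- published_region_counts()
stats_from_counts(tab)
#> # A tibble: 3 × 5
#>   test                                      method      statistic    df  p.value
#>   <chr>                                     <chr>           <dbl> <int>    <dbl>
#> 1 variant_vs_nonvariant_by_interface_region Pearson ch…      72.0     2 2.36e-16
#> 2 rare_vs_common_by_interface_region        Pearson ch…      11.9     2 2.67e- 3
#> 3 interface_vs_surface_by_maf_bin           Pearson ch…      16.1     2 3.22e- 4
```

Variant sites are distributed differently from non-variant sites across
the interface (p ≈ 2.4e-16): variants favour the rim (43.1% of interface
variants vs 37.4% of non-variant interface sites) over core and support.
The effect strengthens with allele frequency (rare vs common, p ≈ 0.003),
and non-rare variants are rarer on interfaces than on ordinary surface
(p ≈ 0.0003): the non-rare fraction is 3.6% on rims but only 2.0% on the
pooled core+support, which behaves like the protein interior.

```r
round(region_ratios(tab)[c("pct_core", "pct_rim", "pct_support",
                           "pct_nonrare_rim", "pct_nonrare_core_support")], 2)
#>                 pct_core                  pct_rim              pct_support
#>                    36.87                    43.13                    20.00
#>          pct_nonrare_rim pct_nonrare_core_support
#>                     3.59                     1.97
```

The same machinery runs end to end on synthetic complexes:

```r
cfg <- sim_config(seed = 7, n_complexes = 2, residues_per_chain = 50,
                  base_rates = c(rare = 0.2, intermediate = 0.04, common = 0.04))
gens <- lapply(1:2, function(i) generate_complex(cfg, complex_index = i))
v <- generate_variants(dplyr::bind_rows(lapply(gens, function(g)
  dplyr::mutate(g$labels, structure_id = attr(g$labels, "structure_id"),
                .before = 1))), cfg)$variants
run_pipeline(lapply(gens, `[[`, "structure"), v)
#> <pipeline_report> 200 sites, 60/60 variants mapped
#> # A tibble: 5 × 8
#>   class         core support   rim interface interior surface total
#>   <chr>        <dbl>   <dbl> <dbl>     <dbl>    <dbl>   <dbl> <dbl>
#> 1 rare             3       5     4        12       16      17    45
#> 2 intermediate     2       0     0         2        3       4     9
#> 3 common           0       1     1         2        2       2     6
#> 4 all_variants     5       6     5        16       21      23    60
#> 5 nonvariant      13      10    11        34       60      46   140
```

Every generated variant maps back to its site, the contingency rows
conserve the input counts, and with the neutral default θ ≡ 1 none of the
three tests finds structure (all p > 0.7 here, as they should on data with
no depletion built in).

Classified sites and relative-frequency tables have `autoplot()` methods;
test objects have broom-style `tidy()`/`glance()` methods.

## Documentation

The methods vignette (`vignettes/interface-variants.Rmd`) describes the
classification rules and their boundary conventions, the ASA engine and
its convergence behaviour, the mapping and redundancy rules, what the
synthetic generator does and does not emulate, and known limitations.
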