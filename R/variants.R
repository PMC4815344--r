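# Variant tables: parsing, MAF binning, and substitution typing.

variant_required_cols <- c("protein_id", "position", "aa_ref", "aa_alt",
                           "nt_ref", "nt_alt", "maf")

#' Read a nonsynonymous variant table
#'
#' Reads a TSV with columns `protein_id`, `position` (1-based protein
#' coordinate), `aa_ref`/`aa_alt` (mutating/mutated amino acid, one
#' letter), `nt_ref`/`nt_alt` (A/C/G/T), `maf`. Synonymous rows
#' (`aa_ref == aa_alt`) and rows with MAF outside 0..1 are rejected and
#' counted; the MAF bin is attached to every retained row.
#'
#' @param path TSV file path.
#' @param maf_percent If `TRUE`, input MAF values are percentages and are
#'   divided by 100.
#' @return A `variant_table` tibble with an added `maf_bin` column and an
#'   attribute `rejected` holding the counts of dropped rows by reason.
#' @export
read_variants <- function(path, maf_percent = FALSE) {
  v <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(variant_required_cols, names(v))
  if (length(missing) > 0) {
    abort(paste0("variant table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  v$position <- as.integer(v$position)
  v$maf <- as.numeric(v$maf)
  if (maf_percent) v$maf <- v$maf / 100
  as_variant_table(v)
}

#' @rdname read_variants
#' @param v A data frame with the variant-table columns.
#' @export
as_variant_table <- function(v) {
  v <- as_tibble(v)
  bad_maf <- is.na(v$maf) | v$maf < 0 | v$maf > 1
  synonymous <- !bad_maf & v$aa_ref == v$aa_alt
  rejected <- c(bad_maf = sum(bad_maf), synonymous = sum(synonymous))
  if (sum(rejected) > 0) {
    inform(sprintf("rejected %d row(s): %d synonymous, %d with MAF outside 0..1",
                   sum(rejected), rejected[["synonymous"]], rejected[["bad_maf"]]))
  }
  v <- v[!bad_maf & !synonymous, , drop = FALSE]
  v$maf_bin <- bin_maf(v$maf)
  attr(v, "rejected") <- rejected
  class(v) <- c("variant_table", class(v))
  v
}

#' Bin minor allele frequencies
#'
#' Rare: MAF <= 1 percent; intermediate: 1 < MAF <= 5 percent; common:
#' MAF > 5 percent. Boundaries belong to the lower bin, so 0.01 is rare and
#' 0.05 is intermediate.
#'
#' @param maf Numeric vector of allele frequencies as fractions between 0 and 1.
#' @return Factor with levels `rare`, `intermediate`, `common`.
#' @export
bin_maf <- function(maf) {
  if (any(is.na(maf) | maf < 0 | maf > 1)) {
    abort("MAF values must lie between 0 and 1")
  }
  cut(maf, breaks = c(-Inf, 0.01, 0.05, Inf),
      labels = c("rare", "intermediate", "common"), right = TRUE)
}

#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions exchange purine for purine (A/G) or pyrimidine for
#' pyrimidine (C/T); the other eight ordered changes are transversions.
#'
#' @param nt_ref,nt_alt Reference and alternate bases, in A/C/G/T
#'   (vectorised; must differ elementwise).
#' @return Character vector, `"transition"` or `"transversion"`.
#' @export
classify_nt_substitution <- function(nt_ref, nt_alt) {
  ok <- nt_ref %in% c("A", "C", "G", "T") & nt_alt %in% c("A", "C", "G", "T")
  if (!all(ok)) abort("nucleotides must be one of A, C, G, T")
  if (any(nt_ref == nt_alt)) abort("nt_ref and nt_alt must differ")
  ifelse(is_transition(nt_ref, nt_alt), "transition", "transversion")
}

#' Classify an amino acid substitution by beta-branching
#'
#' Substitutions within the beta-branched hydrophobic pair Ile/Val are
#' reachable by a transition and are generally mild; exchanges between
#' Ile/Val and Leu require a transversion. Everything else is `other`.
#'
#' @param aa_ref,aa_alt One-letter amino acids (vectorised, must differ).
#' @return Character vector over `c("within_beta_branched",
#'   "beta_to_nonbeta", "other")`.
#' @export
classify_branched_substitution <- function(aa_ref, aa_alt) {
  if (any(aa_ref == aa_alt)) abort("aa_ref and aa_alt must differ")
  bb <- c("I", "V")
  dplyr::case_when(
    aa_ref %in% bb & aa_alt %in% bb ~ "within_beta_branched",
    (aa_ref %in% bb & aa_alt == "L") | (aa_ref == "L" & aa_alt %in% bb) ~
      "beta_to_nonbeta",
    .default = "other")
}

#' Transition/transversion composition of a variant table
#'
#' @param variants A `variant_table` (or any tibble with `nt_ref`,
#'   `nt_alt`), optionally grouped beforehand.
#' @param by Optional column names to stratify by (e.g. `"maf_bin"` or
#'   `"region"`).
#' @return Tibble of counts and the transition fraction per stratum.
#' @export
tstv_summary <- function(variants, by = NULL) {
  out <- variants |>
    dplyr::mutate(change = classify_nt_substitution(.data$nt_ref, .data$nt_alt)) |>
    dplyr::count(dplyr::across(dplyr::all_of(c(by, "change")))) |>
    tidyr::pivot_wider(names_from = "change", values_from = "n",
                       values_fill = 0L)
  for (cc in c("transition", "transversion")) {
    if (!cc %in% names(out)) out[[cc]] <- 0L
  }
  dplyr::mutate(out,
    ts_fraction = .data$transition / (.data$transition + .data$transversion))
}
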