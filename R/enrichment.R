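# Region x variant-class contingency tables, the chi-squared / Fisher
# tests run on them, relative frequencies of mutating amino acids, and the
# cross-region correlation of those relative frequencies.

region_groups <- function() {
  list(interface = c("core", "support", "rim"),
       non_interface = c("interior", "surface"))
}

#' Build the region-by-variant-class contingency table
#'
#' Counts variant sites per structural region and MAF bin, plus the
#' non-variant sites (total sites minus variant sites) per region. One
#' variant site is one mapped variant row; the non-variant row is derived
#' from the per-region site totals of the classified structures.
#'
#' @param sites A `residue_accessibility` table (rows from one or more
#'   complexes bound together) or a tibble with a `region` column, one row
#'   per site.
#' @param variants Mapped variant rows carrying `region` and `maf_bin`.
#' @return A `region_contingency` tibble with rows `rare`, `intermediate`,
#'   `common`, `all_variants`, `nonvariant` and columns `core`, `support`,
#'   `rim`, `interface`, `interior`, `surface`, `total`.
#' @export
tabulate_regions <- function(sites, variants) {
  if (any(is.na(variants$region))) {
    abort("every variant must carry a region; filter to mapped variants first")
  }
  regions <- region_levels()
  variants <- dplyr::mutate(variants, maf_bin = factor(
    as.character(.data$maf_bin), c("rare", "intermediate", "common")))
  vt <- variants |>
    dplyr::count(.data$maf_bin, .data$region) |>
    tidyr::complete(maf_bin = factor(c("rare", "intermediate", "common"),
                                     c("rare", "intermediate", "common")),
                    region = regions, fill = list(n = 0L))
  site_totals <- sites |>
    dplyr::count(.data$region) |>
    tidyr::complete(region = regions, fill = list(n = 0L))
  variant_totals <- vt |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  nonvariant <- site_totals$n[match(regions, site_totals$region)] -
    variant_totals$n[match(regions, variant_totals$region)]
  if (any(nonvariant < 0)) {
    abort("more variant sites than sites in a region; inputs inconsistent")
  }

  wide <- vt |>
    tidyr::pivot_wider(names_from = "region", values_from = "n") |>
    dplyr::rename(class = "maf_bin") |>
    dplyr::mutate(class = as.character(.data$class))
  all_row <- tibble(class = "all_variants",
                    !!!as.list(colSums(wide[, regions])))
  nv_row <- tibble(class = "nonvariant", !!!as.list(setNames(nonvariant, regions)))
  region_counts(dplyr::bind_rows(wide, all_row, nv_row))
}

#' Construct a region contingency table from raw counts
#'
#' Accepts a tibble with a `class` column (`rare`, `intermediate`,
#' `common`, optionally `all_variants`, and `nonvariant`) and the five leaf
#' region columns; derives the `all_variants` row (when absent), the
#' `interface` margin (core + support + rim) and the row `total`.
#'
#' @param counts Tibble of non-negative integer counts.
#' @return A `region_contingency` tibble.
#' @export
region_counts <- function(counts) {
  leaf <- c("core", "support", "rim", "interior", "surface")
  stopifnot(all(c("class", leaf) %in% names(counts)))
  counts <- as_tibble(counts)[, c("class", leaf)]
  if (!"all_variants" %in% counts$class) {
    bins <- counts[counts$class %in% c("rare", "intermediate", "common"), ]
    counts <- dplyr::bind_rows(
      counts,
      tibble(class = "all_variants", !!!as.list(colSums(bins[, leaf]))))
  }
  counts <- counts |>
    dplyr::mutate(interface = .data$core + .data$support + .data$rim,
                  total = .data$interface + .data$interior + .data$surface) |>
    dplyr::select("class", "core", "support", "rim", "interface",
                  "interior", "surface", "total")
  ord <- c("rare", "intermediate", "common", "all_variants", "nonvariant")
  counts <- counts[order(match(counts$class, ord)), , drop = FALSE]
  class(counts) <- c("region_contingency", class(counts))
  counts
}

#' Read a region-counts table from TSV
#'
#' @param path TSV with a `class` column and the five leaf region columns.
#' @return A `region_contingency` tibble.
#' @export
read_region_counts <- function(path) {
  region_counts(readr::read_tsv(path, show_col_types = FALSE))
}

#' The published variant-distribution counts
#'
#' Loads the packaged copy of the published per-region variant counts
#' (20,305 mapped variants on 1,343 complexes) so the headline statistics
#' can be recomputed without any external data.
#'
#' @return A `region_contingency` tibble.
#' @export
published_region_counts <- function() {
  read_region_counts(system.file("extdata", "table1_counts.tsv",
                                 package = "snviface", mustWork = TRUE))
}

rc_cell <- function(tab, class, cols) {
  unlist(tab[tab$class == class, cols, drop = FALSE])
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared without continuity correction on an r x c count
#' matrix; p-value from the upper tail of the chi-squared distribution at
#' full double precision.
#'
#' @param table Matrix (or coercible) of non-negative counts, at least 2x2.
#' @param test_name Label carried into the result.
#' @return An `iface_test` object with `statistic`, `df`, `p_value`.
#' @export
chi2_independence <- function(table, test_name = "chi-squared") {
  m <- as.matrix(table)
  if (nrow(m) < 2 || ncol(m) < 2) abort("need at least a 2x2 table")
  exp_counts <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(exp_counts <= 0)) {
    abort("degenerate table: at least one expected count is zero")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  new_iface_test(test_name, "Pearson chi-squared",
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, table = m)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities of all tables
#' with the observed margins that are no more probable than the observed
#' one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param test_name Label carried into the result.
#' @return An `iface_test` object (`df` is `NA`).
#' @export
fisher_exact_2x2 <- function(table, test_name = "fisher-exact") {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2))) abort("need a 2x2 table")
  ht <- fisher.test(m)
  new_iface_test(test_name, "Fisher's exact",
                 statistic = unname(ht$estimate), df = NA_real_,
                 p_value = ht$p.value, table = m)
}

new_iface_test <- function(test_name, method, statistic, df, p_value, table) {
  structure(list(test_name = test_name, method = method,
                 statistic = statistic, df = df, p_value = p_value,
                 table = table),
            class = "iface_test")
}

#' @export
print.iface_test <- function(x, ...) {
  cat(sprintf("<iface_test> %s (%s)\n  statistic = %.6g, df = %s, p = %s\n",
              x$test_name, x$method, x$statistic,
              ifelse(is.na(x$df), "-", format(x$df)),
              format_p(x$p_value)))
  invisible(x)
}

# two significant figures at or above 1e-3, scientific below
format_p <- function(p) {
  ifelse(p >= 1e-3, signif(p, 2), sprintf("%.1e", p))
}

#' @export
tidy.iface_test <- function(x, ...) {
  tibble(test = x$test_name, method = x$method, statistic = x$statistic,
         df = x$df, p.value = x$p_value)
}

#' @export
glance.iface_test <- function(x, ...) tidy(x)

#' The three headline tests on a region contingency table
#'
#' Runs, on any `region_contingency` table: (1) variant vs non-variant
#' sites across the three interface regions (core/support/rim); (2) rare vs
#' common variants across the three interface regions; (3) interface vs
#' surface sites across the three MAF bins. All are Pearson chi-squared
#' without continuity correction.
#'
#' @param tab A `region_contingency` tibble.
#' @return Tibble with one row per test (`test`, `statistic`, `df`,
#'   `p.value`), also retrievable as `iface_test` objects via
#'   `attr(, "tests")`.
#' @export
stats_from_counts <- function(tab) {
  iface <- c("core", "support", "rim")
  t1 <- rbind(variant = rc_cell(tab, "all_variants", iface),
              nonvariant = rc_cell(tab, "nonvariant", iface))
  t2 <- rbind(rare = rc_cell(tab, "rare", iface),
              common = rc_cell(tab, "common", iface))
  t3 <- rbind(interface = c(rc_cell(tab, "rare", "interface"),
                            rc_cell(tab, "intermediate", "interface"),
                            rc_cell(tab, "common", "interface")),
              surface = c(rc_cell(tab, "rare", "surface"),
                          rc_cell(tab, "intermediate", "surface"),
                          rc_cell(tab, "common", "surface")))
  colnames(t3) <- c("rare", "intermediate", "common")
  tabs <- list(variant_vs_nonvariant_by_interface_region = t1,
               rare_vs_common_by_interface_region = t2,
               interface_vs_surface_by_maf_bin = t3)
  # on sparse inputs a sub-table can be degenerate (an all-zero margin);
  # report the test as not computable rather than failing the whole run
  tests <- purrr::imap(tabs, function(m, nm) {
    tryCatch(chi2_independence(m, nm), error = function(e) {
      new_iface_test(nm, "Pearson chi-squared", NA_real_, NA_real_,
                     NA_real_, m)
    })
  })
  out <- purrr::map(tests, tidy) |> dplyr::bind_rows()
  attr(out, "tests") <- tests
  out
}

#' Printed summary ratios of a region contingency table
#'
#' Recomputes the headline percentages: the core/rim/support split of
#' interface variants; the rare/intermediate/common split of interface
#' variants; and the nonrare (intermediate + common) variant fraction on
#' surfaces, rims, interiors and pooled core+support — each as a percentage
#' of the variants in that region.
#'
#' @param tab A `region_contingency` tibble.
#' @return Named numeric vector of percentages (full precision; round for
#'   display).
#' @export
region_ratios <- function(tab) {
  v <- function(class, cols) sum(rc_cell(tab, class, cols))
  iface_v <- v("all_variants", "interface")
  nonrare <- function(cols) {
    100 * (v("intermediate", cols) + v("common", cols)) / v("all_variants", cols)
  }
  c(pct_core = 100 * v("all_variants", "core") / iface_v,
    pct_rim = 100 * v("all_variants", "rim") / iface_v,
    pct_support = 100 * v("all_variants", "support") / iface_v,
    pct_interface_rare = 100 * v("rare", "interface") / iface_v,
    pct_interface_intermediate = 100 * v("intermediate", "interface") / iface_v,
    pct_interface_common = 100 * v("common", "interface") / iface_v,
    pct_nonrare_surface = nonrare("surface"),
    pct_nonrare_rim = nonrare("rim"),
    pct_nonrare_interior = nonrare("interior"),
    pct_nonrare_interface = nonrare("interface"),
    pct_nonrare_core_support = nonrare(c("core", "support")))
}

#' Relative frequency of mutating amino acids
#'
#' For each amino acid, the ratio of its percentage among variant sites to
#' its percentage among non-variant sites; 1 means the amino acid mutates
#' in proportion to its abundance.
#'
#' @param variant_counts,nonvariant_counts Named integer vectors of
#'   per-amino-acid site counts.
#' @param allow_undefined If `FALSE` (default), an amino acid present among
#'   variants but absent from non-variant sites makes the ratio undefined
#'   and raises an error; if `TRUE`, such amino acids are kept with
#'   `rel_freq = NA` and listed in the `undefined` attribute.
#' @return Tibble with `aa`, `pct_variant`, `pct_nonvariant`, `rel_freq`.
#' @export
relative_frequency <- function(variant_counts, nonvariant_counts,
                               allow_undefined = FALSE) {
  aa <- union(names(variant_counts), names(nonvariant_counts))
  v <- setNames(rep(0, length(aa)), aa)
  v[names(variant_counts)] <- variant_counts
  n <- setNames(rep(0, length(aa)), aa)
  n[names(nonvariant_counts)] <- nonvariant_counts
  undefined <- aa[n == 0 & v > 0]
  if (length(undefined) > 0 && !allow_undefined) {
    abort(paste0("relative frequency undefined (amino acid absent from ",
                 "non-variant sites): ", paste(undefined, collapse = ", ")))
  }
  pv <- 100 * v / sum(v)
  pn <- 100 * n / sum(n)
  out <- tibble(aa = aa, pct_variant = unname(pv), pct_nonvariant = unname(pn),
                rel_freq = unname(ifelse(pn > 0, pv / pn, NA_real_)))
  attr(out, "undefined") <- undefined
  out
}

#' Relative-frequency tables per (region group, MAF group) stratum
#'
#' Computes, for the strata rim vs pooled core+support crossed with rare vs
#' nonrare (intermediate + common), the relative frequency of each mutating
#' amino acid: its percentage among that stratum's variant sites divided by
#' its percentage among the region group's non-variant sites. Core and
#' support are pooled because their substitution spectra are alike;
#' non-variant sites are sites of the region group carrying no variant of
#' any MAF bin.
#'
#' @param sites Classified sites with `region` and `aa` (rows across
#'   complexes; add `structure_id`/`chain`/`resno` for site identity).
#' @param variants Mapped variants with `region`, `maf_bin`, `aa_ref` and
#'   the mapped site key columns (`structure_id`, `chain`, `resno`,
#'   `icode`).
#' @return A `relfreq_table` tibble: `region_group`, `maf_group`, `aa`,
#'   `pct_variant`, `pct_nonvariant`, `rel_freq`.
#' @export
relative_frequency_table <- function(sites, variants) {
  grp <- function(region) {
    dplyr::case_when(region == "rim" ~ "rim",
                     region %in% c("core", "support") ~ "core_support",
                     .default = NA_character_)
  }
  key_cols <- intersect(c("structure_id", "chain", "resno", "icode"),
                        intersect(names(sites), names(variants)))
  if (length(key_cols) == 0) abort("no shared site key columns")
  v <- variants |>
    dplyr::filter(!is.na(.data$region)) |>
    dplyr::mutate(region_group = grp(.data$region),
                  maf_group = ifelse(.data$maf_bin == "rare", "rare", "nonrare")) |>
    dplyr::filter(!is.na(.data$region_group))
  s <- sites |>
    dplyr::mutate(region_group = grp(.data$region)) |>
    dplyr::filter(!is.na(.data$region_group)) |>
    dplyr::anti_join(v, by = key_cols)      # strictly non-variant sites

  strata <- tidyr::expand_grid(region_group = c("rim", "core_support"),
                               maf_group = c("rare", "nonrare"))
  out <- purrr::pmap(strata, function(region_group, maf_group) {
    vc <- v |>
      dplyr::filter(.data$region_group == !!region_group,
                    .data$maf_group == !!maf_group) |>
      dplyr::count(.data$aa_ref)
    nc <- s |>
      dplyr::filter(.data$region_group == !!region_group) |>
      dplyr::count(.data$aa)
    if (nrow(vc) == 0 || nrow(nc) == 0) return(NULL)
    relative_frequency(setNames(vc$n, vc$aa_ref), setNames(nc$n, nc$aa),
                       allow_undefined = TRUE) |>
      dplyr::mutate(region_group = region_group, maf_group = maf_group,
                    .before = 1)
  })
  undefined <- purrr::map(purrr::compact(out), ~attr(.x, "undefined"))
  out <- dplyr::bind_rows(out)
  attr(out, "undefined") <- sort(unique(unlist(undefined)))
  class(out) <- c("relfreq_table", class(out))
  out
}

#' Correlation of relative frequencies between two strata
#'
#' Pearson correlation of per-amino-acid relative frequencies across two
#' strata, over the amino acids present in both, optionally excluding some
#' (e.g. arginine, whose CpG-driven excess dominates).
#'
#' @param rf_a,rf_b Named numeric vectors of relative frequencies by amino
#'   acid.
#' @param exclude Amino acids to drop before computing.
#' @return Pearson correlation coefficient.
#' @export
rf_correlation <- function(rf_a, rf_b, exclude = NULL) {
  shared <- setdiff(intersect(names(rf_a), names(rf_b)), exclude)
  if (length(shared) < 3) {
    abort("need at least 3 shared amino acids to correlate")
  }
  cor(rf_a[shared], rf_b[shared])
}

#' Plot relative frequencies of two strata against each other
#'
#' Scatter of per-amino-acid relative frequencies, rim vs core+support, one
#' panel per MAF group, with amino acid letters as labels.
#'
#' @param object A `relfreq_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relfreq_table <- function(object, ...) {
  wide <- object |>
    dplyr::select("region_group", "maf_group", "aa", "rel_freq") |>
    tidyr::pivot_wider(names_from = "region_group", values_from = "rel_freq")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$rim, y = .data$core_support,
                                     label = .data$aa)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_text() +
    ggplot2::facet_wrap(~maf_group) +
    ggplot2::labs(x = "relative frequency, rim",
                  y = "relative frequency, core + support") +
    ggplot2::theme_minimal()
}
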