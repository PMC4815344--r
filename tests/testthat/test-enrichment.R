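# independent oracles -------------------------------------------------------

# Pearson chi-squared by direct expansion of sum((O-E)^2 / E)
chi2_oracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

# two-sided Fisher p by exhaustive enumeration over fixed margins
fisher_oracle_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("chi-squared independence matches the hand-expanded Pearson formula", {
  m <- matrix(c(12, 7, 5, 15), 2, 2)
  res <- chi2_independence(m)
  orc <- chi2_oracle(m)
  expect_equal(res$statistic, orc$stat, tolerance = 1e-12)
  expect_equal(res$df, orc$df)
  expect_equal(res$p_value, orc$p, tolerance = 1e-12)
  # proportional rows: no association at all
  flat <- chi2_independence(matrix(c(10, 30, 20, 60), 2, 2))
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)
  expect_error(chi2_independence(matrix(c(0, 0, 1, 2), 2, 2)), "degenerate")
  expect_error(chi2_independence(matrix(1:3, 1)), "2x2")
})

test_that("chi-squared p equals the upper-tail distribution on random tables", {
  set.seed(42)
  for (i in 1:20) {
    nr <- sample(2:3, 1)
    m <- matrix(rpois(nr * 2, lambda = 30) + 1, nr, 2)
    res <- chi2_independence(m)
    orc <- chi2_oracle(m)
    expect_equal(res$statistic, orc$stat, tolerance = 1e-10)
    expect_equal(res$p_value, orc$p, tolerance = 1e-10)
  }
})

test_that("Fisher's exact two-sided p matches exhaustive enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  m <- matrix(c(3, 0, 0, 3), 2)
  expect_equal(fisher_exact_2x2(m)$p_value, fisher_oracle_2x2(m),
               tolerance = 1e-9)
  m2 <- matrix(c(8, 2, 3, 9), 2)
  expect_equal(fisher_exact_2x2(m2)$p_value, fisher_oracle_2x2(m2),
               tolerance = 1e-9)
  # invariance under transposition and row/column swaps
  expect_equal(fisher_exact_2x2(t(m2))$p_value,
               fisher_exact_2x2(m2)$p_value)
  expect_equal(fisher_exact_2x2(m2[2:1, ])$p_value,
               fisher_exact_2x2(m2)$p_value)
  expect_equal(fisher_exact_2x2(m2[, 2:1])$p_value,
               fisher_exact_2x2(m2)$p_value)
})

test_that("tidy and glance return one-row summaries for test objects", {
  td <- tidy(chi2_independence(matrix(c(12, 7, 5, 15), 2), "demo"))
  expect_s3_class(td, "tbl_df")
  expect_equal(td$test, "demo")
  expect_named(td, c("test", "method", "statistic", "df", "p.value"))
  expect_equal(nrow(glance(fisher_exact_2x2(matrix(c(3, 1, 2, 4), 2)))), 1)
})

test_that("region tabulation conserves totals and reproduces the margins", {
  sv <- make_sites_variants(seed = 11, n_complexes = 2)
  tab <- tabulate_regions(sv$sites, sv$variants)
  # every variant lands in exactly one cell of its bin row
  expect_equal(sum(rc <- tab$total[tab$class == "all_variants"]),
               nrow(sv$variants))
  # rows add: rare + intermediate + common = all_variants
  leaf <- c("core", "support", "rim", "interior", "surface")
  bins <- tab[tab$class %in% c("rare", "intermediate", "common"), leaf]
  expect_equal(colSums(bins),
               unlist(tab[tab$class == "all_variants", leaf]))
  # interface margin = core + support + rim
  expect_equal(tab$interface, tab$core + tab$support + tab$rim)
  # variant + nonvariant sites = all sites per region
  expect_equal(
    unlist(tab[tab$class == "all_variants", leaf]) +
      unlist(tab[tab$class == "nonvariant", leaf]),
    setNames(as.double(table(factor(sv$sites$region, leaf))), leaf))
})

test_that("zero variants give a pure site table", {
  sv <- make_sites_variants(seed = 11, n_complexes = 1)
  tab <- tabulate_regions(sv$sites, sv$variants[0, ])
  expect_equal(tab$total[tab$class == "all_variants"], 0)
  expect_equal(tab$total[tab$class == "nonvariant"], nrow(sv$sites))
  expect_error(tabulate_regions(sv$sites,
                                dplyr::mutate(sv$variants, region = NA)),
               "region")
})

test_that("the packaged published counts reproduce every printed marginal", {
  tab <- published_region_counts()
  expect_equal(tab$interface[tab$class == "all_variants"], 4204)
  expect_equal(tab$interface[tab$class == "nonvariant"], 71678)
  expect_equal(tab$total[tab$class == "all_variants"], 20305)
  expect_equal(tab$total[tab$class == "nonvariant"], 347354)
  expect_equal(unlist(tab[tab$class == "all_variants",
                          c("core", "support", "rim")]),
               c(core = 1550, support = 841, rim = 1813))
})

test_that("relative frequencies reproduce direct arithmetic and the weighted-mean identity", {
  # 2 of 10 variant sites vs 10 of 100 nonvariant sites -> 20% / 10% = 2
  rf <- relative_frequency(c(A = 2, C = 8), c(A = 10, C = 90))
  expect_equal(rf$rel_freq[rf$aa == "A"], 2.0)
  # identical compositions give 1 everywhere
  rf1 <- relative_frequency(c(A = 5, C = 15), c(A = 50, C = 150))
  expect_equal(rf1$rel_freq, c(1, 1))
  # sum over aa of rel_freq * nonvariant percentage is 100
  set.seed(9)
  v <- setNames(rpois(20, 5) + 1, aa_one_letter())
  n <- setNames(rpois(20, 50) + 1, aa_one_letter())
  rf2 <- relative_frequency(v, n)
  expect_equal(sum(rf2$rel_freq * rf2$pct_nonvariant), 100)
  expect_error(relative_frequency(c(A = 1, W = 1), c(A = 10)), "W")
})

test_that("rf_correlation is affine-invariant and supports exclusions", {
  rf <- setNames(c(3.25, 1.2, 0.8, 0.5, 1.9), c("R", "A", "C", "D", "E"))
  expect_equal(rf_correlation(rf, 2 * rf), 1.0)
  expect_equal(rf_correlation(rf, -rf + 4), -1.0)
  # matches the direct sum formula
  set.seed(3)
  b <- rf + rnorm(5, sd = 0.3)
  direct <- sum((rf - mean(rf)) * (b - mean(b))) /
    sqrt(sum((rf - mean(rf))^2) * sum((b - mean(b))^2))
  expect_equal(rf_correlation(rf, b), direct, tolerance = 1e-12)
  # exclusion drops the point before computing
  expect_equal(rf_correlation(rf, b, exclude = "R"),
               cor(rf[-1], b[-1]))
  expect_error(rf_correlation(rf[1:3], b[1:2]), "3")
})

test_that("per-stratum relative frequency tables use strictly non-variant denominators", {
  sv <- make_sites_variants(seed = 13, n_complexes = 4)
  rft <- relative_frequency_table(sv$sites, sv$variants)
  expect_true(all(rft$region_group %in% c("rim", "core_support")))
  expect_true(all(rft$maf_group %in% c("rare", "nonrare")))
  # percentages sum to 100 within each stratum
  sums <- rft |>
    dplyr::group_by(region_group, maf_group) |>
    dplyr::summarise(v = sum(pct_variant), n = sum(pct_nonvariant),
                     .groups = "drop")
  expect_equal(sums$v, rep(100, nrow(sums)))
  expect_equal(sums$n, rep(100, nrow(sums)))
  # ratios are non-negative; undefined ones (aa absent from the
  # non-variant denominator) are NA and reported, not dropped
  expect_true(all(rft$rel_freq >= 0 | is.na(rft$rel_freq)))
  expect_true(all(rft$aa[is.na(rft$rel_freq) & rft$pct_variant > 0] %in%
                    attr(rft, "undefined")))
})

test_that("the headline tests read the expected sub-tables", {
  tab <- published_region_counts()
  res <- stats_from_counts(tab)
  tests <- attr(res, "tests")
  # variant vs nonvariant x core/support/rim
  expect_equal(unname(tests[[1]]$table["variant", ]), c(1550, 841, 1813))
  expect_equal(unname(tests[[2]]$table["common", ]), c(14, 5, 36))
  expect_equal(unname(tests[[3]]$table["interface", ]), c(4092, 57, 55))
  expect_equal(res$df, rep(2L, 3))
})
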