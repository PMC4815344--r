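test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, residues_per_chain = 27)
  g1 <- generate_complex(cfg, n_points = 240)
  g2 <- generate_complex(cfg, n_points = 240)
  expect_identical(as.data.frame(g1$structure), as.data.frame(g2$structure))
  p1 <- withr::local_tempfile(fileext = ".pdb")
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(g1$structure, p1)
  write_structure(g2$structure, p2)
  expect_identical(readLines(p1), readLines(p2))
  v1 <- generate_variants(g1$labels, cfg)
  v2 <- generate_variants(g2$labels, cfg)
  expect_identical(as.data.frame(v1$variants), as.data.frame(v2$variants))
})

test_that("contact dimers have a populated interface; separated dimers none", {
  g <- generate_complex(sim_config(seed = 1, residues_per_chain = 50))
  counts <- table(factor(g$labels$region, levels = c("core", "rim", "support",
                                                     "interior", "surface")))
  expect_true(all(counts[c("core", "rim", "support")] > 0))
  expect_gte(sum(g$labels$delta_rasa > 1e-6), 0.1 * nrow(g$labels))
  expect_true(any(g$labels$region[g$labels$chain == "A"] == "core"))
  expect_true(any(g$labels$region[g$labels$chain == "B"] == "core"))
})

test_that("emitted substitutions are single-nucleotide consistent with the genetic code", {
  sv <- make_sites_variants(seed = 21, n_complexes = 2)
  v <- sv$variants
  subs <- single_nt_substitutions()
  key <- paste(subs$aa_ref, subs$aa_alt, subs$nt_ref, subs$nt_alt)
  expect_true(all(paste(v$aa_ref, v$aa_alt, v$nt_ref, v$nt_alt) %in% key))
  # the mutating residue is the site's residue
  site_aa <- sv$sites$aa[match(paste(v$structure_id, v$chain, v$resno),
                               paste(sv$sites$structure_id, sv$sites$chain,
                                     sv$sites$resno))]
  expect_equal(v$aa_ref, site_aa)
})

test_that("MAF values respect their bin boundaries exactly", {
  sv <- make_sites_variants(seed = 22, n_complexes = 3)
  v <- sv$variants
  tr <- sv$truth$variants
  expect_equal(as.character(v$maf_bin), tr$maf_bin_true)
  expect_true(all(v$maf[v$maf_bin == "rare"] <= 0.01))
  expect_true(all(v$maf[v$maf_bin == "intermediate"] > 0.01 &
                    v$maf[v$maf_bin == "intermediate"] <= 0.05))
  expect_true(all(v$maf[v$maf_bin == "common"] > 0.05 &
                    v$maf[v$maf_bin == "common"] <= 0.5))
})

test_that("kappa controls the transition fraction up to its limit", {
  g <- generate_complex(sim_config(seed = 30, residues_per_chain = 64),
                        n_points = 240)
  cfg_inf <- sim_config(seed = 30, kappa = Inf,
                        base_rates = c(rare = 0.9, intermediate = 0,
                                       common = 0))
  v_inf <- generate_variants(g$labels, cfg_inf)$variants
  expect_gt(nrow(v_inf), 50)
  expect_true(all(classify_nt_substitution(v_inf$nt_ref, v_inf$nt_alt) ==
                    "transition"))
  # kappa = 4.9 targets about 71% transitions among available changes
  cfg_k <- sim_config(seed = 31, kappa = 4.9,
                      base_rates = c(rare = 0.9, intermediate = 0, common = 0))
  v_k <- generate_variants(g$labels, cfg_k)$variants
  ts <- mean(classify_nt_substitution(v_k$nt_ref, v_k$nt_alt) == "transition")
  expect_gt(ts, 0.55)
  expect_lt(ts, 0.9)
})

test_that("theta = 0 silences a stratum; theta = 1 matches site composition", {
  th <- matrix(1, 5, 3, dimnames = list(
    c("core", "rim", "support", "interior", "surface"),
    c("rare", "intermediate", "common")))
  th["core", "common"] <- 0
  sv <- make_sites_variants(seed = 23, n_complexes = 3,
                            base_rates = c(rare = 0.2, intermediate = 0.05,
                                           common = 0.3),
                            theta = th)
  v <- sv$variants
  expect_equal(sum(v$maf_bin == "common" & v$region == "core"), 0)
  expect_gt(sum(v$maf_bin == "common"), 0)

  # neutral theta: variant regions follow site regions (chi-squared GOF)
  sv1 <- make_sites_variants(seed = 24, n_complexes = 13,
                             residues_per_chain = 195,
                             base_rates = c(rare = 0.15, intermediate = 0.05,
                                            common = 0.05))
  v1 <- sv1$variants
  site_p <- prop.table(table(sv1$sites$region))
  obs <- table(factor(v1$region, names(site_p)))
  gof <- suppressWarnings(chisq.test(obs, p = as.numeric(site_p)))
  expect_gt(gof$p.value, 0.01)
})

test_that("depletion recovery is deterministic and centred on the truth", {
  th <- matrix(1, 5, 3, dimnames = list(
    c("core", "rim", "support", "interior", "surface"),
    c("rare", "intermediate", "common")))
  th["core", "common"] <- 0.3
  sv <- make_sites_variants(seed = 25, n_complexes = 20,
                            residues_per_chain = 125,
                            base_rates = c(rare = 0.1, intermediate = 0.02,
                                           common = 0.1),
                            theta = th)
  est <- recover_depletion(sv$sites, sv$variants)
  est2 <- recover_depletion(sv$sites, sv$variants)
  expect_identical(est, est2)
  row <- est[est$region == "core" & est$maf_bin == "common", ]
  expect_true(row$estimable)
  expect_true(row$conf_low < 0.3 * 1.6 && row$conf_high > 0.3 / 1.6)
  # neutral strata have intervals around 1
  neutral <- est[est$region == "rim" & est$maf_bin == "rare", ]
  expect_true(neutral$conf_low < 1 && neutral$conf_high > 1)
  # empty cells are reported, not fatal
  empty <- recover_depletion(sv$sites[sv$sites$region != "support", ],
                             sv$variants[sv$variants$region != "support", ])
  expect_false(any(empty$estimable[empty$region == "support"]))
})
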