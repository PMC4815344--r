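test_that("identical sequences align with identity 100 and the identity map", {
  s <- paste(sample(aa_one_letter(), 50, replace = TRUE), collapse = "")
  aln <- align_and_map(s, s)
  expect_equal(attr(aln, "identity"), 100)
  expect_equal(aln$query_pos, 1:50)
  expect_equal(aln$chain_pos, 1:50)
})

test_that("a single deletion shifts downstream positions by one", {
  chain <- "ACDEFGHIKL"
  query <- "ACDEGHIKL"    # F (position 5 of chain) deleted
  aln <- align_and_map(query, chain, min_identity = 80)
  expect_false(is.null(aln))
  # positions before the gap map 1:1; after it with offset +1
  before <- aln[aln$query_pos <= 4, ]
  after <- aln[aln$query_pos >= 5, ]
  expect_equal(before$chain_pos, before$query_pos)
  expect_equal(after$chain_pos, after$query_pos + 1L)
  # mapping is injective and order-preserving
  expect_false(any(duplicated(aln$chain_pos)))
  expect_true(all(diff(aln$chain_pos) > 0))
})

test_that("alignments below the identity threshold are discarded", {
  a <- strrep("A", 30)
  b <- paste0(strrep("A", 15), strrep("W", 15))
  expect_null(align_and_map(a, b, min_identity = 95))
  expect_equal(pairwise_identity(a, b), 50)
  expect_error(align_and_map("", a), "nonempty")
})

test_that("variants map only onto aligned, sequence-consistent residues", {
  x <- make_contact_dimer(aa = "A")
  lab <- classify_complex(x, n_points = 240)
  chain_seq <- strrep("A", 9)
  v <- tibble::tibble(
    protein_id = "P1", position = c(2L, 7L, 30L),
    aa_ref = c("A", "W", "A"), aa_alt = c("V", "R", "T"),
    nt_ref = c("C", "T", "C"), nt_alt = c("T", "C", "A"),
    maf = c(0.001, 0.001, 0.2))
  v <- as_variant_table(v)
  aln <- align_and_map(chain_seq, chain_seq)
  out <- map_variants(v, aln, lab, chain = "A", structure_id = "contact")
  expect_equal(out$mapped, c(TRUE, FALSE, FALSE))
  expect_equal(out$reason, c(NA, "mismatch", "out_of_range"))
  expect_equal(out$resno[1], 2L)
  expect_false(is.na(out$region[1]))
  # conservation: every variant is mapped or carries a reason
  expect_true(all(out$mapped | !is.na(out$reason)))
})

test_that("a query position opposite an alignment gap is unmapped(gap)", {
  chain <- "ACDEFGHIKL"
  query <- "ACDEXXFGHIKL"  # two extra residues in the query
  aln <- align_and_map(query, chain, min_identity = 75)
  x <- make_contact_dimer(aa = "A")
  lab <- classify_complex(x, n_points = 240)
  # give the fixture chain the right sequence length/letters for mapping
  lab$aa <- rep(strsplit(chain, "")[[1]][1:9], 2)[seq_len(nrow(lab))]
  v <- as_variant_table(tibble::tibble(
    protein_id = "P1", position = 5L, aa_ref = "X", aa_alt = "A",
    nt_ref = "A", nt_alt = "C", maf = 0.01))
  out <- map_variants(v, aln, lab, chain = "A")
  expect_false(out$mapped)
  expect_equal(out$reason, "gap")
})

test_that("redundancy removal is greedy, deterministic and order-invariant", {
  seq_a <- paste(rep(c("A", "C", "D", "E", "F"), 8), collapse = "")
  seq_c <- paste(sample(c("G", "H", "I", "K", "L", "M", "N"), 35,
                        replace = TRUE), collapse = "")
  chains <- tibble::tibble(id = c("A", "B", "C"),
                           seq = c(seq_a, seq_a, seq_c))
  ref <- remove_redundancy(chains)
  expect_setequal(ref$id, c("A", "C"))
  # identical chains collapse to one; three mutually dissimilar all retained
  expect_equal(nrow(remove_redundancy(chains[c(1, 2), ])), 1)
  dis <- tibble::tibble(
    id = c("X", "Y", "Z"),
    seq = c(strrep("AC", 20), strrep("DE", 20), strrep("FG", 20)))
  expect_equal(nrow(remove_redundancy(dis)), 3)
  # invariance under input order
  for (ord in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    out <- remove_redundancy(chains[ord, ])
    expect_setequal(out$id, c("A", "C"))
  }
})
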