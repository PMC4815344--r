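# Variant-to-chain mapping: global pairwise alignment, position transfer,
# and redundancy removal among chains.

aa_substitution_matrix <- function(match = 1, mismatch = -1) {
  alpha <- c(aa_one_letter(), "X", "*")
  m <- matrix(mismatch, length(alpha), length(alpha),
              dimnames = list(alpha, alpha))
  diag(m) <- match
  m
}

#' Globally align a query protein sequence to a structure chain
#'
#' Needleman-Wunsch global alignment (via Biostrings) of the query protein
#' sequence against the chain sequence. Percent identity is defined as
#' identical columns divided by aligned (non-gap-pair) columns, times 100.
#' Returns `NULL` when identity falls below `min_identity`, mirroring the
#' mapping rule that only near-identical structures are used for a query.
#'
#' @param query_seq,chain_seq Nonempty amino acid strings.
#' @param min_identity Minimum percent identity to accept (default 95).
#' @param match,mismatch,gap_open,gap_extend Alignment scores (gap
#'   penalties are positive costs).
#' @return A `chain_alignment`: a tibble of aligned position pairs
#'   (`query_pos`, `chain_pos`, both 1-based, non-gap columns only, plus
#'   `identical`) with the percent `identity` as an attribute — or `NULL`
#'   below the identity threshold.
#' @export
align_and_map <- function(query_seq, chain_seq, min_identity = 95,
                          match = 1, mismatch = -1,
                          gap_open = 5, gap_extend = 1) {
  if (!nzchar(query_seq) || !nzchar(chain_seq)) {
    abort("sequences must be nonempty")
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query_seq),
    subject = Biostrings::AAString(chain_seq),
    type = "global",
    substitutionMatrix = aa_substitution_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(p != "-")
  cpos <- cumsum(s != "-")
  keep <- p != "-" & s != "-"
  pairs <- tibble(query_pos = qpos[keep], chain_pos = cpos[keep],
                  identical = p[keep] == s[keep])
  identity <- if (nrow(pairs) == 0) 0 else 100 * mean(pairs$identical)
  if (identity < min_identity) return(NULL)
  attr(pairs, "identity") <- identity
  class(pairs) <- c("chain_alignment", class(pairs))
  pairs
}

#' Map variants onto a classified structure chain
#'
#' Transfers each variant's 1-based protein position through a
#' [align_and_map()] alignment onto the chain's residues and annotates it
#' with the residue's structural region. A variant maps only when its
#' position falls in an aligned column and the chain residue's amino acid
#' equals the variant's mutating amino acid; otherwise a reason code is
#' recorded (`out_of_range`, `gap`, or `mismatch`).
#'
#' @param variants A `variant_table` (rows for one protein).
#' @param alignment A `chain_alignment` for that protein vs the chain.
#' @param sites A `residue_accessibility` table for the complex.
#' @param chain Chain identifier the alignment refers to.
#' @param structure_id Structure identifier recorded on mapped rows.
#' @return The variant tibble with added columns `structure_id`, `chain`,
#'   `resno`, `icode`, `region`, `mapped` (logical) and `reason` (`NA` when
#'   mapped).
#' @export
map_variants <- function(variants, alignment, sites, chain,
                         structure_id = attr(sites, "structure_id")) {
  chain_res <- sites |>
    dplyr::filter(.data$chain == !!chain) |>
    dplyr::mutate(chain_pos = dplyr::row_number()) |>
    dplyr::select("chain_pos", "resno", "icode", chain_aa = "aa",
                  "region")
  amap <- alignment |>
    dplyr::left_join(chain_res, by = "chain_pos")

  out <- variants |>
    dplyr::left_join(amap, by = c(position = "query_pos")) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        is.na(.data$chain_pos) & .data$position > max(alignment$query_pos) ~
          "out_of_range",
        is.na(.data$chain_pos) ~ "gap",
        .data$chain_aa != .data$aa_ref ~ "mismatch",
        .default = NA_character_),
      mapped = is.na(.data$reason),
      structure_id = ifelse(.data$mapped, structure_id, NA_character_),
      chain = ifelse(.data$mapped, chain, NA_character_),
      resno = ifelse(.data$mapped, .data$resno, NA_integer_),
      icode = ifelse(.data$mapped, .data$icode, NA_character_),
      region = ifelse(.data$mapped, .data$region, NA_character_)) |>
    dplyr::select(-"chain_pos", -"chain_aa", -"identical")
  out
}

#' Pairwise percent identity between two sequences
#'
#' Identity over aligned non-gap columns of a global alignment, using the
#' same scoring as [align_and_map()] but with no acceptance threshold.
#'
#' @inheritParams align_and_map
#' @return Percent identity between 0 and 100.
#' @export
pairwise_identity <- function(query_seq, chain_seq, ...) {
  aln <- align_and_map(query_seq, chain_seq, min_identity = 0, ...)
  attr(aln, "identity")
}

#' Remove redundant chains by sequence identity
#'
#' Greedy clustering: chains are ordered by decreasing sequence length
#' (ties: lexicographic id) and a chain is retained iff its identity to
#' every already-retained chain is at or below the threshold. The result is
#' deterministic and independent of input order.
#'
#' @param chains Tibble with columns `id` and `seq`.
#' @param threshold Maximum allowed percent identity to any retained chain
#'   (default 50).
#' @return The retained subset of `chains`, in greedy order.
#' @export
remove_redundancy <- function(chains, threshold = 50) {
  stopifnot(all(c("id", "seq") %in% names(chains)))
  if (nrow(chains) == 0) abort("no chains supplied")
  ord <- order(-nchar(chains$seq), chains$id)
  chains <- chains[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(chains))) {
    redundant <- FALSE
    for (k in kept) {
      if (pairwise_identity(chains$seq[i], chains$seq[k]) > threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  chains[kept, , drop = FALSE]
}
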