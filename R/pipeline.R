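# End-to-end orchestration: validate a run configuration, classify
# structures, map variants, tabulate, test, and write a reproducible
# report bundle.

pipeline_defaults <- function() {
  list(probe_radius = 1.4, n_points = 960, rasa_cutoff = 0.25, tol = 1e-6,
       maxasa_set = "naccess", identity_map = 95, identity_redundancy = 50,
       maf_percent = FALSE, seed = 1L)
}

#' Validate a pipeline configuration
#'
#' Fills omitted parameters with documented defaults, reports every
#' violation (not just the first), and warns on unknown keys.
#'
#' @param config Named list of parameter overrides (possibly empty).
#' @return The fully defaulted config, with attribute `warnings`; errors
#'   abort with the full list of offending keys.
#' @export
validate_config <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  warnings <- character(0)
  if (length(unknown) > 0) {
    warnings <- paste0("unknown config key(s) ignored: ",
                       paste(unknown, collapse = ", "))
    warn(warnings)
  }
  out <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  errors <- character(0)
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  chk(out$probe_radius > 0, "probe_radius must be > 0")
  chk(out$n_points >= 92, "n_points must be >= 92")
  chk(out$rasa_cutoff > 0 && out$rasa_cutoff < 1,
      "rasa_cutoff must be in (0, 1)")
  chk(out$tol >= 0, "tol must be >= 0")
  chk(out$identity_map >= 0 && out$identity_map <= 100,
      "identity_map must be in [0, 100]")
  chk(out$identity_redundancy >= 0 && out$identity_redundancy <= 100,
      "identity_redundancy must be in [0, 100]")
  chk(out$maxasa_set %in% c("naccess", "tien"),
      "maxasa_set must be 'naccess' or 'tien'")
  if (length(errors) > 0) {
    abort(paste0("invalid configuration:\n", paste0("- ", errors,
                                                    collapse = "\n")))
  }
  attr(out, "warnings") <- warnings
  out
}

#' Run the variant-to-interface analysis end to end
#'
#' Classifies every complex, removes redundant chains, aligns each query
#' protein to the retained chains, maps variants, builds the region
#' contingency table, runs the headline chi-squared tests, and computes
#' per-stratum relative frequencies. When a variant's protein aligns to
#' several chains of one complex (homodimers), it is counted once per
#' retained non-redundant chain.
#'
#' @param structures List of `structure_complex` objects (or paths, read
#'   with `format`).
#' @param variants A `variant_table` (or path to a variants TSV).
#' @param sequences Named character vector of query protein sequences by
#'   `protein_id`; defaults to the structure chain sequences, which
#'   supports the common case of variants already expressed in chain
#'   coordinates.
#' @param config Parameter overrides, see [validate_config()].
#' @param format Structure format when `structures` are paths.
#' @return A `pipeline_report` list: `sites`, `variants` (with mapping
#'   status), `contingency`, `tests`, `relfreq`, `manifest`.
#' @export
run_pipeline <- function(structures, variants, sequences = NULL,
                         config = list(), format = "pdb") {
  cfg <- validate_config(config)
  if (is.character(structures)) structures <- as.list(structures)
  structures <- purrr::map(structures, function(s) {
    if (is.character(s)) read_structure(s, format = format) else s
  })
  if (is.character(variants)) {
    variants <- read_variants(variants, maf_percent = cfg$maf_percent)
  }

  # classify every complex
  sites <- purrr::map(structures, function(s) {
    classify_complex(s, probe_radius = cfg$probe_radius,
                     n_points = cfg$n_points, rasa_cutoff = cfg$rasa_cutoff,
                     tol = cfg$tol, maxasa_set = cfg$maxasa_set) |>
      dplyr::mutate(structure_id = structure_id(s), .before = 1)
  }) |>
    dplyr::bind_rows()

  # chain inventory and redundancy removal across all complexes
  chain_tbl <- purrr::map(structures, function(s) {
    cs <- chain_sequences(s)
    tibble(structure_id = structure_id(s),
           chain = names(attr(cs, "sequences")),
           seq = unname(attr(cs, "sequences")))
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(id = paste0(.data$structure_id, "_", .data$chain))
  retained <- remove_redundancy(chain_tbl, threshold = cfg$identity_redundancy)

  if (is.null(sequences)) {
    sequences <- setNames(retained$seq, retained$id)
  }

  # align each query protein to every retained chain and map its variants
  mapped <- purrr::map(unique(variants$protein_id), function(pid) {
    v <- variants[variants$protein_id == pid, , drop = FALSE]
    if (!pid %in% names(sequences)) {
      return(dplyr::mutate(v, structure_id = NA_character_,
                           chain = NA_character_, resno = NA_integer_,
                           icode = NA_character_, region = NA_character_,
                           mapped = FALSE, reason = "no_sequence"))
    }
    hits <- purrr::map(seq_len(nrow(retained)), function(i) {
      aln <- align_and_map(sequences[[pid]], retained$seq[i],
                           min_identity = cfg$identity_map)
      if (is.null(aln)) return(NULL)
      st <- sites[sites$structure_id == retained$structure_id[i], ,
                  drop = FALSE]
      map_variants(v, aln, st, chain = retained$chain[i],
                   structure_id = retained$structure_id[i])
    })
    hits <- purrr::compact(hits)
    if (length(hits) == 0) {
      return(dplyr::mutate(v, structure_id = NA_character_,
                           chain = NA_character_, resno = NA_integer_,
                           icode = NA_character_, region = NA_character_,
                           mapped = FALSE, reason = "no_structure"))
    }
    dplyr::bind_rows(hits)
  }) |>
    dplyr::bind_rows()

  mapped_only <- mapped[mapped$mapped, , drop = FALSE]
  contingency <- tabulate_regions(sites, mapped_only)
  tests <- stats_from_counts(contingency)
  relfreq <- tryCatch(relative_frequency_table(sites, mapped_only),
                      error = function(e) NULL)

  manifest <- list(
    package = "snviface",
    version = as.character(utils::packageVersion("snviface")),
    parameters = cfg[order(names(cfg))],
    n_structures = length(structures),
    n_chains = nrow(chain_tbl),
    n_chains_retained = nrow(retained),
    counts = list(variants_in = nrow(variants),
                  rejected = as.list(attr(variants, "rejected") %||%
                                       c(bad_maf = 0L, synonymous = 0L)),
                  mapped = sum(mapped$mapped),
                  unmapped = sum(!mapped$mapped)))
  structure(list(sites = sites, variants = mapped,
                 contingency = contingency, tests = tests,
                 relfreq = relfreq, manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d sites, %d/%d variants mapped\n",
              nrow(x$sites), sum(x$variants$mapped), nrow(x$variants)))
  print(x$contingency)
  print(x$tests)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Emits the contingency table and per-variant table as TSV, the test
#' results and relative frequencies as part of a JSON report, and the run
#' manifest (package version, all parameters, record counts) as JSON.
#' Outputs are deterministic given the same inputs and config.
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(report$contingency, file.path(dir, "region_counts.tsv"))
  readr::write_tsv(report$variants, file.path(dir, "variants_mapped.tsv"))
  readr::write_tsv(report$sites, file.path(dir, "sites.tsv"))
  if (!is.null(report$relfreq)) {
    readr::write_tsv(report$relfreq, file.path(dir, "relative_frequency.tsv"))
  }
  jsonlite::write_json(report$tests, file.path(dir, "tests.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
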