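# Paired-chain cell assembly, nucleotide-level clonotype calling,
# amino-acid-level TCR-type grouping, and dominance ranking.
#
# Definitions used throughout:
#   clonotype — cells sharing identical paired TRA+TRB junction nucleotide
#     sequences (plus V/J gene calls under the default key policy);
#   TCR type — clonotypes sharing identical paired TRA+TRB junction
#     amino-acid sequences. Distinct clonotypes of one TCR type are
#     synonymous nucleotide variants produced by convergent recombination.

#' Translate nucleotide sequences with the standard genetic code
#'
#' @param seq Character vector; each element's length must be a multiple of
#'   three and contain only A/C/G/T. Stops are rendered as `*`. Empty strings
#'   translate to empty strings.
#' @return Character vector of amino-acid strings.
#' @export
translate_nt <- function(seq) {
  if (length(seq) == 0) return(character())
  assert_nt(seq, "translate_nt() input")
  if (any(nchar(seq) %% 3 != 0)) {
    abort("translate_nt(): sequence length must be a multiple of 3")
  }
  out <- character(length(seq))
  nz <- nzchar(seq)
  if (any(nz)) {
    out[nz] <- as.character(suppressWarnings(
      Biostrings::translate(Biostrings::DNAStringSet(seq[nz]),
                            no.init.codon = TRUE, if.fuzzy.codon = "error")
    ))
  }
  out
}

#' Assemble per-cell paired chains from contig records
#'
#' Non-productive contigs are discarded. For each cell and chain the contig
#' with the most UMIs is retained (ties broken by reads, then by junction
#' nucleotide sequence, lexicographically); `multi_tra`/`multi_trb` flag
#' cells that had more than one productive contig on that chain. Cells with
#' no productive contig on either chain do not appear in the output.
#'
#' @param contigs Merged contig tibble from [merge_samples()] (must carry
#'   `cell_id`).
#' @return One row per cell: `cell_id`, `sample_id`, `barcode`, label columns
#'   if present, then `tra_*` and `trb_*` chain fields and the multi flags.
#' @export
assemble_cells <- function(contigs) {
  stopifnot("cell_id" %in% names(contigs))
  prod <- dplyr::filter(contigs, .data$productive)
  label_cols <- intersect(c("gfp_status", "condition", "cluster"), names(contigs))
  if (nrow(prod) == 0) return(empty_cell_tbl(label_cols))
  picked <- prod |>
    dplyr::group_by(.data$cell_id, .data$chain) |>
    dplyr::arrange(dplyr::desc(.data$umis), dplyr::desc(.data$reads),
                   .data$junction_nt, .by_group = TRUE) |>
    dplyr::mutate(n_productive = dplyr::n()) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  base_cols <- c("cell_id", "sample_id", "barcode", label_cols)
  chain_tbl <- function(ch, prefix) {
    x <- dplyr::filter(picked, .data$chain == ch)
    out <- x[, c("cell_id", "v_gene", "d_gene", "j_gene", "junction_nt",
                 "junction_aa", "umis", "n_productive")]
    names(out) <- c("cell_id", paste0(prefix, c("_v", "_d", "_j",
                                                "_junction_nt", "_junction_aa",
                                                "_umis", "_n")))
    out
  }
  cells <- dplyr::distinct(picked[, base_cols])
  cells <- dplyr::left_join(cells, chain_tbl("TRA", "tra"), by = "cell_id")
  cells <- dplyr::left_join(cells, chain_tbl("TRB", "trb"), by = "cell_id")
  cells$multi_tra <- !is.na(cells$tra_n) & cells$tra_n > 1L
  cells$multi_trb <- !is.na(cells$trb_n) & cells$trb_n > 1L
  cells$tra_n <- NULL
  cells$trb_n <- NULL
  cells$tra_d <- NULL  # TRA has no D segment
  cells
}

empty_cell_tbl <- function(label_cols = character()) {
  out <- tibble::tibble(
    cell_id = character(), sample_id = character(), barcode = character(),
    tra_v = character(), tra_j = character(), tra_junction_nt = character(),
    tra_junction_aa = character(), tra_umis = integer(),
    trb_v = character(), trb_d = character(), trb_j = character(),
    trb_junction_nt = character(), trb_junction_aa = character(),
    trb_umis = integer(), multi_tra = logical(), multi_trb = logical()
  )
  for (lc in label_cols) out[[lc]] <- character()
  out
}

clonotype_key_cols <- function(key_policy) {
  switch(key_policy,
    "genes+nt" = c("tra_v", "tra_j", "tra_junction_nt",
                   "trb_v", "trb_d", "trb_j", "trb_junction_nt"),
    "nt" = c("tra_junction_nt", "trb_junction_nt"),
    abort(sprintf("unknown key_policy '%s' (use 'genes+nt' or 'nt')",
                  key_policy))
  )
}

#' Call nucleotide-level clonotypes
#'
#' Partitions paired cells by exact equality of the clonotype key. Under the
#' default `"genes+nt"` policy the key is
#' (tra_v, tra_j, tra_junction_nt, trb_v, trb_d, trb_j, trb_junction_nt);
#' policy `"nt"` uses the two junction sequences alone. With the default
#' strict-paired rule, cells missing either chain are excluded and counted.
#' Clonotype ids `CT0001`, `CT0002`, ... are assigned in order of decreasing
#' size, ties broken lexicographically on the key, so ids are stable across
#' input permutations.
#'
#' @param cells Tibble from [assemble_cells()].
#' @param key_policy `"genes+nt"` (default) or `"nt"`.
#' @param allow_single_chain If `TRUE`, single-chain cells form clonotypes
#'   keyed on their one available chain (exploratory; default `FALSE`).
#' @return List with `clonotypes` (one row per clonotype: ids, key columns,
#'   amino-acid keys, `n_cells`), `cells` (input rows for clonotyped cells
#'   with `clonotype_id` attached) and `n_excluded_single_chain`.
#' @export
call_clonotypes <- function(cells, key_policy = "genes+nt",
                            allow_single_chain = FALSE) {
  key_cols <- clonotype_key_cols(key_policy)
  paired <- !is.na(cells$tra_junction_nt) & !is.na(cells$trb_junction_nt)
  eligible <- if (allow_single_chain) cells else cells[paired, ]
  n_excluded <- nrow(cells) - nrow(eligible)
  key_string <- do.call(paste, c(lapply(key_cols, function(k) {
    v <- eligible[[k]]
    ifelse(is.na(v), "<NA>", v)
  }), sep = "|"))
  eligible$.key <- key_string
  summarise_first <- function(x) x[1L]
  clons <- eligible |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("tra_v", "tra_j", "tra_junction_nt",
                                    "trb_v", "trb_d", "trb_j",
                                    "trb_junction_nt", "tra_junction_aa",
                                    "trb_junction_aa")), summarise_first),
      n_cells = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_cells), .data$.key)
  clons$clonotype_id <- sprintf("CT%04d", seq_len(nrow(clons)))
  cells_out <- dplyr::left_join(eligible,
                                clons[, c(".key", "clonotype_id")],
                                by = ".key")
  cells_out$.key <- NULL
  clons$.key <- NULL
  clons <- clons[, c("clonotype_id", "tra_v", "tra_j", "tra_junction_nt",
                     "trb_v", "trb_d", "trb_j", "trb_junction_nt",
                     "tra_junction_aa", "trb_junction_aa", "n_cells")]
  list(clonotypes = clons, cells = cells_out,
       n_excluded_single_chain = n_excluded)
}

#' Group clonotypes into amino-acid-level TCR types
#'
#' Partitions clonotypes by the paired junction amino-acid key
#' `(tra_junction_aa, trb_junction_aa)`. Every member clonotype's junction
#' nucleotide sequences are re-translated and checked against the recorded
#' amino-acid sequences; a disagreement signals upstream data corruption and
#' is an error. TCR type ids `TT0001`, ... are assigned in order of
#' decreasing total cell count (ties: more clonotypes first, then amino-acid
#' key).
#'
#' @param clonotypes Clonotype tibble from [call_clonotypes()].
#' @return List with `tcr_types` (tcr_type_id, amino-acid keys,
#'   `n_clonotypes`, `n_cells`) and `clonotypes` (input with `tcr_type_id`
#'   attached).
#' @export
group_tcr_types <- function(clonotypes) {
  if (nrow(clonotypes) > 0) {
    ok <- translate_nt(clonotypes$tra_junction_nt) == clonotypes$tra_junction_aa &
      translate_nt(clonotypes$trb_junction_nt) == clonotypes$trb_junction_aa
    if (!all(ok)) {
      abort(paste0("junction nucleotide sequence does not translate to the ",
                   "recorded amino-acid sequence for clonotype(s): ",
                   paste(clonotypes$clonotype_id[!ok], collapse = ", ")))
    }
  }
  types <- clonotypes |>
    dplyr::group_by(.data$tra_junction_aa, .data$trb_junction_aa) |>
    dplyr::summarise(n_clonotypes = dplyr::n(),
                     n_cells = sum(.data$n_cells), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_cells),
                   dplyr::desc(.data$n_clonotypes),
                   .data$tra_junction_aa, .data$trb_junction_aa)
  types$tcr_type_id <- sprintf("TT%04d", seq_len(nrow(types)))
  clons_out <- dplyr::left_join(
    clonotypes,
    types[, c("tra_junction_aa", "trb_junction_aa", "tcr_type_id")],
    by = c("tra_junction_aa", "trb_junction_aa")
  )
  types <- types[, c("tcr_type_id", "tra_junction_aa", "trb_junction_aa",
                     "n_clonotypes", "n_cells")]
  list(tcr_types = types, clonotypes = clons_out)
}

#' Rank TCR types by dominance
#'
#' Sorts by total cell count (descending), then clonotype count (descending),
#' then the amino-acid key, and assigns ranks 1..n ("TCR 1" is the most
#' dominant type). Types beyond `n` keep `NA` rank.
#'
#' @param tcr_types Tibble from [group_tcr_types()].
#' @param n Number of top types to rank (default 30).
#' @return The input sorted, with a `rank` column.
#' @export
rank_tcr_types <- function(tcr_types, n = 30) {
  if (n < 1) abort("n must be >= 1")
  out <- dplyr::arrange(tcr_types, dplyr::desc(.data$n_cells),
                        dplyr::desc(.data$n_clonotypes),
                        .data$tra_junction_aa, .data$trb_junction_aa)
  out$rank <- ifelse(seq_len(nrow(out)) <= n, seq_len(nrow(out)), NA_integer_)
  out
}
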