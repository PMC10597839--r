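# Reading 10x-style filtered contig annotation tables, merging samples, and
# writing the pipeline's result tables.
#
# Internal contig model (one row per sequenced TCR chain contig):
#   barcode, sample_id, chain, v_gene, d_gene, j_gene, junction_nt,
#   junction_aa, productive, umis, reads
# Junction strings are anchor-inclusive (they start at the conserved Cys and
# end at the Phe/Trp), which is also the convention of the 10x `cdr3` /
# `cdr3_nt` columns.

CONTIG_COLUMNS <- c("barcode", "sample_id", "chain", "v_gene", "d_gene",
                    "j_gene", "junction_nt", "junction_aa", "productive",
                    "umis", "reads")

# accepted header spellings, 10x dialect first, then AIRR
CONTIG_ALIASES <- list(
  barcode      = c("barcode", "cell_id"),
  chain        = c("chain", "locus"),
  junction_aa  = c("cdr3", "junction_aa"),
  junction_nt  = c("cdr3_nt", "junction"),
  v_gene       = c("v_gene", "v_call"),
  d_gene       = c("d_gene", "d_call"),
  j_gene       = c("j_gene", "j_call"),
  productive   = c("productive"),
  umis         = c("umis", "umi_count", "duplicate_count"),
  reads        = c("reads", "read_count", "consensus_count"),
  high_confidence = c("high_confidence")
)

parse_productive_flag <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(trimws(as.character(x))) %in% "true"
}

blank_to_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | tolower(x) == "none")] <- NA_character_
  x
}

#' Read a filtered contig annotation table for one sample
#'
#' Accepts the 10x `filtered_contig_annotations.csv` dialect
#' (`cdr3`/`cdr3_nt`/`v_gene`...) as well as AIRR rearrangement headers
#' (`junction_aa`/`junction`/`v_call`...); CSV and TSV are auto-detected from
#' the extension. Rows from loci other than TRA/TRB are dropped with a
#' message. The `productive` column is parsed case-insensitively; any value
#' other than "true" (including "None") yields `FALSE`. Non-productive rows
#' are retained here and excluded later at cell assembly.
#'
#' @param path CSV/TSV file.
#' @param sample_id Sample label attached to every record.
#' @param use_high_confidence If `TRUE` and a `high_confidence` column is
#'   present, keep only high-confidence contigs.
#' @return Tibble of contig records (see `CONTIG_COLUMNS`).
#' @export
read_contig_annotations <- function(path, sample_id,
                                    use_high_confidence = FALSE) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE,
                col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    warn(sprintf("contig file '%s' has no rows", path))
    return(empty_contig_tbl())
  }
  pick <- function(field) {
    hit <- intersect(CONTIG_ALIASES[[field]], names(raw))
    if (length(hit) == 0) NULL else raw[[hit[1L]]]
  }
  for (field in c("barcode", "chain", "junction_aa", "junction_nt", "productive")) {
    if (is.null(pick(field))) {
      abort(sprintf(
        "contig file '%s' is missing mandatory column '%s' (accepted names: %s)",
        path, field, paste(CONTIG_ALIASES[[field]], collapse = "/")
      ))
    }
  }
  out <- tibble::tibble(
    barcode = pick("barcode"),
    sample_id = sample_id,
    chain = toupper(pick("chain")),
    v_gene = blank_to_na(pick("v_gene") %||% NA_character_),
    d_gene = blank_to_na(pick("d_gene") %||% NA_character_),
    j_gene = blank_to_na(pick("j_gene") %||% NA_character_),
    junction_nt = toupper(pick("junction_nt")),
    junction_aa = pick("junction_aa"),
    productive = parse_productive_flag(pick("productive")),
    umis = as.integer(pick("umis") %||% 0L),
    reads = as.integer(pick("reads") %||% 0L)
  )
  if (use_high_confidence && !is.null(pick("high_confidence"))) {
    hc <- parse_productive_flag(pick("high_confidence"))
    inform(sprintf("dropped %d non-high_confidence contig(s)", sum(!hc)))
    out <- out[hc, ]
  }
  other <- !(out$chain %in% c("TRA", "TRB"))
  if (any(other)) {
    inform(sprintf("dropped %d contig(s) from non-TRA/TRB loci (%s)",
                   sum(other),
                   paste(unique(out$chain[other]), collapse = ", ")))
    out <- out[!other, ]
  }
  # TRA contigs never carry a D gene
  out$d_gene[out$chain == "TRA"] <- NA_character_
  out
}

empty_contig_tbl <- function() {
  tibble::tibble(
    barcode = character(), sample_id = character(), chain = character(),
    v_gene = character(), d_gene = character(), j_gene = character(),
    junction_nt = character(), junction_aa = character(),
    productive = logical(), umis = integer(), reads = integer()
  )
}

#' Merge contig records from several samples
#'
#' Cell identity is `(sample_id, barcode)`: a `cell_id` column
#' `<sample_id>_<barcode>` is added so that identical raw barcodes from
#' different samples remain distinct cells. Optional per-cell labels
#' (`barcode`, `sample_id`, and any of `gfp_status`, `condition`, `cluster`)
#' are left-joined; cells without a label row keep `NA` labels.
#'
#' @param contig_list List of tibbles from [read_contig_annotations()].
#' @param labels Optional label tibble as described above.
#' @return Merged contig tibble with `cell_id` (and label columns if given).
#' @export
merge_samples <- function(contig_list, labels = NULL) {
  stopifnot(is.list(contig_list))
  samples <- vapply(contig_list, function(x) {
    u <- unique(x$sample_id)
    if (length(u) > 1) abort("a contig table mixes sample_ids")
    if (length(u) == 0) NA_character_ else u
  }, character(1))
  samples <- samples[!is.na(samples)]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample_id(s) in merge: ",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  merged <- dplyr::bind_rows(contig_list)
  merged$cell_id <- paste(merged$sample_id, merged$barcode, sep = "_")
  if (!is.null(labels)) {
    labels <- tibble::as_tibble(labels)
    if (anyDuplicated(labels[, c("barcode", "sample_id")])) {
      abort("labels must be unique per (barcode, sample_id)")
    }
    merged <- dplyr::left_join(merged, labels, by = c("barcode", "sample_id"))
  }
  merged
}

TABLE_KINDS <- list(
  contigs = c("cell_id", CONTIG_COLUMNS),
  clonotypes = c("clonotype_id", "tra_v", "tra_j", "tra_junction_nt",
                 "trb_v", "trb_d", "trb_j", "trb_junction_nt",
                 "tra_junction_aa", "trb_junction_aa", "n_cells"),
  tcr_types = c("tcr_type_id", "rank", "tra_junction_aa", "trb_junction_aa",
                "n_clonotypes", "n_cells"),
  decompositions = c("clonotype_id", "chain", "part_order", "kind", "seq",
                     "germline_id", "v_trim", "d5_trim", "d3_trim", "j_trim",
                     "d_assigned"),
  mismatches = c("tcr_type_id", "clonotype_id", "chain", "is_reference",
                 "positions"),
  convergence = c("tcr_type_id", "rank", "tra_junction_aa", "trb_junction_aa",
                  "n_clonotypes", "n_cells", "convergent", "gene_concordant",
                  "samples", "conditions"),
  sharing_summary = c("category", "n"),
  composition = c("tcr_type_id", "clonotype_id", "gfp_status", "cluster",
                  "n_cells"),
  demux = c("cell_id", "call", "assigned_to", "top_value", "margin")
)

#' Write a pipeline result table
#'
#' Writes TSV with a fixed, documented column order per table kind so that
#' outputs are diffable across runs.
#'
#' @param records Tibble containing at least the kind's columns.
#' @param path Output path.
#' @param kind One of "contigs", "clonotypes", "tcr_types", "decompositions",
#'   "mismatches", "convergence", "sharing_summary", "composition", "demux".
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @return Invisibly, the written tibble (in output column order).
#' @export
write_table <- function(records, path, kind, overwrite = FALSE) {
  if (!kind %in% names(TABLE_KINDS)) {
    abort(sprintf("unknown table kind '%s' (expected one of: %s)",
                  kind, paste(names(TABLE_KINDS), collapse = ", ")))
  }
  if (file.exists(path) && !overwrite) {
    abort(sprintf("'%s' exists; pass overwrite = TRUE to replace it", path))
  }
  cols <- TABLE_KINDS[[kind]]
  records <- tibble::as_tibble(records)
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    abort(sprintf("table of kind '%s' is missing column(s): %s",
                  kind, paste(missing, collapse = ", ")))
  }
  out <- records[, cols]
  readr::write_tsv(out, path)
  invisible(out)
}
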