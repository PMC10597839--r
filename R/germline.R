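# Germline V/D/J segment references.
#
# A germline set is the local stand-in for an online germline database: a
# FASTA of segment sequences plus a TSV giving, for every segment, its chain
# (TRA/TRB), its class (V/D/J) and -- for V and J -- the 0-based offset of
# the conserved anchor codon (Cys for V, Phe/Trp for J) within the sequence.
# Junctions are handled anchor-INCLUSIVE throughout the package: a junction
# begins at the V Cys codon and ends at the J Phe/Trp codon.

CYS_CODONS <- c("TGT", "TGC")
JANCHOR_CODONS <- c("TTT", "TTC", "TGG")

#' Construct a validated germline segment set
#'
#' @param segments Tibble with columns `id`, `chain` ("TRA"/"TRB"),
#'   `segment_class` ("V"/"D"/"J"), `seq_nt` (uppercase A/C/G/T) and
#'   `anchor_offset` (0-based start of the anchor codon; `NA` for D).
#' @return An object of class `germline_set`.
#' @export
germline_set <- function(segments) {
  segments <- tibble::as_tibble(segments)
  needed <- c("id", "chain", "segment_class", "seq_nt", "anchor_offset")
  missing <- setdiff(needed, names(segments))
  if (length(missing) > 0) {
    abort(paste0("germline metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  segments$seq_nt <- toupper(segments$seq_nt)
  if (anyDuplicated(segments$id)) {
    abort(paste0("duplicate germline segment id(s): ",
                 paste(unique(segments$id[duplicated(segments$id)]), collapse = ", ")))
  }
  if (!all(segments$chain %in% c("TRA", "TRB"))) {
    abort("germline chain must be TRA or TRB")
  }
  if (!all(segments$segment_class %in% c("V", "D", "J"))) {
    abort("germline segment_class must be V, D or J")
  }
  if (any(!nzchar(segments$seq_nt))) abort("germline seq_nt must be non-empty")
  assert_nt(segments$seq_nt, "germline seq_nt")
  is_d <- segments$segment_class == "D"
  if (any(is_d & !is.na(segments$anchor_offset))) {
    abort("D segments must not carry an anchor_offset")
  }
  if (any(is_d & segments$chain == "TRA")) {
    abort("TRA has no D segments")
  }
  vj <- !is_d
  if (any(vj & is.na(segments$anchor_offset))) {
    abort("V and J segments require an anchor_offset")
  }
  off <- segments$anchor_offset[vj]
  len <- nchar(segments$seq_nt[vj])
  if (any(off < 0 | off > len - 3)) {
    abort("anchor_offset must lie in [0, length(seq_nt) - 3]")
  }
  # every chain with a V also has a J
  for (ch in unique(segments$chain)) {
    cls <- segments$segment_class[segments$chain == ch]
    if ("V" %in% cls && !("J" %in% cls)) {
      abort(sprintf("chain %s has V segments but no J segment", ch))
    }
  }
  # anchors should be able to encode the conserved residue; warn, don't fail
  anchor_codon <- substr(segments$seq_nt, segments$anchor_offset + 1L,
                         segments$anchor_offset + 3L)
  bad_v <- segments$segment_class == "V" & !(anchor_codon %in% CYS_CODONS)
  bad_j <- segments$segment_class == "J" & !(anchor_codon %in% JANCHOR_CODONS)
  if (any(bad_v, na.rm = TRUE)) {
    warn(paste0("V anchor codon is not Cys (TGT/TGC) for: ",
                paste(segments$id[which(bad_v)], collapse = ", ")))
  }
  if (any(bad_j, na.rm = TRUE)) {
    warn(paste0("J anchor codon is not Phe/Trp (TTT/TTC/TGG) for: ",
                paste(segments$id[which(bad_j)], collapse = ", ")))
  }
  structure(list(segments = segments), class = "germline_set")
}

#' @export
print.germline_set <- function(x, ...) {
  tab <- table(x$segments$chain, x$segments$segment_class)
  cat("<germline_set> ", nrow(x$segments), " segments\n", sep = "")
  print(tab)
  invisible(x)
}

#' Load a germline set from FASTA + metadata TSV
#'
#' The metadata TSV must have columns `id`, `chain`, `segment_class`,
#' `anchor_offset` (0-based; empty/NA for D segments). Every FASTA record id
#' must have a metadata row and vice versa.
#'
#' @param fasta_path FASTA of segment nucleotide sequences.
#' @param metadata_path TSV as described above.
#' @return A `germline_set`.
#' @export
load_germline <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  # FASTA descriptions may carry extra tokens after the id
  ids <- sub("\\s.*$", "", ids)
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  if (!setequal(ids, meta$id)) {
    abort(sprintf(
      "FASTA ids and metadata ids disagree (only in FASTA: %s; only in metadata: %s)",
      paste(setdiff(ids, meta$id), collapse = ",") ,
      paste(setdiff(meta$id, ids), collapse = ",")
    ))
  }
  seq_chr <- toupper(as.character(seqs))
  names(seq_chr) <- ids
  meta$seq_nt <- unname(seq_chr[meta$id])
  meta$anchor_offset <- suppressWarnings(as.integer(meta$anchor_offset))
  germline_set(meta[, c("id", "chain", "segment_class", "seq_nt", "anchor_offset")])
}

#' Write a germline set to FASTA + metadata TSV
#'
#' Inverse of [load_germline()]; `load_germline(write_germline(x))` returns
#' an identical set.
#'
#' @param gs A `germline_set`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the input `gs`.
#' @export
write_germline <- function(gs, fasta_path, metadata_path) {
  stopifnot(inherits(gs, "germline_set"))
  seqs <- Biostrings::DNAStringSet(gs$segments$seq_nt)
  names(seqs) <- gs$segments$id
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(
    gs$segments[, c("id", "chain", "segment_class", "anchor_offset")],
    metadata_path
  )
  invisible(gs)
}

#' Look up one germline segment by id
#'
#' @param gs A `germline_set`.
#' @param id Segment id.
#' @return One-row tibble.
#' @export
germline_segment <- function(gs, id) {
  stopifnot(inherits(gs, "germline_set"))
  row <- gs$segments[gs$segments$id == id, ]
  if (nrow(row) != 1L) abort(sprintf("no germline segment with id '%s'", id))
  row
}

#' Subset germline segments by chain and class
#'
#' @param gs A `germline_set`.
#' @param chain "TRA" or "TRB".
#' @param segment_class "V", "D" or "J".
#' @return Tibble of matching segments (possibly empty).
#' @export
germline_segments <- function(gs, chain, segment_class) {
  stopifnot(inherits(gs, "germline_set"))
  gs$segments[gs$segments$chain == chain &
                gs$segments$segment_class == segment_class, ]
}

#' Junction-facing region of a V segment
#'
#' The 3' portion of the V from the conserved Cys codon onward -- the part
#' of the germline V that can appear inside a junction.
#'
#' @param seg One-row tibble (or list) with `segment_class`, `seq_nt`,
#'   `anchor_offset`.
#' @return Nucleotide string.
#' @export
v_junction_region <- function(seg) {
  if (!identical(seg$segment_class, "V")) {
    abort("v_junction_region() requires a V segment")
  }
  substr(seg$seq_nt, seg$anchor_offset + 1L, nchar(seg$seq_nt))
}

#' Junction-facing region of a J segment
#'
#' The 5' portion of the J up to and including the conserved Phe/Trp codon.
#'
#' @inheritParams v_junction_region
#' @return Nucleotide string.
#' @export
j_junction_region <- function(seg) {
  if (!identical(seg$segment_class, "J")) {
    abort("j_junction_region() requires a J segment")
  }
  substr(seg$seq_nt, 1L, seg$anchor_offset + 3L)
}
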