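# Convenience wrapper chaining assembly -> clonotypes -> TCR types -> ranks.

#' Run the paired clonotyping pipeline on merged contigs
#'
#' Chains [assemble_cells()], [call_clonotypes()], [group_tcr_types()] and
#' [rank_tcr_types()].
#'
#' @param contigs Merged contig tibble from [merge_samples()].
#' @param key_policy Clonotype key policy, see [call_clonotypes()].
#' @param n_top Number of TCR types to rank (default 30).
#' @return List: `cells` (clonotyped cells with `clonotype_id` and
#'   `tcr_type_id`), `clonotypes`, `tcr_types` (ranked) and
#'   `n_excluded_single_chain`.
#' @export
clonotype_pipeline <- function(contigs, key_policy = "genes+nt", n_top = 30) {
  cells <- assemble_cells(contigs)
  ct <- call_clonotypes(cells, key_policy = key_policy)
  tt <- group_tcr_types(ct$clonotypes)
  ranked <- rank_tcr_types(tt$tcr_types, n = n_top)
  cells_out <- dplyr::left_join(
    ct$cells, tt$clonotypes[, c("clonotype_id", "tcr_type_id")],
    by = "clonotype_id"
  )
  list(cells = cells_out, clonotypes = tt$clonotypes, tcr_types = ranked,
       n_excluded_single_chain = ct$n_excluded_single_chain)
}
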