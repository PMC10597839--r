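# Small fixtures built in code.

toy_germline_tbl <- function() {
  tibble::tibble(
    id = c("TRAV1", "TRAJ1", "TRBV1", "TRBV2", "TRBD1", "TRBJ1", "TRBJ2"),
    chain = c("TRA", "TRA", "TRB", "TRB", "TRB", "TRB", "TRB"),
    segment_class = c("V", "J", "V", "V", "D", "J", "J"),
    seq_nt = c(
      "AAATGTGCC",            # TRA V: region TGTGCC
      "GAAACGTTCGGT",         # TRA J: region GAAACGTTC (anchor TTC)
      "CCCTGTGCCAGC",         # TRB V: region TGTGCCAGC
      "CCCTGCGCAAGT",         # TRB V: region TGCGCAAGT
      "GGGACAGGGGGC",         # TRB D
      "AACTATTTCGAG",         # TRB J: region AACTATTTC (anchor TTC)
      "GAACAGTGGACT"          # TRB J: region GAACAGTGG (anchor TGG)
    ),
    anchor_offset = c(3L, 6L, 3L, 3L, NA, 6L, 6L)
  )
}

toy_germline <- function() germline_set(toy_germline_tbl())

# write a 10x-dialect contig CSV from a tibble of fields
write_toy_contig_csv <- function(rows, path) {
  readr::write_csv(rows, path)
  path
}

toy_contig_rows <- function() {
  tibble::tibble(
    barcode = c("AAAC-1", "AAAC-1", "AAAG-1", "AAAG-1", "AAAT-1", "AAAT-1"),
    chain = c("TRA", "TRB", "TRA", "TRB", "TRG", "TRG"),
    v_gene = c("TRAV1", "TRBV1", "TRAV1", "TRBV2", "TRGV1", "TRGV2"),
    d_gene = c("None", "TRBD1", "None", "TRBD1", "None", "None"),
    j_gene = c("TRAJ1", "TRBJ1", "TRAJ1", "TRBJ1", "TRGJ1", "TRGJ1"),
    cdr3 = c("CAF", "CASF", "CAF", "CATF", "CG", "CG"),
    cdr3_nt = c("TGTGCCTTT", "TGTGCCAGCTTT", "TGTGCCTTC", "TGTGCAACCTTT",
                "TGTGGG", "TGTGGG"),
    productive = c("True", "True", "true", "None", "True", "True"),
    umis = c(5L, 7L, 3L, 2L, 1L, 1L),
    reads = c(50L, 70L, 30L, 20L, 10L, 10L)
  )
}

# a small, fast study configuration for unit tests
small_config <- function(seed, doublet_rate = 0.05, n_cells = 200, ...) {
  simulation_config(seed = seed, n_clones = 12, n_cells = n_cells,
                    doublet_rate = doublet_rate, ...)
}
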