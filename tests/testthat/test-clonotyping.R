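test_that("translation follows the standard code", {
  expect_equal(translate_nt("TGTGCTAGC"), "CAS")
  expect_equal(translate_nt(""), "")
  expect_equal(translate_nt("TGA"), "*")
  expect_error(translate_nt("TGTG"), "multiple of 3")
  expect_error(translate_nt("TGN"), "non-ACGT")

  # 300-codon random sequence vs the literal codon-table oracle
  set.seed(99)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE), collapse = "")
  }, character(1))
  expect_equal(translate_nt(seqs), oracle_translate(seqs))
})

make_contig <- function(cell_id, chain, junction_nt, umis = 5L, reads = 50L,
                        productive = TRUE, v = "V1", d = NA_character_,
                        j = "J1") {
  tibble::tibble(
    barcode = sub("^s1_", "", cell_id), sample_id = "s1", cell_id = cell_id,
    chain = chain, v_gene = v, d_gene = d, j_gene = j,
    junction_nt = junction_nt, junction_aa = translate_nt(junction_nt),
    productive = productive, umis = umis, reads = reads
  )
}

test_that("cell assembly pairs chains and applies the top-UMI tie rules", {
  contigs <- dplyr::bind_rows(
    make_contig("s1_a", "TRA", "TGTGCCTTT"),
    make_contig("s1_a", "TRB", "TGTGCCAGCTTT"),
    make_contig("s1_b", "TRA", "TGTGCATTT", umis = 5L),
    make_contig("s1_b", "TRA", "TGTGCGTTT", umis = 9L),
    make_contig("s1_b", "TRB", "TGTGCCAGCTTT"),
    make_contig("s1_c", "TRB", "TGTTTTAGCTTT"),
    make_contig("s1_d", "TRA", "TGTAAATTT", productive = FALSE)
  )
  cells <- assemble_cells(contigs)
  expect_equal(sort(cells$cell_id), c("s1_a", "s1_b", "s1_c"))  # d dropped
  a <- cells[cells$cell_id == "s1_a", ]
  expect_false(a$multi_tra)
  b <- cells[cells$cell_id == "s1_b", ]
  expect_equal(b$tra_junction_nt, "TGTGCGTTT")  # 9 umis beats 5
  expect_equal(b$tra_umis, 9L)
  expect_true(b$multi_tra)
  expect_false(b$multi_trb)
  c_ <- cells[cells$cell_id == "s1_c", ]
  expect_true(is.na(c_$tra_junction_nt))

  # UMI tie broken by reads, then lexicographic junction
  tie <- dplyr::bind_rows(
    make_contig("s1_e", "TRA", "TGTGCGTTT", umis = 5L, reads = 10L),
    make_contig("s1_e", "TRA", "TGTGCATTT", umis = 5L, reads = 10L),
    make_contig("s1_e", "TRB", "TGTGCCAGCTTT")
  )
  e <- assemble_cells(tie)
  expect_equal(e$tra_junction_nt, "TGTGCATTT")
})

test_that("clonotypes partition cells at nucleotide resolution", {
  contigs <- dplyr::bind_rows(
    make_contig("s1_a", "TRA", "TGTGCCTTT"),
    make_contig("s1_a", "TRB", "TGTGCCAGCTTT"),
    make_contig("s1_b", "TRA", "TGTGCCTTT"),
    make_contig("s1_b", "TRB", "TGTGCCAGCTTT"),
    make_contig("s1_c", "TRA", "TGTGCCTTT"),
    make_contig("s1_c", "TRB", "TGTGCCAGTTTT"),  # synonymous TRB variant
    make_contig("s1_d", "TRA", "TGTGCCTTT")      # single-chain
  )
  res <- call_clonotypes(assemble_cells(contigs))
  expect_equal(nrow(res$clonotypes), 2)
  expect_equal(res$n_excluded_single_chain, 1)
  expect_equal(sort(res$clonotypes$n_cells, decreasing = TRUE), c(2, 1))
  # ids ordered by size
  expect_equal(res$clonotypes$n_cells[res$clonotypes$clonotype_id == "CT0001"], 2)
  # total conservation
  expect_equal(sum(res$clonotypes$n_cells), nrow(res$cells))
})

test_that("clonotype partition equals an independent group-by oracle", {
  bundle <- simulate_study(small_config(seed = 3, doublet_rate = 0))
  cells <- assemble_cells(bundle$contigs)
  res <- call_clonotypes(cells)
  oracle_key <- paste(cells$tra_v, cells$tra_j, cells$tra_junction_nt,
                      cells$trb_v, cells$trb_d, cells$trb_j,
                      cells$trb_junction_nt)
  oracle_groups <- split(cells$cell_id, oracle_key)
  got_groups <- split(res$cells$cell_id, res$cells$clonotype_id)
  normalize <- function(gr) unname(lapply(gr[order(vapply(gr, min, ""))], sort))
  expect_equal(normalize(got_groups), normalize(oracle_groups))

  # assembled pairs equal simulator truth for every singlet cell
  truth <- bundle$cells
  m <- match(truth$cell_id, cells$cell_id)
  expect_false(anyNA(m))
  cl <- bundle$clones[match(truth$clone_id, bundle$clones$clone_id), ]
  expect_equal(cells$tra_junction_nt[m], cl$tra_junction_nt)
  expect_equal(cells$trb_junction_nt[m], cl$trb_junction_nt)
})

test_that("TCR types group synonymous clonotypes and conserve counts", {
  clons <- tibble::tibble(
    clonotype_id = c("CT0001", "CT0002", "CT0003"),
    tra_v = "V1", tra_j = "J1",
    tra_junction_nt = c("TGTGCCTTT", "TGTGCCTTT", "TGTGGGTTT"),
    trb_v = "V2", trb_d = "D1", trb_j = "J2",
    trb_junction_nt = c("TGTGCAAGCTTT", "TGCGCAAGCTTT", "TGTGCAAGCTTT"),
    tra_junction_aa = c("CAF", "CAF", "CGF"),
    trb_junction_aa = c("CASF", "CASF", "CASF"),
    n_cells = c(5L, 2L, 1L)
  )
  res <- group_tcr_types(clons)
  expect_equal(nrow(res$tcr_types), 2)
  conv <- res$tcr_types[res$tcr_types$n_clonotypes == 2, ]
  expect_equal(conv$n_cells, 7)
  expect_equal(sum(res$tcr_types$n_cells), sum(clons$n_cells))
  # synonymous variants of one type necessarily share nt length
  by_type <- split(clons$trb_junction_nt, res$clonotypes$tcr_type_id)
  for (grp in by_type) expect_equal(length(unique(nchar(grp))), 1)

  # corrupted aa is an error
  bad <- clons
  bad$tra_junction_aa[1] <- "CWF"
  expect_error(group_tcr_types(bad), "does not translate")

  # all-distinct aa keys -> one type per clonotype
  uniq <- clons
  uniq$tra_junction_aa <- c("CAF", "CHF", "CGF")
  uniq$tra_junction_nt <- c("TGTGCCTTT", "TGTCACTTT", "TGTGGGTTT")
  expect_equal(nrow(group_tcr_types(uniq)$tcr_types), 3)
})

test_that("ranking is by cells, then clonotypes, then amino-acid key", {
  types <- tibble::tibble(
    tcr_type_id = paste0("TT", 1:4),
    tra_junction_aa = c("CAF", "CBF", "CCF", "CDF"),
    trb_junction_aa = "CASF",
    n_clonotypes = c(1L, 3L, 1L, 1L),
    n_cells = c(10L, 7L, 7L, 2L)
  )
  ranked <- rank_tcr_types(types, n = 30)
  expect_equal(ranked$rank, 1:4)
  expect_equal(ranked$tra_junction_aa[2], "CBF")  # 3 clonotypes beats 1
  expect_equal(rank_tcr_types(types, n = 2)$rank, c(1L, 2L, NA, NA))
  expect_error(rank_tcr_types(types, n = 0), "n must be")

  # independent sort oracle
  o <- order(-types$n_cells, -types$n_clonotypes, types$tra_junction_aa,
             types$trb_junction_aa)
  expect_equal(ranked$tcr_type_id, types$tcr_type_id[o])
})

test_that("grouping is invariant under permutation of input cells", {
  bundle <- simulate_study(small_config(seed = 31, doublet_rate = 0))
  cells <- assemble_cells(bundle$contigs)
  res1 <- group_tcr_types(call_clonotypes(cells)$clonotypes)
  set.seed(1)
  res2 <- group_tcr_types(
    call_clonotypes(cells[sample(nrow(cells)), ])$clonotypes)
  expect_equal(res1$tcr_types, res2$tcr_types)
  expect_equal(res1$clonotypes, res2$clonotypes)
})
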