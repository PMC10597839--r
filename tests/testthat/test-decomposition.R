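test_that("exact germline concatenation decomposes with empty N and P", {
  dec <- decompose_junction("TGTGCCTTTGGC", "TGTGCC", "TTTGGC")
  parts <- setNames(dec$parts$seq, dec$parts$kind)
  expect_equal(unname(parts[c("V", "N1", "J")]), c("TGTGCC", "", "TTTGGC"))
  expect_equal(dec$v_trim, 0L)
  expect_equal(dec$j_trim, 0L)
  expect_false(dec$d_assigned)
  expect_equal(paste(dec$parts$seq, collapse = ""), "TGTGCCTTTGGC")
})

test_that("P nucleotides are labeled greedily at untrimmed ends", {
  # middle GGA between untrimmed V (..CC) and untrimmed J (TT..):
  # GG is the V-end palindrome, A the J-end palindrome, nothing remains for N
  dec <- decompose_junction("TGTGCCGGATTCGGC", "TGTGCC", "TTCGGC")
  parts <- setNames(dec$parts$seq, dec$parts$kind)
  expect_equal(unname(parts["P_V"]), "GG")
  expect_equal(unname(parts["P_J"]), "A")
  expect_equal(unname(parts["N1"]), "")
  # the independent exhaustive labeler agrees
  o <- oracle_label_no_d("TGTGCCGGATTCGGC", "TGTGCC", "TTCGGC")
  expect_equal(as.list(parts[c("V", "P_V", "N1", "P_J", "J")]),
               setNames(o, c("V", "P_V", "N1", "P_J", "J")))

  # a trimmed V end gets no P even if nucleotides happen to be palindromic;
  # the untrimmed J side still claims its palindromic A
  dec2 <- decompose_junction("TGTGCGGATTCGGC", "TGTGCC", "TTCGGC")
  parts2 <- setNames(dec2$parts$seq, dec2$parts$kind)
  expect_equal(dec2$v_trim, 1L)
  expect_equal(unname(parts2["P_V"]), "")
  expect_equal(unname(parts2["N1"]), "GG")
  expect_equal(unname(parts2["P_J"]), "A")
})

test_that("D segments are found by longest exact match with stated ties", {
  vreg <- "TGTGCCAGC"; jreg <- "AACTATTTC"
  d <- c(TRBD1 = "GGGACAGGGGGC")
  jx <- paste0(vreg, "TT", "ACAGGG", "CC", jreg)
  dec <- decompose_junction(jx, vreg, jreg, d)
  expect_true(dec$d_assigned)
  expect_equal(dec$d_id, "TRBD1")
  parts <- setNames(dec$parts$seq, dec$parts$kind)
  expect_equal(unname(parts["D"]), "ACAGGG")
  expect_equal(dec$d5_trim, 3L)
  expect_equal(dec$d3_trim, 3L)
  expect_equal(unname(parts["N1"]), "TT")
  expect_equal(unname(parts["N2"]), "CC")

  # below min_d_match nothing is assigned
  jx2 <- paste0(vreg, "TTACATT", jreg)
  dec2 <- decompose_junction(jx2, vreg, jreg, d, min_d_match = 4)
  expect_false(dec2$d_assigned)

  # junction too short
  expect_error(decompose_junction("TGTGC", vreg, jreg), "2 codons")
})

test_that("TRA decompositions never contain a D block", {
  g <- make_fixture_germline(seed = 4)
  set.seed(4)
  for (i in 1:25) {
    ev <- simulate_recombination(g, "TRA", require_productive = FALSE)
    dec <- decompose_junction(ev$junction_nt,
                              germline_segment(g, ev$v_id),
                              germline_segment(g, ev$j_id))
    expect_false(any(dec$parts$kind %in% c("D", "P_D5", "P_D3", "N2")))
    expect_equal(paste(dec$parts$seq, collapse = ""), ev$junction_nt)
  }
})

test_that("reconstruction holds and greedy agrees with the exhaustive oracle", {
  g <- make_fixture_germline(seed = 17)
  dcands <- germline_segments(g, "TRB", "D")
  set.seed(17)
  for (i in 1:150) {
    ev <- simulate_recombination(g, "TRB", require_productive = FALSE)
    vseg <- germline_segment(g, ev$v_id)
    jseg <- germline_segment(g, ev$j_id)
    dec <- decompose_junction(ev$junction_nt, vseg, jseg, dcands)
    expect_equal(paste(dec$parts$seq, collapse = ""), ev$junction_nt)
    oracle <- enumerate_junction_attributions(ev$junction_nt, vseg, jseg,
                                              dcands)
    expect_equal(dec$v_len, oracle$v_len[1])
    expect_equal(dec$j_len, oracle$j_len[1])
    if (all(is.na(oracle$d_len))) {
      expect_false(dec$d_assigned)
    } else {
      expect_true(dec$d_assigned)
      expect_equal(dec$d_len, oracle$d_len[1])
      # the greedy placement is among the oracle's optimal placements,
      # and is the canonical one under the stated tie-break
      canon <- oracle[order(oracle$d_start, oracle$d_id, oracle$d_offset), ][1, ]
      expect_equal(dec$d_start, canon$d_start)
      expect_equal(dec$d_id, canon$d_id)
    }
  }
})

test_that("raising max_p never decreases germline+P attribution", {
  g <- make_fixture_germline(seed = 23)
  dcands <- germline_segments(g, "TRB", "D")
  set.seed(23)
  for (i in 1:40) {
    ev <- simulate_recombination(g, "TRB", require_productive = FALSE)
    attributed <- function(max_p) {
      dec <- decompose_junction(ev$junction_nt,
                                germline_segment(g, ev$v_id),
                                germline_segment(g, ev$j_id), dcands,
                                max_p = max_p)
      sum(nchar(dec$parts$seq[!dec$parts$kind %in% c("N1", "N2")]))
    }
    vals <- vapply(0:3, attributed, numeric(1))
    expect_true(all(diff(vals) >= 0))
  }
})

test_that("synonymous comparison reports positional mismatches per chain", {
  members <- tibble::tibble(
    clonotype_id = c("CT0001", "CT0002"),
    n_cells = c(4L, 1L),
    tra_junction_nt = c("TGTGCA", "TGCGCA"),
    trb_junction_nt = c("TGTAGC", "TGTAGT")
  )
  prof <- compare_synonymous(members)
  ref <- prof[prof$clonotype_id == "CT0001", ]
  expect_true(all(ref$is_reference))
  expect_true(all(lengths(ref$positions) == 0))
  alt <- prof[prof$clonotype_id == "CT0002", ]
  expect_equal(alt$positions[alt$chain == "TRA"][[1]], 2L)
  expect_equal(alt$positions[alt$chain == "TRB"][[1]], 5L)

  # single member -> empty profile
  single <- compare_synonymous(members[1, ])
  expect_true(all(lengths(single$positions) == 0))

  # unequal lengths signal an upstream invariant breach
  bad <- members
  bad$tra_junction_nt[2] <- "TGTGCATTT"
  expect_error(compare_synonymous(bad), "unequal")
})

test_that("is_synonymous requires equal aa and different nt", {
  c1 <- list(tra_junction_nt = "TGTGCA", trb_junction_nt = "TGTAGC")
  c2 <- list(tra_junction_nt = "TGCGCA", trb_junction_nt = "TGTAGC")
  expect_true(is_synonymous(c1, c2))
  expect_false(is_synonymous(c1, c1))
  c3 <- list(tra_junction_nt = "TGTGGA", trb_junction_nt = "TGTAGC")
  expect_false(is_synonymous(c1, c3))

  # random codon-resampled pairs agree with the translation oracle
  set.seed(12)
  for (i in 1:30) {
    nt <- paste(sample(names(ORACLE_CODONS), 5, replace = TRUE), collapse = "")
    syn <- vapply(seq(1, 13, 3), function(s) {
      codon <- substr(nt, s, s + 2)
      alts <- names(ORACLE_CODONS)[ORACLE_CODONS == ORACLE_CODONS[codon]]
      sample(alts, 1)
    }, character(1))
    nt2 <- paste(syn, collapse = "")
    a <- list(tra_junction_nt = nt, trb_junction_nt = "TGTAGC")
    b <- list(tra_junction_nt = nt2, trb_junction_nt = "TGTAGC")
    expect_equal(is_synonymous(a, b),
                 oracle_translate(nt) == oracle_translate(nt2) && nt != nt2)
  }
})

test_that("repertoire decomposition emits ordered parts per clonotype chain", {
  bundle <- simulate_study(small_config(seed = 6, doublet_rate = 0))
  res <- call_clonotypes(assemble_cells(bundle$contigs))
  dtab <- decompose_repertoire(res$clonotypes, bundle$germline)
  expect_setequal(unique(dtab$chain), c("TRA", "TRB"))
  per <- split(dtab, paste(dtab$clonotype_id, dtab$chain))
  for (grp in per) {
    jx <- paste(grp$seq[order(grp$part_order)], collapse = "")
    chain <- grp$chain[1]
    clon <- res$clonotypes[res$clonotypes$clonotype_id == grp$clonotype_id[1], ]
    target <- if (chain == "TRA") clon$tra_junction_nt else clon$trb_junction_nt
    expect_equal(jx, target)
  }
})
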