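test_that("degenerate parameters give verbatim germline concatenation", {
  g <- make_fixture_germline(seed = 2)
  set.seed(2)
  for (ch in c("TRA", "TRB")) {
    ev <- simulate_recombination(g, ch, trim_p = 1, trim_max = 0,
                                 lambda_n = 0, p_p = 0,
                                 require_productive = FALSE)
    vreg <- v_junction_region(germline_segment(g, ev$v_id))
    jreg <- j_junction_region(germline_segment(g, ev$j_id))
    mid <- if (ch == "TRB") germline_segment(g, ev$d_id)$seq_nt else ""
    expect_equal(ev$junction_nt, paste0(vreg, mid, jreg))
    expect_true(ev$productive)  # fixture regions are stop-free and in frame
  }
})

test_that("a fixed seed reproduces the identical event", {
  g <- make_fixture_germline(seed = 2)
  ev1 <- clonoverge:::with_seed(5, simulate_recombination(g, "TRB"))
  ev2 <- clonoverge:::with_seed(5, simulate_recombination(g, "TRB"))
  expect_identical(ev1, ev2)
})

test_that("events satisfy the construction invariant", {
  g <- make_fixture_germline(seed = 9)
  set.seed(9)
  for (i in 1:100) {
    ch <- if (i %% 2 == 0) "TRA" else "TRB"
    ev <- simulate_recombination(g, ch, require_productive = FALSE)
    expect_equal(event_junction(ev, g), ev$junction_nt)
    # P parts only at untrimmed ends and within max_p
    if (nchar(ev$p_v) > 0) expect_equal(ev$v_trim, 0L)
    if (nchar(ev$p_j) > 0) expect_equal(ev$j_trim, 0L)
    expect_lte(nchar(ev$p_v), 2)
    expect_lte(nchar(ev$p_j), 2)
    if (ch == "TRB") {
      if (nchar(ev$p_d5) > 0) expect_equal(ev$d5_trim, 0L)
      if (nchar(ev$p_d3) > 0) expect_equal(ev$d3_trim, 0L)
    }
  }
  # productive events are in frame and stop-free
  set.seed(10)
  for (i in 1:20) {
    ev <- simulate_recombination(g, "TRB")
    expect_true(ev$productive)
    expect_equal(nchar(ev$junction_nt) %% 3, 0)
    expect_false(grepl("\\*", ev$junction_aa))
  }
})

test_that("N-insertion lengths follow the configured Poisson law", {
  g <- make_fixture_germline(seed = 2)
  set.seed(20)
  total_n <- vapply(1:10000, function(i) {
    ev <- simulate_recombination(g, "TRB", require_productive = FALSE)
    nchar(ev$n1) + nchar(ev$n2)
  }, numeric(1))
  # sum of two Poisson(4): mean 8, sampling error bound of 3 SE
  se <- sqrt(8 / 10000)
  expect_lt(abs(mean(total_n) - 8), 3 * se)
})

test_that("spiked convergent variants share aa and genes but differ in nt", {
  g <- make_fixture_germline(seed = 5)
  set.seed(5)
  vars <- spike_convergent_type(g, n_variants = 5)
  expect_length(vars, 5)
  aa <- vapply(vars, function(v) {
    paste(v$tra$junction_aa, v$trb$junction_aa)
  }, character(1))
  expect_equal(length(unique(aa)), 1)
  nt <- vapply(vars, function(v) {
    paste(v$tra$junction_nt, v$trb$junction_nt)
  }, character(1))
  expect_equal(length(unique(nt)), 5)
  genes <- vapply(vars, function(v) {
    paste(v$tra$v_id, v$tra$j_id, v$trb$v_id, v$trb$d_id, v$trb$j_id)
  }, character(1))
  expect_equal(length(unique(genes)), 1)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_true(is_synonymous(
      list(tra_junction_nt = vars[[i]]$tra$junction_nt,
           trb_junction_nt = vars[[i]]$trb$junction_nt),
      list(tra_junction_nt = vars[[j]]$tra$junction_nt,
           trb_junction_nt = vars[[j]]$trb$junction_nt)
    ))
  }
  # variants remain valid events (construction invariant)
  for (v in vars) {
    expect_equal(event_junction(v$tra, g), v$tra$junction_nt)
    expect_equal(event_junction(v$trb, g), v$trb$junction_nt)
  }
  expect_error(spike_convergent_type(g, 1), "n_variants")
})

test_that("full GFP enrichment labels every cell of a clone reporter-positive", {
  b <- simulate_study(simulation_config(seed = 15, n_clones = 8,
                                        n_cells = 150, doublet_rate = 0,
                                        spike_gfp = 1,
                                        p_gfp = c(control = 0, HCC = 0,
                                                  both = 0)))
  spike_cells <- b$cells[grepl("^S1_", b$cells$clone_id), ]
  expect_gt(nrow(spike_cells), 0)
  expect_true(all(spike_cells$gfp_status == "GFP_pos"))
  other <- b$cells[!grepl("^S1_", b$cells$clone_id), ]
  expect_true(all(other$gfp_status == "GFP_neg"))
})

test_that("zero doublet rate yields no multiplet calls at default demux", {
  b <- simulate_study(simulation_config(seed = 16, n_clones = 8,
                                        n_cells = 200, doublet_rate = 0))
  expect_equal(nrow(b$doublets), 0)
  res <- assign_hashtags(normalize_hashtags(b$hashtag))
  expect_equal(sum(res$call == "multiplet"), 0)
})

test_that("clone sizes follow the configured power law (rank-size check)", {
  cfg <- simulation_config(seed = 30, n_clones = 40, n_cells = 10000,
                           doublet_rate = 0, spikes = list())
  b <- simulate_study(cfg)
  emp <- table(factor(b$cells$clone_id, levels = b$clones$clone_id)) /
    nrow(b$cells)
  ks <- max(abs(cumsum(as.numeric(emp)) - cumsum(b$clones$weight)))
  expect_lt(ks, 0.05)
})

test_that("exported bundles reload into the structures the pipeline expects", {
  dir <- withr::local_tempdir()
  b <- simulate_study(small_config(seed = 7), out_dir = dir)
  expect_true(file.exists(file.path(dir, "truth", "clones.tsv")))
  expect_true(file.exists(file.path(dir, "qc.tsv")))
  ht <- read_hashtag_mtx(file.path(dir, "hashtag"))
  expect_equal(ht, b$hashtag)
  gl <- load_germline(file.path(dir, "germline", "segments.fasta"),
                      file.path(dir, "germline", "segments.tsv"))
  expect_equal(gl$segments, b$germline$segments)
  labs <- readr::read_tsv(file.path(dir, "labels.tsv"), show_col_types = FALSE)
  expect_equal(nrow(labs), nrow(b$cells) + nrow(b$doublets))
  truth <- readr::read_tsv(file.path(dir, "truth", "cell_map.tsv"),
                           show_col_types = FALSE)
  expect_equal(sum(!truth$is_doublet), nrow(b$cells))
})
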