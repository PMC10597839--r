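# Whole-study simulation: clones -> cells -> contigs / hashtags / QC / labels,
# plus truth tables, exported in the formats the ingestion modules read.

event_cols <- function(event, prefix) {
  out <- event[c("v_id", "d_id", "j_id", "v_trim", "d5_trim", "d3_trim",
                 "j_trim", "p_v", "p_d5", "p_d3", "p_j", "n1", "n2",
                 "junction_nt", "junction_aa")]
  names(out) <- paste0(prefix, "_", c("v", "d", "j", "v_trim", "d5_trim",
                                      "d3_trim", "j_trim", "p_v", "p_d5",
                                      "p_d3", "p_j", "n1", "n2",
                                      "junction_nt", "junction_aa"))
  tibble::as_tibble(out[!vapply(out, is.null, logical(1))])
}

clone_key <- function(tra, trb) {
  paste(tra$v_id, tra$j_id, tra$junction_nt,
        trb$v_id, trb$d_id, trb$j_id, trb$junction_nt, sep = "|")
}

unique_barcodes <- function(n, width = 14) {
  bc <- replicate(n, paste0(random_nt(width), "-1"))
  while (anyDuplicated(bc)) {
    dup <- duplicated(bc)
    bc[dup] <- replicate(sum(dup), paste0(random_nt(width), "-1"))
  }
  bc
}

#' Simulate a complete hashed multi-mouse paired TCR study
#'
#' Draws clones (regular clones plus configured convergent spikes), expands
#' them into cells under the power-law size law, assigns each cell to a mouse
#' of its clone's condition, attaches reporter and cluster labels, simulates
#' hashtag counts (with doublets whose parents sit on distinct mice), QC
#' metrics and occasional non-productive extra contigs, and optionally
#' exports everything to disk. All sampling uses a single stream seeded from
#' `config$seed`, so bundles are reproducible.
#'
#' @param config A [simulation_config()].
#' @param out_dir If non-`NULL`, export the bundle there (see
#'   [write_study_bundle()]).
#' @return A list bundle: `germline`, `clones` (one row per clone with truth
#'   event fields), `cells` (singlets with clone, mouse and labels),
#'   `doublets`, `contigs` (internal contig format incl. `cell_id`),
#'   `hashtag` (cells x mice count matrix), `qc`, `labels`, `config`.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  germline <- config$germline %||% make_fixture_germline(seed = config$seed)

  conds <- names(config$n_mice)
  mice <- unlist(lapply(conds, function(cc) {
    paste0(cc, "_m", seq_len(config$n_mice[[cc]]))
  }))
  mouse_condition <- stats::setNames(
    rep(conds, times = unlist(config$n_mice)), mice)

  # ---- clones -------------------------------------------------------------
  rows <- list()
  keys <- character()
  add_clone <- function(clone_id, spike_id, condition, weight, p_gfp,
                        tra, trb) {
    tibble::tibble(
      clone_id = clone_id, spike_id = spike_id, condition = condition,
      weight = weight, p_gfp = p_gfp,
      dominant_cluster = sample(config$cluster_ids, 1L,
                                prob = config$cluster_probs)
    ) |>
      dplyr::bind_cols(event_cols(tra, "tra"), event_cols(trb, "trb"))
  }
  for (si in seq_along(config$spikes)) {
    sp <- config$spikes[[si]]
    vars <- spike_convergent_type(germline, sp$n_variants,
                                  config$trim_p, config$trim_max,
                                  config$lambda_n, config$p_p, config$max_p)
    for (vi in seq_along(vars)) {
      rows[[length(rows) + 1L]] <- add_clone(
        sprintf("S%d_V%02d", si, vi), sprintf("S%d", si),
        config$spike_condition, sp$share / sp$n_variants, config$spike_gfp,
        vars[[vi]]$tra, vars[[vi]]$trb
      )
      keys <- c(keys, clone_key(vars[[vi]]$tra, vars[[vi]]$trb))
    }
  }
  reg_w <- seq_len(config$n_clones)^(-config$clone_alpha)
  spike_share <- sum(vapply(config$spikes, function(s) s$share, numeric(1)))
  reg_w <- reg_w / sum(reg_w) * (1 - spike_share)
  for (i in seq_len(config$n_clones)) {
    repeat {
      tra <- simulate_recombination(germline, "TRA", config$trim_p,
                                    config$trim_max, config$lambda_n,
                                    config$p_p, config$max_p)
      trb <- simulate_recombination(germline, "TRB", config$trim_p,
                                    config$trim_max, config$lambda_n,
                                    config$p_p, config$max_p)
      k <- clone_key(tra, trb)
      if (!k %in% keys) break
    }
    keys <- c(keys, k)
    condition <- sample(names(config$p_condition), 1L,
                        prob = config$p_condition)
    rows[[length(rows) + 1L]] <- add_clone(
      sprintf("C%03d", i), NA_character_, condition, reg_w[i],
      config$p_gfp[[condition]], tra, trb
    )
  }
  clones <- dplyr::bind_rows(rows)

  # ---- singlet cells ------------------------------------------------------
  n <- config$n_cells
  clone_idx <- sample.int(nrow(clones), n, replace = TRUE,
                          prob = clones$weight)
  cell_mouse <- vapply(clone_idx, function(ci) {
    cond <- clones$condition[ci]
    pool <- if (cond == "both") mice else mice[mouse_condition == cond]
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  n_doub <- round(config$doublet_rate * n)
  bc <- unique_barcodes(n + n_doub)
  dom <- clones$dominant_cluster[clone_idx]
  other_cluster <- vapply(dom, function(d) {
    pool <- setdiff(config$cluster_ids, d)
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  cells <- tibble::tibble(
    barcode = bc[seq_len(n)],
    sample_id = cell_mouse,
    cell_id = paste(cell_mouse, bc[seq_len(n)], sep = "_"),
    clone_id = clones$clone_id[clone_idx],
    condition = unname(mouse_condition[cell_mouse]),
    gfp_status = ifelse(stats::runif(n) < clones$p_gfp[clone_idx],
                        "GFP_pos", "GFP_neg"),
    cluster = ifelse(stats::runif(n) < config$cluster_purity, dom,
                     other_cluster)
  )

  # ---- doublets (parents on distinct mice) --------------------------------
  doublets <- if (n_doub > 0) {
    p1 <- integer(n_doub); p2 <- integer(n_doub)
    for (d in seq_len(n_doub)) {
      i <- sample.int(n, 1L)
      repeat {
        j <- sample.int(n, 1L)
        if (cells$sample_id[j] != cells$sample_id[i]) break
      }
      p1[d] <- i; p2[d] <- j
    }
    dbc <- bc[n + seq_len(n_doub)]
    tibble::tibble(
      barcode = dbc,
      sample_id = cells$sample_id[p1],
      cell_id = paste(cells$sample_id[p1], dbc, sep = "_"),
      parent1 = cells$cell_id[p1],
      parent2 = cells$cell_id[p2],
      mouse1 = cells$sample_id[p1],
      mouse2 = cells$sample_id[p2]
    )
  } else {
    tibble::tibble(barcode = character(), sample_id = character(),
                   cell_id = character(), parent1 = character(),
                   parent2 = character(), mouse1 = character(),
                   mouse2 = character())
  }

  # ---- contigs ------------------------------------------------------------
  chain_contigs <- function(cell_tbl, idx, chain) {
    pre <- if (chain == "TRA") "tra" else "trb"
    k <- nrow(cell_tbl)
    umis <- stats::rpois(k, 5) + 1L
    dg <- if (chain == "TRB") clones[[paste0(pre, "_d")]][idx]
          else rep(NA_character_, k)
    tibble::tibble(
      barcode = cell_tbl$barcode, sample_id = cell_tbl$sample_id,
      cell_id = cell_tbl$cell_id, chain = chain,
      v_gene = clones[[paste0(pre, "_v")]][idx],
      d_gene = dg,
      j_gene = clones[[paste0(pre, "_j")]][idx],
      junction_nt = clones[[paste0(pre, "_junction_nt")]][idx],
      junction_aa = clones[[paste0(pre, "_junction_aa")]][idx],
      productive = TRUE,
      umis = umis, reads = umis * 12L + stats::rpois(k, 30)
    )
  }
  contig_list <- list(chain_contigs(cells, clone_idx, "TRA"),
                      chain_contigs(cells, clone_idx, "TRB"))
  # ambient non-productive extra contigs
  for (i in which(stats::runif(n) < config$extra_contig_rate)) {
    ch <- sample(c("TRA", "TRB"), 1L)
    ev <- simulate_recombination(germline, ch, config$trim_p,
                                 config$trim_max, config$lambda_n,
                                 config$p_p, config$max_p,
                                 require_productive = FALSE)
    if (ev$productive) next
    umis <- stats::rpois(1L, 2) + 1L
    contig_list[[length(contig_list) + 1L]] <- tibble::tibble(
      barcode = cells$barcode[i], sample_id = cells$sample_id[i],
      cell_id = cells$cell_id[i], chain = ch,
      v_gene = ev$v_id, d_gene = ev$d_id, j_gene = ev$j_id,
      junction_nt = ev$junction_nt, junction_aa = ev$junction_aa,
      productive = FALSE, umis = umis,
      reads = umis * 12L + stats::rpois(1L, 30)
    )
  }
  if (nrow(doublets) > 0) {
    for (parent in c("parent1", "parent2")) {
      pidx <- match(doublets[[parent]], cells$cell_id)
      dcells <- tibble::tibble(barcode = doublets$barcode,
                               sample_id = doublets$sample_id,
                               cell_id = doublets$cell_id)
      cidx <- match(cells$clone_id[pidx], clones$clone_id)
      contig_list <- c(contig_list,
                       list(chain_contigs(dcells, cidx, "TRA"),
                            chain_contigs(dcells, cidx, "TRB")))
    }
  }
  contigs <- dplyr::bind_rows(contig_list)

  # ---- hashtag counts -----------------------------------------------------
  all_ids <- c(cells$cell_id, doublets$cell_id)
  n_ids <- length(all_ids)
  ht <- matrix(stats::rnbinom(n_ids * length(mice),
                              mu = config$hashtag_background_mean,
                              size = config$hashtag_background_size),
               nrow = n_ids, ncol = length(mice),
               dimnames = list(all_ids, mice))
  sig <- function(k) stats::rnbinom(k, mu = config$hashtag_signal_mean,
                                    size = config$hashtag_signal_size)
  ht[cbind(seq_len(n), match(cells$sample_id, mice))] <- sig(n)
  if (nrow(doublets) > 0) {
    drow <- n + seq_len(nrow(doublets))
    ht[cbind(drow, match(doublets$mouse1, mice))] <- sig(nrow(doublets))
    ht[cbind(drow, match(doublets$mouse2, mice))] <- sig(nrow(doublets))
  }

  # ---- QC and labels ------------------------------------------------------
  qc <- tibble::tibble(
    cell_id = all_ids,
    total_counts = round(stats::rlnorm(n_ids, config$qc_counts_meanlog,
                                       config$qc_counts_sdlog)),
    mito_pct = stats::rbeta(n_ids, config$qc_mito_shape1,
                            config$qc_mito_shape2) * 100
  )
  labels <- cells[, c("barcode", "sample_id", "gfp_status", "condition",
                      "cluster")]
  if (nrow(doublets) > 0) {
    dl <- tibble::tibble(
      barcode = doublets$barcode, sample_id = doublets$sample_id,
      gfp_status = cells$gfp_status[match(doublets$parent1, cells$cell_id)],
      condition = unname(mouse_condition[doublets$sample_id]),
      cluster = cells$cluster[match(doublets$parent1, cells$cell_id)]
    )
    labels <- dplyr::bind_rows(labels, dl)
  }

  bundle <- list(germline = germline, clones = clones, cells = cells,
                 doublets = doublets, contigs = contigs, hashtag = ht,
                 qc = qc, labels = labels, config = config)
  if (!is.null(out_dir)) {
    write_study_bundle(bundle, out_dir)
    bundle$out_dir <- out_dir
  }
  bundle
}

#' Export a simulated study bundle to disk
#'
#' Writes one 10x-dialect `<mouse>_filtered_contig_annotations.csv` per
#' mouse, a hashtag MTX triplet under `hashtag/`, `qc.tsv`, `labels.tsv`,
#' the germline FASTA/TSV under `germline/`, and truth tables under `truth/`
#' (`clones.tsv` with the full recombination events, `cell_map.tsv` mapping
#' cells to clones and mice, doublets included).
#'
#' @param bundle List from [simulate_study()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, `out_dir`.
#' @export
write_study_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  na_none <- function(x) ifelse(is.na(x), "None", x)
  for (mouse in unique(bundle$contigs$sample_id)) {
    sub <- bundle$contigs[bundle$contigs$sample_id == mouse, ]
    out <- tibble::tibble(
      barcode = sub$barcode,
      is_cell = "True",
      contig_id = paste0(sub$barcode, "_contig_", seq_len(nrow(sub))),
      high_confidence = "True",
      length = nchar(sub$junction_nt) + 450L,
      chain = sub$chain,
      v_gene = na_none(sub$v_gene),
      d_gene = na_none(sub$d_gene),
      j_gene = na_none(sub$j_gene),
      c_gene = ifelse(sub$chain == "TRA", "TRAC", "TRBC1"),
      full_length = "True",
      productive = ifelse(sub$productive, "True", "None"),
      cdr3 = na_none(sub$junction_aa),
      cdr3_nt = sub$junction_nt,
      reads = sub$reads,
      umis = sub$umis,
      raw_clonotype_id = "None"
    )
    readr::write_csv(
      out, file.path(out_dir,
                     sprintf("%s_filtered_contig_annotations.csv", mouse)))
  }
  write_hashtag_mtx(bundle$hashtag, file.path(out_dir, "hashtag"))
  readr::write_tsv(bundle$qc, file.path(out_dir, "qc.tsv"))
  readr::write_tsv(bundle$labels, file.path(out_dir, "labels.tsv"))
  dir.create(file.path(out_dir, "germline"), showWarnings = FALSE)
  write_germline(bundle$germline,
                 file.path(out_dir, "germline", "segments.fasta"),
                 file.path(out_dir, "germline", "segments.tsv"))
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  readr::write_tsv(bundle$clones, file.path(out_dir, "truth", "clones.tsv"))
  cell_map <- dplyr::bind_rows(
    tibble::tibble(cell_id = bundle$cells$cell_id,
                   barcode = bundle$cells$barcode,
                   sample_id = bundle$cells$sample_id,
                   clone_id = bundle$cells$clone_id,
                   is_doublet = FALSE,
                   parent1 = NA_character_, parent2 = NA_character_),
    tibble::tibble(cell_id = bundle$doublets$cell_id,
                   barcode = bundle$doublets$barcode,
                   sample_id = bundle$doublets$sample_id,
                   clone_id = NA_character_,
                   is_doublet = TRUE,
                   parent1 = bundle$doublets$parent1,
                   parent2 = bundle$doublets$parent2)
  )
  readr::write_tsv(cell_map, file.path(out_dir, "truth", "cell_map.tsv"))
  invisible(out_dir)
}
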