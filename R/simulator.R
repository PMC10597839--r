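# Ground-truth repertoire simulator.
#
# Generates paired TRA/TRB rearrangements from a germline set with a
# trimming / P-addition / N-insertion model, expands them into clones under a
# power-law size law, plants convergent (synonymous-variant) TCR types,
# attaches condition / reporter / cluster labels, synthesizes per-mouse
# hashtag count profiles with doublets plus per-cell QC metrics, and exports
# everything in the formats the ingestion modules read, alongside truth
# tables. All randomness flows through one seeded stream per run.

NT <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: four control and
#' four tumor-bearing mice pooled in one hashed run, ~2,000 paired CD4 T
#' cells over 50 clones expanded under a power law, one planted 5-variant
#' convergent TCR type concentrated in the tumor condition and enriched for
#' the reporter-positive compartment, hashing depth of a few hundred signal
#' UMIs against a low background, and a 5% doublet rate.
#'
#' @param seed Integer seed for the run's single random stream.
#' @param n_clones Number of regular (non-spike) clones.
#' @param n_cells Total number of singlet cells.
#' @param clone_alpha Power-law exponent: clone k gets weight `k^-alpha`.
#' @param n_mice Named integer vector, mice per condition.
#' @param trim_p,trim_max Truncated-geometric trimming law per germline end:
#'   `min(rgeom(p), trim_max)` (further capped so anchors survive).
#' @param lambda_n Poisson mean of each N-insertion length.
#' @param p_p Probability of a P addition at an untrimmed germline end.
#' @param max_p Maximum P length.
#' @param spikes List of `list(n_variants =, share =)` convergent spikes.
#' @param spike_condition Condition the spike clones are confined to.
#' @param p_condition Named probabilities that a clone is confined to each
#'   condition or present in `both`.
#' @param p_gfp Named per-condition probability that a cell of a clone is
#'   reporter-positive; `spike_gfp` overrides it for spike clones.
#' @param spike_gfp See `p_gfp`.
#' @param cluster_ids,cluster_probs Synthetic cluster labels and the law for
#'   a clone's dominant cluster.
#' @param cluster_purity Probability a cell carries its clone's dominant
#'   cluster (otherwise one of the others, uniformly).
#' @param hashtag_signal_mean,hashtag_signal_size Negative-binomial law of
#'   the cell's own hashtag counts.
#' @param hashtag_background_mean,hashtag_background_size Law of the other
#'   hashtags' counts.
#' @param doublet_rate Doublets as a fraction of `n_cells`; doublet parents
#'   are drawn from distinct mice.
#' @param extra_contig_rate Probability a cell carries an additional
#'   non-productive contig.
#' @param qc_counts_meanlog,qc_counts_sdlog Log-normal law of per-cell total
#'   counts.
#' @param qc_mito_shape1,qc_mito_shape2 Beta law (x100) of the mitochondrial
#'   percentage.
#' @param germline Optional `germline_set`; default is
#'   [make_fixture_germline()] at this config's seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_clones = 50,
                              n_cells = 2000,
                              clone_alpha = 1,
                              n_mice = c(control = 4, HCC = 4),
                              trim_p = 0.5, trim_max = 4,
                              lambda_n = 4, p_p = 0.5, max_p = 2,
                              spikes = list(list(n_variants = 5, share = 0.05)),
                              spike_condition = "HCC",
                              p_condition = c(control = 0.3, HCC = 0.6,
                                              both = 0.1),
                              p_gfp = c(control = 0.2, HCC = 0.7, both = 0.45),
                              spike_gfp = 0.9,
                              cluster_ids = c("C3", "C7", "C9"),
                              cluster_probs = c(0.5, 0.3, 0.2),
                              cluster_purity = 0.8,
                              hashtag_signal_mean = 200,
                              hashtag_signal_size = 20,
                              hashtag_background_mean = 2,
                              hashtag_background_size = 1,
                              doublet_rate = 0.05,
                              extra_contig_rate = 0.05,
                              qc_counts_meanlog = log(12000),
                              qc_counts_sdlog = 0.5,
                              qc_mito_shape1 = 2,
                              qc_mito_shape2 = 18,
                              germline = NULL) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg$spikes, function(s) s$n_variants >= 2, logical(1))))
  probs <- c(cfg$p_p, cfg$p_condition, cfg$p_gfp, cfg$spike_gfp,
             cfg$doublet_rate, cfg$extra_contig_rate, cfg$cluster_purity)
  stopifnot(all(probs >= 0 & probs <= 1))
  structure(cfg, class = "simulation_config")
}

trim_draw <- function(trim_p, trim_max, max_allowed) {
  min(stats::rgeom(1L, trim_p), trim_max, max_allowed)
}

#' Simulate one V(D)J recombination event
#'
#' Draws segments uniformly, trims each germline end by a truncated
#' geometric, adds P nucleotides (reverse complement of the untrimmed
#' terminus) with probability `p_p`, inserts Poisson-length random N runs,
#' and concatenates. With `require_productive = TRUE` the draw is repeated
#' until the junction is in frame and stop-free (at most `max_attempts`
#' times).
#'
#' @param germline A `germline_set`.
#' @param chain "TRA" or "TRB".
#' @inheritParams simulation_config
#' @param require_productive Rejection-sample to a productive junction.
#' @param max_attempts Rejection bound (error beyond it).
#' @return A `recombination_event` list: segment ids, the four trim lengths,
#'   P and N part strings, `junction_nt`, `junction_aa` (NA when out of
#'   frame), `productive`.
#' @export
simulate_recombination <- function(germline, chain,
                                   trim_p = 0.5, trim_max = 4,
                                   lambda_n = 4, p_p = 0.5, max_p = 2,
                                   require_productive = TRUE,
                                   max_attempts = 1000) {
  vs <- germline_segments(germline, chain, "V")
  js <- germline_segments(germline, chain, "J")
  ds <- germline_segments(germline, chain, "D")
  if (nrow(vs) == 0 || nrow(js) == 0) {
    abort(sprintf("germline lacks V or J segments for %s", chain))
  }
  has_d <- nrow(ds) > 0
  for (attempt in seq_len(max_attempts)) {
    vrow <- vs[sample.int(nrow(vs), 1L), ]
    jrow <- js[sample.int(nrow(js), 1L), ]
    vreg <- v_junction_region(vrow)
    jreg <- j_junction_region(jrow)
    v_trim <- trim_draw(trim_p, trim_max, nchar(vreg) - 3L)
    j_trim <- trim_draw(trim_p, trim_max, nchar(jreg) - 3L)
    p_part <- function(trim, source) {
      if (trim == 0L && stats::runif(1) < p_p) {
        source(sample.int(max_p, 1L))
      } else ""
    }
    p_v <- p_part(v_trim, function(p) {
      revcomp_nt(substr(vreg, nchar(vreg) - p + 1L, nchar(vreg)))
    })
    p_j <- p_part(j_trim, function(p) revcomp_nt(substr(jreg, 1L, p)))
    n1 <- random_nt(stats::rpois(1L, lambda_n))
    if (has_d) {
      drow <- ds[sample.int(nrow(ds), 1L), ]
      dseq <- drow$seq_nt
      d5_trim <- trim_draw(trim_p, trim_max, nchar(dseq) - 1L)
      d3_trim <- trim_draw(trim_p, trim_max, nchar(dseq) - d5_trim - 1L)
      d_part_seq <- substr(dseq, d5_trim + 1L, nchar(dseq) - d3_trim)
      p_d5 <- p_part(d5_trim, function(p) revcomp_nt(substr(dseq, 1L, p)))
      p_d3 <- p_part(d3_trim, function(p) {
        revcomp_nt(substr(dseq, nchar(dseq) - p + 1L, nchar(dseq)))
      })
      n2 <- random_nt(stats::rpois(1L, lambda_n))
      junction <- paste0(
        substr(vreg, 1L, nchar(vreg) - v_trim), p_v, n1,
        p_d5, d_part_seq, p_d3, n2,
        p_j, substr(jreg, j_trim + 1L, nchar(jreg))
      )
      d_id <- drow$id
    } else {
      d_id <- NA_character_
      d5_trim <- NA_integer_; d3_trim <- NA_integer_
      p_d5 <- ""; p_d3 <- ""; n2 <- ""
      junction <- paste0(
        substr(vreg, 1L, nchar(vreg) - v_trim), p_v, n1,
        p_j, substr(jreg, j_trim + 1L, nchar(jreg))
      )
    }
    in_frame <- nchar(junction) %% 3L == 0L
    aa <- if (in_frame) translate_nt(junction) else NA_character_
    productive <- in_frame && !grepl("\\*", aa)
    if (!require_productive || productive) {
      return(structure(list(
        chain = chain, v_id = vrow$id, d_id = d_id, j_id = jrow$id,
        v_trim = as.integer(v_trim), d5_trim = as.integer(d5_trim),
        d3_trim = as.integer(d3_trim), j_trim = as.integer(j_trim),
        p_v = p_v, p_d5 = p_d5, p_d3 = p_d3, p_j = p_j,
        n1 = n1, n2 = n2,
        junction_nt = junction, junction_aa = aa,
        productive = productive
      ), class = "recombination_event"))
    }
  }
  abort("could not draw a productive rearrangement within max_attempts; the configuration is pathological")
}

#' Reconstruct an event's junction from its stored parts
#'
#' @param event A `recombination_event`.
#' @param germline The `germline_set` it was drawn from.
#' @return The junction nucleotide string implied by segments, trims, P and N
#'   parts; equals `event$junction_nt` for any valid event.
#' @export
event_junction <- function(event, germline) {
  vreg <- v_junction_region(germline_segment(germline, event$v_id))
  jreg <- j_junction_region(germline_segment(germline, event$j_id))
  mid <- if (!is.na(event$d_id)) {
    dseq <- germline_segment(germline, event$d_id)$seq_nt
    paste0(event$p_d5,
           substr(dseq, event$d5_trim + 1L, nchar(dseq) - event$d3_trim),
           event$p_d3, event$n2)
  } else {
    ""
  }
  paste0(substr(vreg, 1L, nchar(vreg) - event$v_trim), event$p_v, event$n1,
         mid, event$p_j, substr(jreg, event$j_trim + 1L, nchar(jreg)))
}

# true part boundaries of an event within its junction (1-based)
event_boundaries <- function(event, germline) {
  vreg <- v_junction_region(germline_segment(germline, event$v_id))
  jreg <- j_junction_region(germline_segment(germline, event$j_id))
  v_len <- nchar(vreg) - event$v_trim
  j_len <- nchar(jreg) - event$j_trim
  if (!is.na(event$d_id)) {
    dseq <- germline_segment(germline, event$d_id)$seq_nt
    d_len <- nchar(dseq) - event$d5_trim - event$d3_trim
    d_start <- v_len + nchar(event$p_v) + nchar(event$n1) +
      nchar(event$p_d5) + 1L
  } else {
    d_len <- NA_integer_; d_start <- NA_integer_
  }
  list(v_len = v_len, j_len = j_len, d_start = d_start, d_len = d_len)
}

# synonymous single-substitution options within the N parts of an event
synonymous_n_options <- function(event, germline) {
  b <- event_boundaries(event, germline)
  jx <- event$junction_nt
  n1_start <- b$v_len + nchar(event$p_v) + 1L
  spans <- list(c(n1_start, n1_start + nchar(event$n1) - 1L))
  if (!is.na(event$d_id) && nchar(event$n2) > 0) {
    n2_start <- b$d_start + b$d_len + nchar(event$p_d3)
    spans <- c(spans, list(c(n2_start, n2_start + nchar(event$n2) - 1L)))
  }
  opts <- list()
  for (sp in spans) {
    if (sp[2] < sp[1]) next
    for (pos in sp[1]:sp[2]) {
      codon_start <- ((pos - 1L) %/% 3L) * 3L + 1L
      codon <- substr(jx, codon_start, codon_start + 2L)
      if (nchar(codon) < 3L) next
      within <- pos - codon_start + 1L
      cur <- substr(codon, within, within)
      for (alt in setdiff(NT, cur)) {
        cand <- codon
        substr(cand, within, within) <- alt
        if (translate_nt(cand) == translate_nt(codon)) {
          opts[[length(opts) + 1L]] <- list(pos = pos, alt = alt)
        }
      }
    }
  }
  opts
}

apply_n_substitution <- function(event, pos, alt, germline) {
  b <- event_boundaries(event, germline)
  jx <- event$junction_nt
  substr(jx, pos, pos) <- alt
  n1_start <- b$v_len + nchar(event$p_v) + 1L
  if (pos >= n1_start && pos < n1_start + nchar(event$n1)) {
    off <- pos - n1_start + 1L
    substr(event$n1, off, off) <- alt
  } else {
    n2_start <- b$d_start + b$d_len + nchar(event$p_d3)
    off <- pos - n2_start + 1L
    stopifnot(off >= 1L, off <= nchar(event$n2))
    substr(event$n2, off, off) <- alt
  }
  event$junction_nt <- jx
  event
}

#' Plant a convergent TCR type of synonymous nucleotide variants
#'
#' Draws a productive paired (TRA, TRB) base rearrangement, then derives
#' `n_variants - 1` further valid events by substituting synonymous
#' alternatives at wobble positions that fall inside the base event's
#' N-insertion parts; bases are redrawn (rejection) until enough synonymous
#' options exist. All variants share the base's V/D/J combination, trims and
#' P parts, encode the identical paired amino-acid sequence, and differ
#' pairwise at the nucleotide level.
#'
#' @inheritParams simulate_recombination
#' @param n_variants Number of synonymous clonotype variants (>= 2).
#' @return List of length `n_variants`; each element is
#'   `list(tra = <event>, trb = <event>)`.
#' @export
spike_convergent_type <- function(germline, n_variants,
                                  trim_p = 0.5, trim_max = 4,
                                  lambda_n = 4, p_p = 0.5, max_p = 2,
                                  max_attempts = 200) {
  if (n_variants < 2) abort("n_variants must be >= 2")
  for (attempt in seq_len(max_attempts)) {
    base <- list(
      tra = simulate_recombination(germline, "TRA", trim_p, trim_max,
                                   lambda_n, p_p, max_p),
      trb = simulate_recombination(germline, "TRB", trim_p, trim_max,
                                   lambda_n, p_p, max_p)
    )
    opts <- c(
      lapply(synonymous_n_options(base$tra, germline), function(o) {
        c(o, list(chain = "tra"))
      }),
      lapply(synonymous_n_options(base$trb, germline), function(o) {
        c(o, list(chain = "trb"))
      })
    )
    if (length(opts) >= n_variants - 1L) {
      variants <- list(base)
      for (i in seq_len(n_variants - 1L)) {
        o <- opts[[i]]
        var <- base
        var[[o$chain]] <- apply_n_substitution(var[[o$chain]], o$pos, o$alt,
                                               germline)
        variants[[length(variants) + 1L]] <- var
      }
      return(variants)
    }
  }
  abort(paste0("could not plant a convergent type within max_attempts; ",
               "increase lambda_n so junctions carry more N nucleotides"))
}
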