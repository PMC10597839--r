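# V(D)J junction decomposition.
#
# A junction nucleotide sequence is partitioned into ordered parts
#   V | P_V | N1 | P_D5 | D | P_D3 | N2 | P_J | J
# (the D block is absent for TRA) by maximal germline attribution:
#   1. V part: the longest junction prefix matching the V junction region
#      trimmed from its 3' end;
#   2. J part: the longest remaining suffix matching the J junction region
#      trimmed from its 5' end (V wins ties over J by being fixed first);
#   3. D part: the longest contiguous exact match (>= min_d_match) between
#      the middle segment and any candidate D, ties broken by 5'-most
#      placement, then candidate id;
#   4. P nucleotides: assigned greedily (<= max_p per end) only where the
#      adjacent germline end is untrimmed and the junction nucleotides equal
#      the reverse complement of that germline terminus;
#   5. everything left in the middle is non-templated N1/N2.
# The concatenation of the part sequences always reproduces the input
# junction exactly (asserted on every call).
#
# When trimming and insertion conspire so that an inserted nucleotide equals
# the trimmed germline base, maximal attribution will extend a germline part
# past the true recombination boundary. This ambiguity is inherent to the
# sequence (no decomposition algorithm can resolve it); the exhaustive
# reference [enumerate_junction_attributions()] identifies such cases.

PART_ORDER_TRB <- c("V", "P_V", "N1", "P_D5", "D", "P_D3", "N2", "P_J", "J")
PART_ORDER_TRA <- c("V", "P_V", "N1", "P_J", "J")

as_v_region <- function(x) if (is.character(x)) x else v_junction_region(x)
as_j_region <- function(x) if (is.character(x)) x else j_junction_region(x)

as_d_candidates <- function(x) {
  if (is.null(x)) return(character())
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("D", seq_along(x))
    return(x)
  }
  stats::setNames(x$seq_nt, x$id)
}

# longest exact substring match between `middle` and one candidate `d`;
# returns zero-row tibble if no match
longest_d_match <- function(middle, d) {
  n <- nchar(middle); m <- nchar(d)
  if (n == 0L || m == 0L) {
    return(tibble::tibble(len = integer(), start = integer(),
                          d_start = integer()))
  }
  mv <- substring(middle, seq_len(n), seq_len(n))
  dv <- substring(d, seq_len(m), seq_len(m))
  # dp[i, k]: length of common substring ending at middle[i], d[k]
  best <- tibble::tibble(len = 0L, start = 0L, d_start = 0L)[0, ]
  dp_prev <- integer(m)
  for (i in seq_len(n)) {
    dp_cur <- integer(m)
    hit <- which(dv == mv[i])
    for (k in hit) {
      dp_cur[k] <- if (k == 1L) 1L else dp_prev[k - 1L] + 1L
    }
    if (length(hit) > 0) {
      best <- dplyr::bind_rows(best, tibble::tibble(
        len = dp_cur[hit],
        start = i - dp_cur[hit] + 1L,
        d_start = hit - dp_cur[hit] + 1L
      ))
    }
    dp_prev <- dp_cur
  }
  best
}

# greedy palindromic (P) run: longest prefix of `zone` equal to the reverse
# complement of the germline terminus `terminus_rc_source`, read from its end
p_run_left <- function(zone, germ, germ_end = c("3p", "5p"), max_p) {
  # P adjacent to the right side of a germline part (e.g. after V): compare
  # zone prefix against revcomp of the germline 3' terminus
  germ_end <- match.arg(germ_end)
  limit <- min(max_p, nchar(zone), nchar(germ))
  for (p in rev(seq_len(limit))) {
    term <- if (germ_end == "3p") {
      substr(germ, nchar(germ) - p + 1L, nchar(germ))
    } else {
      substr(germ, 1L, p)
    }
    if (substr(zone, 1L, p) == revcomp_nt(term)) return(p)
  }
  0L
}

p_run_right <- function(zone, germ, germ_end = c("5p", "3p"), max_p) {
  # P adjacent to the left side of a germline part (e.g. before J): compare
  # zone suffix against revcomp of the germline 5' terminus
  germ_end <- match.arg(germ_end)
  limit <- min(max_p, nchar(zone), nchar(germ))
  for (p in rev(seq_len(limit))) {
    term <- if (germ_end == "5p") {
      substr(germ, 1L, p)
    } else {
      substr(germ, nchar(germ) - p + 1L, nchar(germ))
    }
    if (substr(zone, nchar(zone) - p + 1L, nchar(zone)) == revcomp_nt(term)) {
      return(p)
    }
  }
  0L
}

#' Decompose a junction into germline V/P/N/D/P/J parts
#'
#' See the algorithm sketch at the top of this file. The V and J inputs may
#' be germline segment rows (anchors are used to derive the junction-facing
#' regions) or the region strings themselves.
#'
#' @param junction_nt Junction nucleotide sequence (anchor-inclusive).
#' @param v_seg V segment row from a [germline_set()], or the V junction
#'   region string.
#' @param j_seg J segment row, or the J junction region string.
#' @param d_candidates D segments to consider: a tibble with `id`/`seq_nt`,
#'   a named character vector, or `NULL` for TRA.
#' @param max_p Maximum P-nucleotide run per germline end (default 2).
#' @param min_d_match Minimum exact D match length to assign a D (default 3).
#' @return Object of class `junction_decomposition`: fields `parts` (tibble
#'   `kind`, `seq`, `germline_id` in linear order; empty parts retained with
#'   `seq = ""`), trim lengths, `d_assigned`, `d_id`, absolute boundary
#'   fields `v_len`, `j_len`, `d_start`, `d_len`, and warning flags
#'   `no_v_overlap`/`no_j_overlap`.
#' @export
decompose_junction <- function(junction_nt, v_seg, j_seg,
                               d_candidates = NULL,
                               max_p = 2, min_d_match = 3) {
  assert_nt(junction_nt, "junction")
  L <- nchar(junction_nt)
  if (L < 6L) abort("junction shorter than 2 codons cannot be decomposed")
  vreg <- as_v_region(v_seg)
  jreg <- as_j_region(j_seg)
  dset <- as_d_candidates(d_candidates)
  has_d_pool <- length(dset) > 0

  v_len <- lcp_len(junction_nt, vreg)
  rest <- substr(junction_nt, v_len + 1L, L)
  j_len <- lcs_len(rest, jreg)
  v_trim <- nchar(vreg) - v_len
  j_trim <- nchar(jreg) - j_len
  middle <- substr(junction_nt, v_len + 1L, L - j_len)

  # D assignment
  d_assigned <- FALSE
  d_id <- NA_character_
  d_len <- 0L; d_start_mid <- NA_integer_; d_offset <- NA_integer_
  d5_trim <- NA_integer_; d3_trim <- NA_integer_
  if (has_d_pool && nchar(middle) >= min_d_match) {
    cand <- dplyr::bind_rows(lapply(sort(names(dset)), function(id) {
      hits <- longest_d_match(middle, dset[[id]])
      if (nrow(hits) == 0) return(hits)
      hits$d_id <- id
      hits
    }))
    cand <- cand[cand$len >= min_d_match, , drop = FALSE]
    if (nrow(cand) > 0) {
      cand <- cand[order(-cand$len, cand$start, cand$d_id, cand$d_start), ]
      top <- cand[1L, ]
      d_assigned <- TRUE
      d_id <- top$d_id
      d_len <- top$len
      d_start_mid <- top$start
      d_offset <- top$d_start
      d5_trim <- top$d_start - 1L
      d3_trim <- nchar(dset[[d_id]]) - (top$d_start - 1L + top$len)
    }
  }

  left_zone <- if (d_assigned) substr(middle, 1L, d_start_mid - 1L) else middle
  right_zone <- if (d_assigned) {
    substr(middle, d_start_mid + d_len, nchar(middle))
  } else {
    ""
  }

  p_v_len <- if (v_trim == 0L && v_len > 0L) {
    p_run_left(left_zone, vreg, "3p", max_p)
  } else 0L
  left_rem <- substr(left_zone, p_v_len + 1L, nchar(left_zone))

  if (d_assigned) {
    dseq <- dset[[d_id]]
    p_d5_len <- if (d5_trim == 0L) p_run_right(left_rem, dseq, "5p", max_p) else 0L
    n1 <- substr(left_rem, 1L, nchar(left_rem) - p_d5_len)
    p_d3_len <- if (d3_trim == 0L) p_run_left(right_zone, dseq, "3p", max_p) else 0L
    right_rem <- substr(right_zone, p_d3_len + 1L, nchar(right_zone))
    p_j_len <- if (j_trim == 0L && j_len > 0L) {
      p_run_right(right_rem, jreg, "5p", max_p)
    } else 0L
    n2 <- substr(right_rem, 1L, nchar(right_rem) - p_j_len)
  } else {
    p_d5_len <- 0L; p_d3_len <- 0L
    p_j_len <- if (j_trim == 0L && j_len > 0L) {
      p_run_right(left_rem, jreg, "5p", max_p)
    } else 0L
    n1 <- substr(left_rem, 1L, nchar(left_rem) - p_j_len)
    n2 <- ""
  }

  seg <- function(from, len) if (len <= 0L) "" else substr(junction_nt, from, from + len - 1L)
  pos <- 1L
  take <- function(len) {
    s <- seg(pos, len)
    pos <<- pos + max(len, 0L)
    s
  }
  v_part <- take(v_len)
  p_v <- take(p_v_len)
  n1_part <- take(nchar(n1))
  if (d_assigned) {
    p_d5 <- take(p_d5_len)
    d_part <- take(d_len)
    p_d3 <- take(p_d3_len)
    n2_part <- take(nchar(n2))
  } else {
    p_d5 <- ""; d_part <- ""; p_d3 <- ""; n2_part <- take(nchar(n2))
  }
  p_j <- take(p_j_len)
  j_part <- take(j_len)

  use_d_block <- has_d_pool
  kinds <- if (use_d_block) PART_ORDER_TRB else PART_ORDER_TRA
  seqs <- if (use_d_block) {
    c(v_part, p_v, n1_part, p_d5, d_part, p_d3, n2_part, p_j, j_part)
  } else {
    c(v_part, p_v, n1_part, p_j, j_part)
  }
  germ_ids <- rep(NA_character_, length(kinds))
  germ_ids[kinds == "V"] <- if (is.character(v_seg)) NA_character_ else v_seg$id
  germ_ids[kinds == "J"] <- if (is.character(j_seg)) NA_character_ else j_seg$id
  germ_ids[kinds == "D"] <- d_id
  parts <- tibble::tibble(kind = kinds, seq = seqs, germline_id = germ_ids)

  stopifnot(identical(paste(parts$seq, collapse = ""), junction_nt))

  structure(list(
    junction_nt = junction_nt,
    parts = parts,
    v_trim = v_trim, d5_trim = d5_trim, d3_trim = d3_trim, j_trim = j_trim,
    d_assigned = d_assigned, d_id = d_id, d_offset = d_offset,
    v_len = v_len, j_len = j_len,
    d_start = if (d_assigned) v_len + d_start_mid else NA_integer_,
    d_len = if (d_assigned) d_len else NA_integer_,
    no_v_overlap = v_len == 0L,
    no_j_overlap = j_len == 0L
  ), class = "junction_decomposition")
}

#' @export
print.junction_decomposition <- function(x, ...) {
  shown <- x$parts[nzchar(x$parts$seq), ]
  cat("<junction_decomposition> ", x$junction_nt, "\n", sep = "")
  cat(paste(sprintf("%s:%s", shown$kind, shown$seq), collapse = " | "), "\n")
  invisible(x)
}

#' Exhaustive reference attribution of a junction
#'
#' Independent, brute-force counterpart of [decompose_junction()]: enumerates
#' every boundary tuple (V prefix length, J suffix length, D placement)
#' consistent with the germline sequences and returns all tuples attaining
#' the lexicographic optimum (max V, then max J, then max D length). Used to
#' validate the greedy decomposer and to detect attribution ambiguity.
#'
#' @inheritParams decompose_junction
#' @return Tibble of optimal tuples: `v_len`, `j_len`, `d_len`, `d_start`
#'   (1-based in the junction; `NA` when no D is assigned), `d_id`,
#'   `d_offset` (1-based match start within the D sequence). More than one
#'   row means the optimum is ambiguous.
#' @export
enumerate_junction_attributions <- function(junction_nt, v_seg, j_seg,
                                            d_candidates = NULL,
                                            min_d_match = 3) {
  vreg <- as_v_region(v_seg)
  jreg <- as_j_region(j_seg)
  dset <- as_d_candidates(d_candidates)
  L <- nchar(junction_nt)

  # all feasible V prefix lengths
  v_ok <- 0L
  for (v in seq_len(min(L, nchar(vreg)))) {
    if (substr(junction_nt, 1L, v) == substr(vreg, 1L, v)) v_ok <- c(v_ok, v)
  }
  best_v <- max(v_ok)
  # all feasible J suffix lengths given best_v
  j_ok <- 0L
  for (j in seq_len(min(L - best_v, nchar(jreg)))) {
    if (substr(junction_nt, L - j + 1L, L) ==
        substr(jreg, nchar(jreg) - j + 1L, nchar(jreg))) {
      j_ok <- c(j_ok, j)
    }
  }
  best_j <- max(j_ok)
  middle <- substr(junction_nt, best_v + 1L, L - best_j)

  if (length(dset) == 0) {
    return(tibble::tibble(v_len = best_v, j_len = best_j,
                          d_len = NA_integer_, d_start = NA_integer_,
                          d_id = NA_character_, d_offset = NA_integer_))
  }
  placements <- list()
  nm <- nchar(middle)
  for (id in sort(names(dset))) {
    dseq <- dset[[id]]
    nd <- nchar(dseq)
    for (s in seq_len(max(nm, 0L))) {
      for (o in seq_len(nd)) {
        len <- 0L
        while (s + len <= nm && o + len <= nd &&
               substr(middle, s + len, s + len) == substr(dseq, o + len, o + len)) {
          len <- len + 1L
        }
        if (len >= min_d_match) {
          placements[[length(placements) + 1L]] <-
            tibble::tibble(d_len = len, d_start = best_v + s, d_id = id,
                           d_offset = o)
        }
      }
    }
  }
  if (length(placements) == 0) {
    return(tibble::tibble(v_len = best_v, j_len = best_j,
                          d_len = NA_integer_, d_start = NA_integer_,
                          d_id = NA_character_, d_offset = NA_integer_))
  }
  pl <- dplyr::distinct(dplyr::bind_rows(placements))
  # keep only maximal placements (drop sub-runs of a longer run)
  pl <- pl[pl$d_len == max(pl$d_len), , drop = FALSE]
  pl$v_len <- best_v
  pl$j_len <- best_j
  pl[, c("v_len", "j_len", "d_len", "d_start", "d_id", "d_offset")]
}

#' Positional mismatches across the synonymous clonotypes of one TCR type
#'
#' Within a TCR type all member junctions of a chain have equal nucleotide
#' length (equal amino-acid sequence forces it); the reference is the largest
#' clonotype (ties broken by clonotype id) and mismatched positions are
#' reported 0-based per member and chain.
#'
#' @param members Tibble with `clonotype_id`, `n_cells`, `tra_junction_nt`,
#'   `trb_junction_nt` for the clonotypes of one TCR type.
#' @return Tibble: `clonotype_id`, `chain`, `is_reference`, `positions`
#'   (list column of 0-based integer vectors).
#' @export
compare_synonymous <- function(members) {
  members <- tibble::as_tibble(members)
  for (col in c("tra_junction_nt", "trb_junction_nt")) {
    if (length(unique(nchar(members[[col]]))) > 1) {
      abort(sprintf(
        "unequal %s lengths within a TCR type: upstream grouping invariant breached",
        col))
    }
  }
  ord <- order(-members$n_cells, members$clonotype_id)
  ref <- members[ord[1L], ]
  rows <- lapply(seq_len(nrow(members)), function(i) {
    pos_for <- function(col) {
      a <- strsplit(members[[col]][i], "")[[1]]
      b <- strsplit(ref[[col]], "")[[1]]
      as.integer(which(a != b) - 1L)
    }
    tibble::tibble(
      clonotype_id = members$clonotype_id[i],
      chain = c("TRA", "TRB"),
      is_reference = members$clonotype_id[i] == ref$clonotype_id,
      positions = list(pos_for("tra_junction_nt"), pos_for("trb_junction_nt"))
    )
  })
  dplyr::bind_rows(rows)
}

#' Are two clonotypes synonymous variants of one TCR type?
#'
#' `TRUE` iff the paired junction amino-acid sequences are identical while
#' the paired nucleotide sequences differ (convergent recombination).
#'
#' @param c1,c2 Lists or one-row tibbles with `tra_junction_nt` and
#'   `trb_junction_nt`.
#' @return Logical scalar.
#' @export
is_synonymous <- function(c1, c2) {
  nt1 <- c(c1$tra_junction_nt, c1$trb_junction_nt)
  nt2 <- c(c2$tra_junction_nt, c2$trb_junction_nt)
  aa_equal <- identical(translate_nt(nt1), translate_nt(nt2))
  aa_equal && !identical(nt1, nt2)
}

#' Decompose every clonotype of a repertoire
#'
#' Runs [decompose_junction()] for each clonotype and chain using the
#' clonotype's V/J gene calls against a germline set; all D segments of the
#' chain are considered as candidates regardless of the upstream D call.
#' Clonotype chains lacking a V or J gene call are skipped with a message.
#'
#' @param clonotypes Clonotype tibble from [call_clonotypes()].
#' @param germline A `germline_set`.
#' @inheritParams decompose_junction
#' @return Long tibble, one row per part: `clonotype_id`, `chain`,
#'   `part_order`, `kind`, `seq`, `germline_id`, the four trim lengths and
#'   `d_assigned`.
#' @export
decompose_repertoire <- function(clonotypes, germline,
                                 max_p = 2, min_d_match = 3) {
  stopifnot(inherits(germline, "germline_set"))
  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(clonotypes))) {
    for (ch in c("TRA", "TRB")) {
      pre <- if (ch == "TRA") "tra" else "trb"
      v_id <- clonotypes[[paste0(pre, "_v")]][i]
      j_id <- clonotypes[[paste0(pre, "_j")]][i]
      jx <- clonotypes[[paste0(pre, "_junction_nt")]][i]
      if (is.na(v_id) || is.na(j_id) || is.na(jx)) {
        n_skipped <- n_skipped + 1L
        next
      }
      dcands <- if (ch == "TRB") germline_segments(germline, "TRB", "D") else NULL
      dec <- decompose_junction(jx, germline_segment(germline, v_id),
                                germline_segment(germline, j_id),
                                d_candidates = dcands,
                                max_p = max_p, min_d_match = min_d_match)
      p <- dec$parts
      p$clonotype_id <- clonotypes$clonotype_id[i]
      p$chain <- ch
      p$part_order <- seq_len(nrow(p))
      p$v_trim <- dec$v_trim
      p$d5_trim <- dec$d5_trim
      p$d3_trim <- dec$d3_trim
      p$j_trim <- dec$j_trim
      p$d_assigned <- dec$d_assigned
      rows[[length(rows) + 1L]] <- p
    }
  }
  if (n_skipped > 0) {
    inform(sprintf("skipped %d clonotype chain(s) lacking V/J gene calls",
                   n_skipped))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out[, c("clonotype_id", "chain", "part_order", "kind", "seq", "germline_id",
          "v_trim", "d5_trim", "d3_trim", "j_trim", "d_assigned")]
}
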