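# Synthetic germline reference used by the simulator and the test suite.
# The segments are generated, not copied from any database: junction-facing
# regions are built from stop-free codons so that an untrimmed, insertion-free
# V(+D)+J concatenation is always in frame and translatable, which the
# decomposition and simulator modules rely on.

# codons that cannot introduce a stop in frame 0
SAFE_CODONS <- c("GCC", "AGC", "GGG", "ACA", "CTG", "TAT", "GAA", "CAG",
                 "AAC", "TCC", "GGA", "CTT", "ATC", "CAC")

safe_codon_run <- function(n_codons) {
  paste(sample(SAFE_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Generate a small synthetic germline set
#'
#' Builds a reproducible `germline_set` with TRA V/J and TRB V/D/J segments.
#' V segments carry a leader region followed by a Cys anchor and a short
#' junction tail; J segments carry a junction head ending in a Phe/Trp anchor
#' followed by a downstream region; D segments are 12 nt. All junction-facing
#' regions have lengths divisible by three and are stop-free in frame, so a
#' zero-trim, zero-insertion recombination is productive by construction.
#'
#' @param seed Integer seed; the generator does not disturb the caller's RNG
#'   stream.
#' @param n_v,n_j Number of V and J segments per chain.
#' @param n_d Number of TRB D segments.
#' @return A `germline_set`.
#' @export
make_fixture_germline <- function(seed = 1, n_v = 3, n_j = 3, n_d = 2) {
  with_seed(seed, {
    rows <- list()
    mk_v <- function(chain, i) {
      leader <- random_nt(18L)
      anchor <- sample(CYS_CODONS, 1L)
      tail <- safe_codon_run(sample(2:3, 1L))
      tibble::tibble(
        id = sprintf("%sV%d", chain, i), chain = chain, segment_class = "V",
        seq_nt = paste0(leader, anchor, tail), anchor_offset = 18L
      )
    }
    mk_j <- function(chain, i) {
      m <- sample(2:3, 1L)
      head <- safe_codon_run(m)
      anchor <- sample(JANCHOR_CODONS, 1L)
      downstream <- random_nt(15L)
      tibble::tibble(
        id = sprintf("%sJ%d", chain, i), chain = chain, segment_class = "J",
        seq_nt = paste0(head, anchor, downstream), anchor_offset = 3L * m
      )
    }
    mk_d <- function(i) {
      tibble::tibble(
        id = sprintf("TRBD%d", i), chain = "TRB", segment_class = "D",
        seq_nt = safe_codon_run(4L), anchor_offset = NA_integer_
      )
    }
    for (ch in c("TRA", "TRB")) {
      for (i in seq_len(n_v)) rows <- c(rows, list(mk_v(ch, i)))
      for (i in seq_len(n_j)) rows <- c(rows, list(mk_j(ch, i)))
    }
    for (i in seq_len(n_d)) rows <- c(rows, list(mk_d(i)))
    segs <- dplyr::bind_rows(rows)
    # junction-facing regions must be pairwise distinct within a class so
    # gene calls are unambiguous in simulated data
    stopifnot(!anyDuplicated(segs$seq_nt))
    germline_set(segs)
  })
}
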