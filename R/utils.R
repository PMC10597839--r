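# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn inform .data
NULL

assert_nt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-ACGT characters: %s",
      what, paste(utils::head(x[bad], 3), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Reverse-complement a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that tolerates
#' empty strings (returned unchanged) and is vectorised.
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp_nt <- function(x) {
  assert_nt(x, "revcomp_nt() input")
  out <- x
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Longest common prefix length of two strings.
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- substring(a, seq_len(n), seq_len(n))
  bv <- substring(b, seq_len(n), seq_len(n))
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

# Longest common suffix length of two strings.
lcs_len <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  if (n == 0L) return(0L)
  av <- substring(a, na - seq_len(n) + 1L, na - seq_len(n) + 1L)
  bv <- substring(b, nb - seq_len(n) + 1L, nb - seq_len(n) + 1L)
  neq <- which(av != bv)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

random_nt <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
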