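# Independent oracles used to validate the package's own implementations.
# Each is a deliberately separate implementation (literal tables, exhaustive
# enumeration) so that tests compare two routes, not one.

# literal standard genetic code table
ORACLE_CODONS <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(nt) {
  vapply(nt, function(s) {
    if (nchar(s) == 0) return("")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    paste(ORACLE_CODONS[codons], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# two-sided Fisher p by full enumeration with choose(), no dhyper
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  p_of <- function(x) choose(m, x) * choose(n, k - x) / choose(m + n, k)
  probs <- vapply(xs, p_of, numeric(1))
  sum(probs[probs <= p_of(a) * (1 + 1e-7)])
}

# independent reverse complement
oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s) {
    if (nchar(s) == 0) return("")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# exhaustive middle labeling for a no-D junction under the module's stated
# precedence: maximal V prefix, then maximal J suffix, then greedy P at
# untrimmed ends (longest first, V side first), remainder N1
oracle_label_no_d <- function(junction, vreg, jreg, max_p = 2) {
  v_len <- 0
  while (v_len < min(nchar(junction), nchar(vreg)) &&
         substr(junction, v_len + 1, v_len + 1) ==
         substr(vreg, v_len + 1, v_len + 1)) {
    v_len <- v_len + 1
  }
  j_len <- 0
  L <- nchar(junction)
  while (j_len < min(L - v_len, nchar(jreg)) &&
         substr(junction, L - j_len, L - j_len) ==
         substr(jreg, nchar(jreg) - j_len, nchar(jreg) - j_len)) {
    j_len <- j_len + 1
  }
  middle <- substr(junction, v_len + 1, L - j_len)
  p_v <- ""
  if (v_len == nchar(vreg)) {
    for (p in rev(seq_len(min(max_p, nchar(middle))))) {
      cand <- oracle_revcomp(substr(vreg, nchar(vreg) - p + 1, nchar(vreg)))
      if (substr(middle, 1, p) == cand) { p_v <- cand; break }
    }
  }
  rem <- substr(middle, nchar(p_v) + 1, nchar(middle))
  p_j <- ""
  if (j_len == nchar(jreg)) {
    for (p in rev(seq_len(min(max_p, nchar(rem))))) {
      cand <- oracle_revcomp(substr(jreg, 1, p))
      if (substr(rem, nchar(rem) - p + 1, nchar(rem)) == cand) {
        p_j <- cand; break
      }
    }
  }
  list(
    v = substr(junction, 1, v_len), p_v = p_v,
    n1 = substr(rem, 1, nchar(rem) - nchar(p_j)),
    p_j = p_j, j = substr(junction, L - j_len + 1, L)
  )
}
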