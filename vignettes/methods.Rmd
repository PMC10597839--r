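---
title: "Methods: paired TCR clonotyping, junction decomposition, and the repertoire simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired TCR clonotyping, junction decomposition, and the repertoire simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoverge)
```

## Scope and definitions

`clonoverge` analyzes paired single-cell TCR repertoires from hashed
multi-animal experiments. Two grouping units are used throughout:

* a **clonotype** is a set of cells with identical paired TRA+TRB junction
  *nucleotide* sequences (under the default key policy, identical V/J gene
  calls as well);
* a **TCR type** is a set of clonotypes with identical paired junction
  *amino-acid* sequences.

A TCR type with two or more member clonotypes is *convergent*: independent
rearrangements, typically in different animals, arrived at the same protein
through codon redundancy. Detecting and describing this convergence — and
the compartment composition of the cells that carry it — is the package's
purpose. Gene-expression processing (normalization, clustering, embeddings)
is intentionally out of scope; cluster labels enter as plain per-cell
annotations.

All junction sequences are **anchor-inclusive**: they run from the conserved
V cysteine codon through the J phenylalanine/tryptophan codon, matching the
`cdr3_nt` column of 10x contig tables. Germline references are supplied
locally as FASTA plus a TSV of chains, segment classes and 0-based anchor
codon offsets; no online database is contacted.

## Hashtag demultiplexing and QC

Counts of the barcoded hashing antibodies are normalized per cell: with $g$
the geometric mean over hashtag features of $c+1$, the normalized value is
$\log_2\!\big((c+1)/g + 1\big)$. Equal counts across features map to exactly
1, values are positive and finite, and a cell of all-zero counts is valid.

The assignment rule is a transparent margin rule (the rule used by the
commercial software this replaces is unpublished): a cell is **assigned**
to its top hashtag iff the top normalized value is at least `floor`
(default 2.0) and exceeds the runner-up by at least `delta` (default 1.0
log~2~ units); **multiplet** if the top clears the floor but the margin does
not; **ambiguous** otherwise. Both thresholds are exposed; the defaults
separate a few-hundred-UMI signal from a few-UMI background by a wide
margin and call a two-signal doublet a multiplet even under substantial
count noise.

The cell QC filter takes the stated thresholds — total counts 30,000 and
mitochondrial percentage 30 — as retention bounds by default
(`total_counts <= 30000`, `mito_pct <= 30`). Because a bare "counts of
<30,000" can also be read as an exclusion of low-count cells, the
`direction = "min"` option applies `total_counts >= 30000` instead without
any other change; neither reading is asserted as the original intent.

## Clonotype calling

Per cell and chain, the most UMI-supported productive contig is retained
(ties: reads, then lexicographically smallest junction). Cells with more
than one productive contig on a chain are kept but flagged
(`multi_tra`/`multi_trb`) so reports can exclude them. The default policy is
strict-paired: cells lacking either chain are excluded and counted.
Clonotype ids are assigned in order of decreasing size with a lexicographic
key tie-break, so the partition is invariant under permutation of the input.

Whether the original clonotype definition included gene calls in addition to
the junction nucleotide sequences is ambiguous; both policies are
implemented (`key_policy = "genes+nt"`, the default matching upstream caller
conventions, or `"nt"`). The TCR-type key is amino-acid-only by definition;
V/D/J concordance across member clonotypes is *reported*
(`gene_concordant`), never imposed, because shared gene usage is an observed
outcome of convergence, not part of the grouping.

Ranking is by total cells, then clonotype count, then the amino-acid key.
"TCR 1" in reports means the rank-1 type.

## Junction decomposition

Each junction is partitioned into V | P~V~ | N1 | P~D5~ | D | P~D3~ | N2 |
P~J~ | J (no D block for TRA) by **maximal germline attribution**:

1. V part: longest junction prefix equal to a 3′-trimmed V junction region;
2. J part: longest remaining suffix equal to a 5′-trimmed J region (V is
   fixed before J, which resolves overlap ties in favor of V);
3. D part: longest contiguous exact match of at least `min_d_match`
   (default 3) nucleotides to any candidate D, ties broken by 5′-most
   placement, then candidate id, then offset within the D;
4. P nucleotides: up to `max_p` (default 2) per end, only where the adjacent
   germline end is untrimmed, and only if the junction nucleotides equal the
   reverse complement of that germline terminus, assigned greedily
   (longest first, V side before J side);
5. the remaining middle nucleotides are N1/N2.

The concatenation of the parts always reproduces the input junction; this is
asserted on every call. `min_d_match = 3` reflects that mouse TRB D segments
are 12–14 nt and shorter matches are statistically indistinguishable from N
nucleotides; `max_p = 2` is the usual biological bound for P additions.
Junctions shorter than two codons are an error; junctions with no germline
overlap at all return zero-length V/J parts with a warning flag rather than
failing, since such contigs do occur in real data with wrong gene calls.

An exhaustive reference, `enumerate_junction_attributions()`, enumerates
every boundary tuple consistent with the germline and returns all optima of
the same lexicographic objective (max V, then J, then D length). It serves
two roles: an independent check that the greedy decomposer attains the
optimum, and a detector of *ambiguity* — junctions where the optimum is not
unique or where the true boundaries do not attain it.

**Identifiability limitation.** When an inserted nucleotide happens to equal
the germline base that was trimmed away, maximal attribution necessarily
extends the germline part past the true recombination boundary; no algorithm
operating on the sequence alone can avoid this. With the simulator's default
trimming law (about half of ends trimmed) and four boundaries per TRB
junction, roughly 40% of junctions contain at least one such coincidence, so
exact boundary recovery against simulator truth is only about 60% overall —
while on the subset the enumeration oracle certifies as unambiguous it is
100%, and the part concatenation is exact everywhere. The acceptance report
computes all three rates on every run. Mismatch positions across synonymous
clonotypes (`compare_synonymous()`) use the largest member clonotype as the
reference, with a lexicographic id tie-break, since the original figure's
reference choice is unstated.

## The simulator: what it emulates, and what it does not

`simulate_study()` generates a complete hashed study and its ground truth.
Defaults were chosen once to emulate the targeted study design and are not
tuned to test outcomes:

* **Design**: four control and four tumor (HCC) mice pooled in one run; one
  hashtag feature per mouse; 50 regular clones over 2,000 cells.
* **Rearrangement model**: uniform segment choice; per-end trimming
  `min(Geometric(p = 0.5), 4)` (mean just under 1 nt, modal 0 — light but
  realistic trimming); N-insertion lengths Poisson(λ = 4) per side with
  uniform bases; P additions with probability 0.5 at untrimmed ends, length
  1–2; productive junctions by rejection (in frame, stop-free).
* **Expansion**: clone $k$ receives weight $k^{-\alpha}$ with α = 1, a
  power-law rank-size law; cells are multinomial over clones.
* **Convergence spike**: one planted TCR type of 5 synonymous clonotype
  variants holding 5% of cells, confined to the tumor condition and 90%
  reporter-positive — the phenomenon the convergence report exists to
  detect. Pure rejection sampling for an identical paired amino-acid
  sequence is astronomically unlikely, so variants are constructed from a
  base event by substituting synonymous alternatives at codon positions that
  fall inside the N-insertion parts; every variant therefore remains a valid
  recombination event with the same V/D/J combination, trims and P parts,
  and the set is pairwise nucleotide-distinct with one shared translation.
  Bases without enough synonymous N positions are redrawn.
* **Labels**: each regular clone is confined to one condition or present in
  both (probabilities 0.3 / 0.6 / 0.1 for control / HCC / both, echoing
  tumor-dominated expansion); reporter-positive probabilities per condition
  0.2 / 0.7 / 0.45; cluster labels ("C3", "C7", "C9") with a per-clone
  dominant cluster carried by 80% of the clone's cells.
* **Hashing**: signal counts NB(mean 200, size 20), background NB(mean 2,
  size 1) — a few hundred signal UMIs against single-digit background, as
  at typical hashing read depth; 5% doublets whose two parents always sit on
  distinct mice (same-mouse doublets are invisible to hashing by
  construction and are not modeled).
* **QC metrics**: total counts log-normal(meanlog log 12,000, sdlog 0.5);
  mitochondrial percentage 100·Beta(2, 18); a few percent of cells fall
  outside the default thresholds.

Not modeled, by design: sequencing error and UMI collisions, ambient
contamination of productive chains, genuine dual-productive-chain cells,
transcriptome counts, thymic selection, and biased segment usage. Extra
contigs are simulated only as non-productive (5% of cells), so passing the
exact-recovery test shows the pairing and keying logic is correct, not that
the pipeline is robust to chimeric or error-bearing contigs. Real dual-TRA
cells in particular will be resolved by UMI rank, which the `multi_tra`
flag surfaces but the simulator does not exercise.

Doublets carry the union of their parents' contigs, so a doublet that
escapes hashtag filtering can pair one parent's TRA with the other's TRB
and create a spurious clonotype — which is why the pipeline demultiplexes
and removes multiplets *before* clonotyping, and why recovery is asserted
on singlets.

## Numerical and degenerate-input choices

* Empty contig files return empty, correctly-typed tables with a warning;
  unknown loci (TRG/TRD/IG) are dropped with a logged count; a `productive`
  value of anything but "true" (case-insensitive), including "None", is
  `FALSE`.
* `normalize_hashtags` on a single-feature matrix returns exactly 1 for any
  count (self-normalization), and the margin of a single-feature demux is
  infinite, so only the floor applies.
* Fisher's exact test for 2×2 tables is computed by direct hypergeometric
  enumeration; a table's two-sided p sums all tables with fixed margins
  whose probability does not exceed the observed one within a relative
  tolerance of 1e-7 (guarding against floating-point ties), capped at 1.
* Translation uses the standard code with no initiation-codon special case
  (junctions are internal fragments); stops render as `*`.
* All simulator randomness flows through one seeded stream per run; helper
  fixtures restore the caller's RNG state.

## Problem sizes

The shipped checks run at desk scale, chosen to keep the full suite fast
while leaving no stage untested: 2,000-cell studies for end-to-end recovery
and demultiplexing (500 singlets + 50 doublets for the demux accuracy
check), 1,000 TRB junctions for decomposition against the exhaustive oracle,
10,000 events for the insertion-law and clone-size-law checks, and full
enumeration of all 2×2 tables with margins ≤ 8 for the Fisher test.
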