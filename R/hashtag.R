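# Hashtag (cell-hashing) normalization, demultiplexing and cell QC.
#
# Counts of DNA-barcoded hashing antibodies identify the animal of origin of
# each cell in a pooled run. Counts are normalized per cell with the
# centered-log-ratio-style transform "add 1.0, divide by geometric mean,
# add 1.0 and log 2.0"; cells are then assigned to the hashtag with the
# highest normalized value provided it clears a floor and beats the runner-up
# by a margin. Cells whose top two values are close are multiplets; cells
# with no strong signal are ambiguous. Both are filtered before repertoire
# analysis.

#' Normalize a hashtag count matrix
#'
#' For each cell, with `g` the geometric mean over hashtag features of
#' `count + 1`, the normalized value is `log2((count + 1) / g + 1)`.
#' Equal counts across features therefore map to exactly 1 for every feature,
#' and all values are positive and finite.
#'
#' @param counts Matrix-like, cells in rows, hashtag features in columns,
#'   non-negative counts. A `Matrix` sparse matrix is accepted.
#' @return Dense numeric matrix of normalized values, same dimnames.
#' @export
normalize_hashtags <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) < 1L) abort("need at least one hashtag feature")
  if (any(m < 0)) abort("hashtag counts must be non-negative")
  logp1 <- log(m + 1)
  g <- exp(rowMeans(logp1))
  log2((m + 1) / g + 1)
}

#' Assign cells to hashtags (demultiplex)
#'
#' A cell is `assigned` to its top hashtag iff the top normalized value is at
#' least `floor` and exceeds the second-highest value by at least `delta`
#' (log2 units); `multiplet` if the top value clears the floor but the margin
#' does not; `ambiguous` if no value clears the floor. With a single hashtag
#' feature the margin is infinite.
#'
#' @param normalized Matrix from [normalize_hashtags()] (cells x features).
#' @param delta Minimum top-minus-second margin, log2 units (> 0).
#' @param floor Minimum top value for a cell to be assignable.
#' @return Tibble: `cell_id`, `call` ("assigned"/"multiplet"/"ambiguous"),
#'   `assigned_to` (feature id or `NA`), `top_value`, `margin`.
#' @export
assign_hashtags <- function(normalized, delta = 1.0, floor = 2.0) {
  if (delta <= 0) abort("delta must be > 0")
  m <- as.matrix(normalized)
  features <- colnames(m) %||% paste0("HT", seq_len(ncol(m)))
  cells <- rownames(m) %||% paste0("cell", seq_len(nrow(m)))
  top_idx <- max.col(m, ties.method = "first")
  top <- m[cbind(seq_len(nrow(m)), top_idx)]
  second <- if (ncol(m) == 1L) {
    rep(-Inf, nrow(m))
  } else {
    m2 <- m
    m2[cbind(seq_len(nrow(m)), top_idx)] <- -Inf
    m2[cbind(seq_len(nrow(m)), max.col(m2, ties.method = "first"))]
  }
  margin <- top - second
  call <- ifelse(top < floor, "ambiguous",
                 ifelse(margin < delta, "multiplet", "assigned"))
  tibble::tibble(
    cell_id = cells,
    call = call,
    assigned_to = ifelse(call == "assigned", features[top_idx], NA_character_),
    top_value = top,
    margin = margin
  )
}

#' Filter cells on total counts and mitochondrial percentage
#'
#' Default direction `"max"` keeps cells with `total_counts <= max_counts`
#' and `mito_pct <= max_mito`. Direction `"min"` instead keeps cells with
#' `total_counts >= max_counts` (the mitochondrial rule is unchanged),
#' supporting the alternative reading of a `< 30,000 counts` exclusion rule.
#'
#' @param qc Tibble with `cell_id`, `total_counts`, `mito_pct` (0-100).
#' @param max_counts Count threshold (default 30000).
#' @param max_mito Mitochondrial percentage threshold (default 30).
#' @param direction `"max"` or `"min"`, see above.
#' @return List: `kept` (cell ids) and `excluded`, a named vector of
#'   per-reason exclusion counts (`counts`, `mito`; a cell failing both is
#'   counted under both reasons).
#' @export
qc_filter <- function(qc, max_counts = 30000, max_mito = 30,
                      direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (max_counts <= 0 || max_mito <= 0) abort("thresholds must be positive")
  qc <- tibble::as_tibble(qc)
  if (nrow(qc) == 0) {
    return(list(kept = character(),
                excluded = c(counts = 0L, mito = 0L)))
  }
  if (any(qc$mito_pct < 0 | qc$mito_pct > 100)) {
    abort("mito_pct must lie in [0, 100]")
  }
  bad_counts <- if (direction == "max") qc$total_counts > max_counts
                else qc$total_counts < max_counts
  bad_mito <- qc$mito_pct > max_mito
  list(
    kept = qc$cell_id[!bad_counts & !bad_mito],
    excluded = c(counts = sum(bad_counts), mito = sum(bad_mito))
  )
}

#' Read a hashtag matrix from an MTX triplet directory
#'
#' Expects `matrix.mtx` (features x barcodes, as written by cell-calling
#' pipelines), `features.tsv` and `barcodes.tsv`. Returned transposed to the
#' package's cells-in-rows orientation. A dense TSV (cells in rows, feature
#' ids as header, cell ids in the first column) is read via
#' [read_hashtag_tsv()].
#'
#' @param dir Directory holding the triplet.
#' @return Integer matrix, cells x features.
#' @export
read_hashtag_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_names = FALSE, show_col_types = FALSE,
                              progress = FALSE)[[1]]
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = FALSE, show_col_types = FALSE,
                              progress = FALSE)[[1]]
  m <- as.matrix(Matrix::t(m))
  dimnames(m) <- list(barcodes, features)
  storage.mode(m) <- "integer"
  m
}

#' Write a hashtag matrix as an MTX triplet directory
#'
#' @param counts Matrix, cells x features, with dimnames.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_hashtag_mtx <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- Matrix::Matrix(t(as.matrix(counts)), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble::tibble(x = colnames(counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(x = rownames(counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  invisible(dir)
}

#' Read a dense hashtag TSV (cells in rows)
#'
#' @param path TSV whose first column holds cell ids and remaining columns
#'   hashtag features.
#' @return Integer matrix, cells x features.
#' @export
read_hashtag_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  m
}
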