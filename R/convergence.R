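# Convergence and composition reporting: which TCR types are encoded by
# multiple synonymous clonotypes, which conditions each type is seen in,
# and how each clonotype splits across reporter compartments and clusters.

# attach tcr_type_id to cells via their clonotype unless already present
join_type_id <- function(cells, clonotypes) {
  if ("tcr_type_id" %in% names(cells)) return(cells)
  dplyr::left_join(cells, clonotypes[, c("clonotype_id", "tcr_type_id")],
                   by = "clonotype_id")
}

#' Flag convergent TCR types and gene-usage concordance
#'
#' A TCR type is convergent iff it has at least two member clonotypes
#' (distinct nucleotide variants encoding the same receptor). For each type
#' the V/D/J gene usage of its members is compared: `gene_concordant` is
#' `TRUE` when all member clonotypes use the same combination of
#' (tra_v, tra_j, trb_v, trb_d, trb_j).
#'
#' @param tcr_types Ranked tibble from [rank_tcr_types()] (a `rank` column is
#'   required; unranked rows sort last).
#' @param clonotypes Clonotype tibble carrying `tcr_type_id` (from
#'   [group_tcr_types()]).
#' @param cells Optional clonotyped cell tibble (with `clonotype_id`,
#'   `sample_id` and, if available, `condition`); adds `samples` and
#'   `conditions` columns listing where each type was observed.
#' @return `tcr_types` sorted by rank with `convergent`, `gene_concordant`
#'   and (given `cells`) `samples`/`conditions` columns.
#' @export
detect_convergent_types <- function(tcr_types, clonotypes, cells = NULL) {
  gene_cols <- c("tra_v", "tra_j", "trb_v", "trb_d", "trb_j")
  conc <- clonotypes |>
    dplyr::group_by(.data$tcr_type_id) |>
    dplyr::summarise(
      gene_concordant = dplyr::n_distinct(paste(
        ifelse(is.na(.data$tra_v), "<NA>", .data$tra_v),
        ifelse(is.na(.data$tra_j), "<NA>", .data$tra_j),
        ifelse(is.na(.data$trb_v), "<NA>", .data$trb_v),
        ifelse(is.na(.data$trb_d), "<NA>", .data$trb_d),
        ifelse(is.na(.data$trb_j), "<NA>", .data$trb_j)
      )) == 1L,
      .groups = "drop"
    )
  out <- dplyr::left_join(tcr_types, conc, by = "tcr_type_id")
  out$convergent <- out$n_clonotypes >= 2L
  if (!is.null(cells)) {
    cells2 <- join_type_id(cells, clonotypes)
    obs <- cells2 |>
      dplyr::filter(!is.na(.data$tcr_type_id)) |>
      dplyr::group_by(.data$tcr_type_id) |>
      dplyr::summarise(
        samples = paste(sort(unique(.data$sample_id)), collapse = ","),
        conditions = if ("condition" %in% names(cells2)) {
          paste(sort(unique(stats::na.omit(.data$condition))), collapse = ",")
        } else {
          NA_character_
        },
        .groups = "drop"
      )
    out <- dplyr::left_join(out, obs, by = "tcr_type_id")
  }
  dplyr::arrange(out, is.na(.data$rank), .data$rank)
}

#' Condition sharing among the top-ranked TCR types
#'
#' A type is "present" in a condition iff at least `min_cells` of its member
#' cells carry that condition label. Over the `n` top-ranked types the
#' summary counts types present in only one condition or in both. Cells
#' without a condition label are excluded with a warning.
#'
#' @param tcr_types Ranked tibble (with `rank`).
#' @param clonotypes Clonotype tibble with `tcr_type_id`.
#' @param cells Clonotyped cell tibble with `clonotype_id` and `condition`.
#' @param n Number of top types to summarize (default 30; capped at the
#'   number of types).
#' @param min_cells Presence threshold per condition (default 1).
#' @return Tibble `category`/`n` with one `"<condition>_only"` row per
#'   condition level plus `"both"` (levels sorted; with a single observed
#'   condition, just that `_only` row).
#' @export
sharing_summary <- function(tcr_types, clonotypes, cells, n = 30,
                            min_cells = 1) {
  if (!"condition" %in% names(cells)) {
    abort("sharing_summary() needs a 'condition' column on cells")
  }
  unlabeled <- is.na(cells$condition)
  if (any(unlabeled)) {
    warn(sprintf("excluding %d cell(s) without a condition label",
                 sum(unlabeled)))
  }
  cells <- cells[!unlabeled, ]
  levels <- sort(unique(cells$condition))
  top <- tcr_types[!is.na(tcr_types$rank) & tcr_types$rank <= n, ]
  cells2 <- join_type_id(cells, clonotypes)
  pres <- cells2 |>
    dplyr::filter(.data$tcr_type_id %in% top$tcr_type_id) |>
    dplyr::group_by(.data$tcr_type_id, .data$condition) |>
    dplyr::summarise(n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_cells >= min_cells)
  per_type <- split(pres$condition, pres$tcr_type_id)
  cats <- vapply(per_type, function(conds) {
    if (length(unique(conds)) > 1L) "both" else paste0(conds[1L], "_only")
  }, character(1))
  wanted <- c(paste0(levels, "_only"), if (length(levels) > 1) "both")
  tibble::tibble(
    category = wanted,
    n = vapply(wanted, function(w) sum(cats == w), integer(1),
               USE.NAMES = FALSE)
  )
}

#' Compartment and cluster composition of each clonotype
#'
#' For each member clonotype of the requested TCR types, counts cells by
#' reporter compartment (`gfp_status`) and cluster; missing labels are binned
#' as `"unlabeled"`.
#'
#' @param cells Clonotyped cell tibble with `clonotype_id` (and, when
#'   available, `gfp_status`/`cluster` label columns).
#' @param clonotypes Clonotype tibble with `tcr_type_id`.
#' @param tcr_type_ids Types to report; default all.
#' @return Tibble: `tcr_type_id`, `clonotype_id`, `gfp_status`, `cluster`,
#'   `n_cells`.
#' @export
compartment_composition <- function(cells, clonotypes, tcr_type_ids = NULL) {
  cells2 <- join_type_id(cells, clonotypes)
  if (!is.null(tcr_type_ids)) {
    cells2 <- cells2[cells2$tcr_type_id %in% tcr_type_ids, ]
  }
  bin <- function(x) {
    if (is.null(x)) return("unlabeled")
    ifelse(is.na(x), "unlabeled", x)
  }
  cells2$gfp_status <- bin(cells2[["gfp_status"]])
  cells2$cluster <- bin(cells2[["cluster"]])
  cells2 |>
    dplyr::filter(!is.na(.data$clonotype_id)) |>
    dplyr::group_by(.data$tcr_type_id, .data$clonotype_id, .data$gfp_status,
                    .data$cluster) |>
    dplyr::summarise(n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$tcr_type_id, .data$clonotype_id, .data$gfp_status,
                   .data$cluster)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value by direct hypergeometric enumeration: with
#' margins fixed, every achievable table whose probability does not exceed
#' the observed table's probability (within a small numerical tolerance)
#' contributes to p.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("fisher_exact_2x2() needs non-negative integer counts")
  }
  if (sum(cells) == 0) abort("all-zero 2x2 table")
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}
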