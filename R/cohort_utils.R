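#' Lift gene symbols to their current HGNC names
#'
#' Replaces outdated symbols with current ones using a symbol-change map;
#' symbols not in the map (including already-current ones) pass through
#' unchanged.
#'
#' @param table Any tibble carrying gene-symbol columns.
#' @param map Tibble `prev_symbol`, `symbol` (an HGNC symbol-change
#'   table), or a named character vector `old -> new`.
#' @param cols Columns of `table` to update; defaults to the intersection
#'   with `c("hugo_symbol", "gene", "gene5", "gene3", "symbol")`.
#' @return `table` with updated symbols.
#' @examples
#' liftover_symbols(tibble::tibble(gene = c("FAM123B", "TP53")),
#'                  tibble::tibble(prev_symbol = "FAM123B", symbol = "AMER1"))
#' @export
liftover_symbols <- function(table, map, cols = NULL) {
  if (is.data.frame(map)) {
    lookup <- setNames(map$symbol, map$prev_symbol)
  } else {
    lookup <- map
  }
  cols <- cols %||% intersect(c("hugo_symbol", "gene", "gene5", "gene3", "symbol"),
                              names(table))
  for (col in cols) {
    hit <- table[[col]] %in% names(lookup)
    table[[col]][hit] <- unname(lookup[table[[col]][hit]])
  }
  table
}

#' Collapse an expression matrix to unique gene symbols
#'
#' Rows with no nonzero expression are dropped first; among rows sharing a
#' gene symbol, the one with the maximum mean value across samples is
#' retained (ties broken by Ensembl id order), so downstream modules can
#' key on unique symbols. Idempotent.
#'
#' @param x Expression tibble with `ensembl_id` and `symbol` columns
#'   followed by numeric sample columns (see [read_expression()]).
#' @return Collapsed tibble with unique, nonzero-expressed symbols.
#' @export
collapse_matrix <- function(x) {
  sample_cols <- setdiff(names(x), c("ensembl_id", "symbol"))
  vals <- as.matrix(x[sample_cols])
  keep <- rowSums(vals != 0, na.rm = TRUE) > 0
  x <- x[keep, , drop = FALSE]
  x |>
    mutate(.mean = rowMeans(as.matrix(x[sample_cols]), na.rm = TRUE)) |>
    arrange(.data$symbol, desc(.data$.mean), .data$ensembl_id) |>
    distinct(.data$symbol, .keep_all = TRUE) |>
    select(-".mean") |>
    arrange(.data$symbol)
}

#' Select one independent biospecimen per participant
#'
#' For analyses whose statistics must not double-count patients, selects
#' exactly one biospecimen per participant: eligible records (after the
#' optional `filter_fn`) are ranked by the position of their
#' `tumor_descriptor` then `experimental_strategy` in the stated
#' preference orders (unlisted values rank last), with the
#' lexicographically smallest `biospecimen_id` as the final deterministic
#' tie-break. Participants with no eligible biospecimen are omitted.
#'
#' @param histologies Histology tibble (see [read_histologies()]).
#' @param tumor_descriptor_order Character vector, most preferred first.
#' @param strategy_order Character vector, most preferred first.
#' @param filter_fn Optional function tibble -> tibble applying
#'   analysis-specific eligibility filters before selection.
#' @return Tibble of the selected rows, one per participant, ordered by
#'   `participant_id`.
#' @export
select_independent <- function(histologies,
                               tumor_descriptor_order = c(
                                 "Initial CNS Tumor", "Primary Tumor",
                                 "Progressive", "Recurrence"),
                               strategy_order = c("WGS", "WXS", "Targeted",
                                                  "RNA-Seq", "Methylation"),
                               filter_fn = NULL) {
  x <- if (is.null(filter_fn)) histologies else filter_fn(histologies)
  rank_in <- function(v, ord) {
    r <- match(v, ord)
    ifelse(is.na(r), length(ord) + 1L, r)
  }
  x |>
    mutate(.td = rank_in(.data$tumor_descriptor, tumor_descriptor_order),
           .st = rank_in(.data$experimental_strategy, strategy_order)) |>
    arrange(.data$participant_id, .data$.td, .data$.st, .data$biospecimen_id) |>
    distinct(.data$participant_id, .keep_all = TRUE) |>
    select(-".td", -".st") |>
    arrange(.data$participant_id)
}
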