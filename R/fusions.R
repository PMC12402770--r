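split_set <- function(x) strsplit(dplyr::coalesce(x, ""), ",", fixed = TRUE)

#' Annotate fusions as putative oncogenic
#'
#' A fusion is putative oncogenic when either partner gene is a known
#' kinase, oncogene, tumor suppressor, curated transcription factor, on
#' the COSMIC Cancer Gene Census list, or observed in TCGA.
#'
#' @param fusions Fusion tibble (`gene5`, `gene3`, ...).
#' @param gene_lists Named list of character vectors, e.g. elements
#'   `kinase`, `oncogene`, `tsg`, `tf`, `cosmic_cgc`, `tcga_observed`.
#' @return `fusions` with a logical `putative_oncogenic` column.
#' @examples
#' annotate_oncogenic(
#'   tibble::tibble(gene5 = "KIAA1549", gene3 = "BRAF"),
#'   list(kinase = "BRAF"))
#' @export
annotate_oncogenic <- function(fusions, gene_lists) {
  listed <- unique(unlist(gene_lists, use.names = FALSE))
  mutate(fusions,
         putative_oncogenic = .data$gene5 %in% listed | .data$gene3 %in% listed)
}

#' Retain prioritized fusions
#'
#' After artifact filtering (carried on input flags), a fusion call is
#' retained when any of the following hold: it was called by both RNA
#' callers; it is recurrent in a cancer group (at least
#' `cfg$fusion_recurrent_min` independent patients, default 3); it is
#' specific to exactly one cancer group; or it is annotated as putative
#' oncogenic. Fusion-panel (`dgd_panel`) calls pass through untouched.
#'
#' @param fusions Fusion tibble with `fusion_name`, `callers`
#'   (comma-separated), `sample_id`, `cancer_group` and a
#'   `putative_oncogenic` column (see [annotate_oncogenic()]).
#' @param cohort_counts Optional tibble `fusion_name`, `cancer_group`,
#'   `n_patients` of independent-patient counts; computed from `fusions`
#'   (distinct `sample_id` per group) when absent.
#' @param cfg A [rule_config()].
#' @return Retained fusions with a comma-separated `retained_reason`
#'   column (subset of `both_callers`, `recurrent`,
#'   `cancer_group_specific`, `oncogenic`, `dgd_panel`).
#' @export
retain_fusions <- function(fusions, cohort_counts = NULL,
                           cfg = rule_config()) {
  if (nrow(fusions) == 0) return(mutate(fusions, retained_reason = character()))
  if (!"putative_oncogenic" %in% names(fusions)) {
    abort("retain_fusions: run annotate_oncogenic() first")
  }
  if (is.null(cohort_counts)) {
    cohort_counts <- fusions |>
      distinct(.data$fusion_name, .data$cancer_group, .data$sample_id) |>
      count(.data$fusion_name, .data$cancer_group, name = "n_patients")
  }
  n_groups <- fusions |>
    distinct(.data$fusion_name, .data$cancer_group) |>
    count(.data$fusion_name, name = "n_cancer_groups")
  caller_sets <- split_set(fusions$callers)
  rna <- cfg$rna_fusion_callers
  fusions |>
    mutate(is_dgd = map_lgl(caller_sets, ~ "dgd_panel" %in% .x),
           both_callers = map_lgl(caller_sets,
                                  ~ length(intersect(.x, rna)) >= 2)) |>
    left_join(cohort_counts, by = c("fusion_name", "cancer_group")) |>
    left_join(n_groups, by = "fusion_name") |>
    mutate(
      recurrent = dplyr::coalesce(.data$n_patients, 0L) >= cfg$fusion_recurrent_min,
      cancer_group_specific = dplyr::coalesce(.data$n_cancer_groups, 0L) == 1L,
      retained_reason = purrr::pmap_chr(
        list(.data$is_dgd, .data$both_callers, .data$recurrent,
             .data$cancer_group_specific, .data$putative_oncogenic),
        function(d, b, r, s, o) {
          paste(c(if (d) "dgd_panel", if (b) "both_callers",
                  if (r) "recurrent", if (s) "cancer_group_specific",
                  if (o) "oncogenic"), collapse = ",")
        })
    ) |>
    filter(.data$retained_reason != "") |>
    select(-"is_dgd", -"both_callers", -"recurrent", -"cancer_group_specific",
           -"n_patients", -"n_cancer_groups") |>
    arrange(.data$sample_id, .data$fusion_name)
}
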