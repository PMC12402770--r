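#' Default histology dispatch table
#'
#' Maps `pathology_diagnosis` strings (case-insensitive regular
#' expressions, first match wins) to the histology-specific rule set the
#' subtyping engine runs for that tumor event.
#'
#' @return A tibble with `histology_group` and `pattern`.
#' @export
subtype_dispatch_table <- function() {
  tibble::tribble(
    ~histology_group, ~pattern,
    "ATRT",   "atypical teratoid|\\batrt\\b",
    "MB",     "medulloblastoma",
    "PB",     "pineoblastoma",
    "ETMR",   "multilayered rosettes|\\betmr\\b|embryonal tumor",
    "EPN",    "ependymoma",
    "CRANIO", "craniopharyngioma",
    "NBL",    "ganglioneuroblastoma|neuroblastoma|ganglioneuroma",
    "LGG",    "low-grade glioma|pilocytic|ganglioglioma|subependymal giant cell",
    "HGG",    "high-grade glioma|glioblastoma|diffuse midline glioma|diffuse hemispheric glioma|infant-type hemispheric glioma|astrocytoma"
  )
}

#' Closed vocabulary of molecular subtype labels
#'
#' @return Tibble `histology_group`, `molecular_subtype` (shipped in
#'   `extdata/subtype_labels.tsv`).
#' @export
subtype_labels <- function() read_label_map("subtype_labels.tsv")

dispatch_group <- function(diagnosis, dispatch) {
  if (is.na(diagnosis)) return(NA_character_)
  d <- tolower(diagnosis)
  for (i in seq_len(nrow(dispatch))) {
    if (grepl(dispatch$pattern[i], d)) return(dispatch$histology_group[i])
  }
  NA_character_
}

#' Assign WHO-2021-aligned molecular subtypes to a cohort
#'
#' Routes every tumor event to its histology-specific rule set by
#' `pathology_diagnosis` (see [subtype_dispatch_table()]) and runs the
#' corresponding rules over the integrated evidence. High-grade glioma
#' events are first screened for infant-type hemispheric glioma
#' eligibility; "MB, SHH" calls are refined into the alpha/beta/gamma/
#' delta subgroups. Events whose diagnosis matches no rule set produce no
#' call. Output is deterministic and independent of input ordering.
#'
#' @param evidence A [cohort_evidence()] object.
#' @param cfg A [rule_config()].
#' @param dispatch Dispatch tibble, by default [subtype_dispatch_table()].
#' @return Tibble `tumor_event_id`, `histology_group`, `molecular_subtype`,
#'   `evidence_used`, `confidence_basis`, sorted by event id.
#' @export
run_subtyping <- function(evidence, cfg = rule_config(),
                          dispatch = subtype_dispatch_table()) {
  stopifnot(inherits(evidence, "pedcan_evidence"))
  ids <- sort(evidence$histologies$tumor_event_id)
  calls <- map_dfr(ids, function(id) {
    e <- event_evidence(evidence, id)
    grp <- dispatch_group(e$pathology_diagnosis, dispatch)
    if (is.na(grp)) return(NULL)
    res <- switch(
      grp,
      HGG = subtype_ihg(e, cfg) %||% subtype_hgg(e, cfg),
      ATRT = subtype_atrt(e, cfg),
      NBL = subtype_nbl(e, cfg),
      CRANIO = subtype_cranio(e, cfg),
      EPN = subtype_epn(e, cfg),
      LGG = subtype_lgg_methyl(e, cfg),
      MB = {
        mb <- subtype_mb(e, cfg)
        if (mb$molecular_subtype == "MB, SHH") subtype_mb_shh(e, cfg) else mb
      },
      PB = subtype_pb(e, cfg),
      ETMR = subtype_etmr(e, cfg)
    )
    if (is.null(res)) return(NULL)
    mutate(res, histology_group = grp, .after = "tumor_event_id")
  })
  if (nrow(calls) == 0) {
    return(tibble(tumor_event_id = character(), histology_group = character(),
                  molecular_subtype = character(), evidence_used = character(),
                  confidence_basis = character()))
  }
  arrange(calls, .data$tumor_event_id)
}

#' Methylation-vs-RNA subtype concordance
#'
#' Cross-tabulates paired methylation subclasses and RNA-derived group
#' labels per sample, maps each methylation subclass to its consensus
#' group via [mb_methyl_group()], and counts the pairs whose mapped group
#' disagrees with the RNA label.
#'
#' @param meth_labels Character vector of methylation subclasses.
#' @param rna_labels Parallel character vector of RNA group labels.
#' @return An object of class `pedcan_concordance` with elements `pairs`
#'   (tibble of the input pairs with the mapped group and an `agree`
#'   flag), `table` (wide contingency tibble, methylation subclass by RNA
#'   group), `n_pairs`, and `n_mismatch`.
#' @examples
#' cc <- concordance_table(c("MB_WNT", "MB_MYO"), c("WNT", "Group3"))
#' cc$n_mismatch
#' @export
concordance_table <- function(meth_labels, rna_labels) {
  stopifnot(length(meth_labels) == length(rna_labels))
  pairs <- tibble(
    methylation_subclass = meth_labels,
    rna_group = rna_labels,
    mapped_group = mb_methyl_group(meth_labels)
  ) |>
    mutate(agree = !is.na(.data$mapped_group) &
             .data$mapped_group == .data$rna_group)
  wide <- pairs |>
    count(.data$methylation_subclass, .data$rna_group) |>
    tidyr::pivot_wider(names_from = "rna_group", values_from = "n",
                       values_fill = 0L) |>
    arrange(.data$methylation_subclass)
  structure(
    list(pairs = pairs, table = wide,
         n_pairs = nrow(pairs), n_mismatch = sum(!pairs$agree)),
    class = "pedcan_concordance"
  )
}

#' @export
print.pedcan_concordance <- function(x, ...) {
  cat("<pedcan_concordance> ", x$n_pairs, " pairs, ", x$n_mismatch,
      " discordant\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Tidy a concordance result into long contingency counts
#'
#' @param x A `pedcan_concordance` object.
#' @param ... Unused.
#' @return Tibble `methylation_subclass`, `rna_group`, `mapped_group`,
#'   `agree`, `n`.
#' @exportS3Method generics::tidy
tidy.pedcan_concordance <- function(x, ...) {
  x$pairs |>
    count(.data$methylation_subclass, .data$rna_group, .data$mapped_group,
          .data$agree, name = "n") |>
    arrange(.data$methylation_subclass, .data$rna_group)
}

#' One-row summary of a concordance result
#'
#' @param x A `pedcan_concordance` object.
#' @param ... Unused.
#' @return Tibble with `n_pairs`, `n_mismatch`, `concordance`.
#' @exportS3Method generics::glance
glance.pedcan_concordance <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, n_mismatch = x$n_mismatch,
         concordance = 1 - x$n_mismatch / x$n_pairs)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Heatmap of a methylation-vs-RNA concordance table
#'
#' @param object A `pedcan_concordance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pedcan_concordance <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rna_group,
                                   y = .data$methylation_subclass,
                                   fill = .data$n)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "RNA-seq group", y = "Methylation subclass",
                  fill = "samples") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of molecular subtype calls
#'
#' @param calls Output of [run_subtyping()].
#' @return A ggplot object.
#' @export
plot_subtype_counts <- function(calls) {
  df <- count(calls, .data$histology_group, .data$molecular_subtype)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n,
                                   y = stats::reorder(.data$molecular_subtype, .data$n),
                                   fill = .data$histology_group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "tumor events", y = NULL, fill = "histology") +
    ggplot2::theme_minimal()
}

#' Distribution of tumor mutation burden across samples
#'
#' @param tmb Output of [calculate_tmb()].
#' @return A ggplot object.
#' @export
plot_tmb <- function(tmb) {
  df <- tidyr::pivot_longer(tmb, cols = any_of(c("tmb_all", "tmb_coding")),
                            names_to = "measure", values_to = "tmb")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$tmb)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "mutations per Mb") +
    ggplot2::theme_minimal()
}
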