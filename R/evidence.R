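empty_evidence_tables <- function() {
  list(
    histologies = tibble(tumor_event_id = character(),
                         participant_id = character(),
                         pathology_diagnosis = character(),
                         pathology_free_text_diagnosis = character(),
                         age_at_diagnosis_years = numeric(),
                         tumor_descriptor = character(),
                         cns_region = character(),
                         germline_pathogenic = character(),
                         rna_mb_class = character()),
    variants = tibble(tumor_event_id = character(), hugo_symbol = character(),
                      hgvsp_short = character(),
                      variant_classification = character(),
                      hotspot = logical(), origin = character()),
    gene_cn = tibble(tumor_event_id = character(), gene = character(),
                     status = character()),
    arm_cn = tibble(tumor_event_id = character(), arm = character(),
                    status = character()),
    fusions = tibble(tumor_event_id = character(), fusion_name = character(),
                     gene5 = character(), gene3 = character()),
    expression = tibble(tumor_event_id = character(), gene = character(),
                        tpm = numeric(), z = numeric()),
    methylation = tibble(tumor_event_id = character(), classifier = character(),
                         subclass = character(), score = numeric()),
    tp53 = tibble(tumor_event_id = character(), tp53_status = character()),
    flags = tibble(tumor_event_id = character(), u1_snrna_hotspot = logical(),
                   chr19_amplified = logical(), has_dna = logical(),
                   has_rna = logical())
  )
}

#' Assemble the per-tumor-event evidence consumed by the subtyping engine
#'
#' Bundles the clinical table with every molecular evidence channel, all
#' keyed by `tumor_event_id`. Any channel may be omitted; missing columns
#' in a supplied channel are filled with `NA` defaults.
#'
#' @param histologies Tibble with at least `tumor_event_id` and
#'   `pathology_diagnosis`; recognized columns further include
#'   `participant_id`, `pathology_free_text_diagnosis`,
#'   `age_at_diagnosis_years`, `tumor_descriptor`, `cns_region`,
#'   `germline_pathogenic` (comma-separated gene symbols with
#'   pathogenic/likely-pathogenic germline variants), `rna_mb_class`
#'   (external RNA medulloblastoma classifier label).
#' @param variants Consensus somatic (and annotated germline) small
#'   variants: `tumor_event_id`, `hugo_symbol`, `hgvsp_short`,
#'   `variant_classification`, `hotspot`, `origin`.
#' @param gene_cn Gene-level CN status (`gene`, `status`), e.g. from
#'   [assign_gene_status()].
#' @param arm_cn Arm-level status (`arm`, `status`), e.g. from
#'   [arm_status()].
#' @param fusions Prioritized fusions (`fusion_name`, `gene5`, `gene3`).
#' @param expression Per-gene RNA evidence (`gene`, `tpm`, `z`), the
#'   z-score taken over log2(TPM+1) within the cohort stratum.
#' @param methylation Methylation classifier calls (`classifier`,
#'   `subclass`, `score`).
#' @param tp53 Per-event TP53 status (`tp53_status`), e.g. from
#'   [classify_tp53()].
#' @param flags Per-event boolean evidence with no tabular home:
#'   `u1_snrna_hotspot`, `chr19_amplified`, `has_dna`, `has_rna`.
#' @return An object of class `pedcan_evidence` (a named list of tibbles).
#' @export
cohort_evidence <- function(histologies, variants = NULL, gene_cn = NULL,
                            arm_cn = NULL, fusions = NULL, expression = NULL,
                            methylation = NULL, tp53 = NULL, flags = NULL) {
  defaults <- empty_evidence_tables()
  supplied <- list(histologies = histologies, variants = variants,
                   gene_cn = gene_cn, arm_cn = arm_cn, fusions = fusions,
                   expression = expression, methylation = methylation,
                   tp53 = tp53, flags = flags)
  ev <- purrr::imap(defaults, function(proto, nm) {
    x <- supplied[[nm]]
    if (is.null(x)) return(proto)
    x <- as_tibble(x)
    if (!"tumor_event_id" %in% names(x)) {
      abort(paste0("cohort_evidence: ", nm, " lacks tumor_event_id"))
    }
    for (col in setdiff(names(proto), names(x))) x[[col]] <- proto[[col]][NA_integer_][rep(1, nrow(x))]
    x[union(names(proto), setdiff(names(x), names(proto)))]
  })
  if (nrow(ev$histologies) == 0) abort("cohort_evidence: empty histology table")
  if (anyDuplicated(ev$histologies$tumor_event_id)) {
    abort("cohort_evidence: duplicated tumor_event_id in histologies")
  }
  structure(ev, class = c("pedcan_evidence", "list"))
}

#' @export
print.pedcan_evidence <- function(x, ...) {
  cat("<pedcan_evidence> ", nrow(x$histologies), " tumor event(s)\n", sep = "")
  for (nm in setdiff(names(x), "histologies")) {
    if (nrow(x[[nm]]) > 0) cat("  ", nm, ": ", nrow(x[[nm]]), " row(s)\n", sep = "")
  }
  invisible(x)
}

# Extract one event's evidence as a flat list used by the rule functions.
event_evidence <- function(ev, id) {
  h <- filter(ev$histologies, .data$tumor_event_id == id)
  stopifnot(nrow(h) == 1)
  fl <- filter(ev$flags, .data$tumor_event_id == id)
  flag <- function(col) nrow(fl) > 0 && isTRUE(any(fl[[col]]))
  germ <- h$germline_pathogenic
  list(
    tumor_event_id = id,
    pathology_diagnosis = h$pathology_diagnosis %||% NA_character_,
    free_text = tolower(dplyr::coalesce(h$pathology_free_text_diagnosis, "")),
    age = h$age_at_diagnosis_years,
    cns_region = tolower(dplyr::coalesce(h$cns_region, "")),
    germline = if (is.na(germ) || germ == "") character() else
      strsplit(germ, ",", fixed = TRUE)[[1]],
    rna_mb_class = h$rna_mb_class,
    variants = filter(ev$variants, .data$tumor_event_id == id),
    gene_cn = filter(ev$gene_cn, .data$tumor_event_id == id),
    arm_cn = filter(ev$arm_cn, .data$tumor_event_id == id),
    fusions = filter(ev$fusions, .data$tumor_event_id == id),
    expression = filter(ev$expression, .data$tumor_event_id == id),
    methylation = filter(ev$methylation, .data$tumor_event_id == id),
    tp53 = filter(ev$tp53, .data$tumor_event_id == id),
    u1_snrna_hotspot = flag("u1_snrna_hotspot"),
    chr19_amplified = flag("chr19_amplified"),
    has_dna = flag("has_dna") || nrow(filter(ev$gene_cn, .data$tumor_event_id == id)) > 0,
    has_rna = flag("has_rna") || nrow(filter(ev$expression, .data$tumor_event_id == id)) > 0
  )
}

#' Select a high-confidence methylation classifier call
#'
#' Returns the matching classifier call only when its score reaches the
#' high-confidence threshold (`cfg$methyl_high_confidence`, 0.8) and the
#' subclass satisfies `wanted`; otherwise an empty tibble.
#'
#' @param methylation Methylation call tibble (`subclass`, `score`).
#' @param wanted Either a character vector of exact subclass labels or a
#'   predicate function over subclass strings.
#' @param cfg A [rule_config()].
#' @return The best-scoring matching row, or a zero-row tibble.
#' @examples
#' high_conf_methyl(
#'   tibble::tibble(subclass = "ATRT_MYC", score = 0.85), "ATRT_MYC")
#' @export
high_conf_methyl <- function(methylation, wanted, cfg = rule_config()) {
  if (nrow(methylation) == 0) return(methylation)
  ok <- if (is.function(wanted)) {
    map_lgl(methylation$subclass, function(s) !is.na(s) && isTRUE(wanted(s)))
  } else {
    methylation$subclass %in% wanted
  }
  hit <- methylation[ok & !is.na(methylation$score) &
                       methylation$score >= cfg$methyl_high_confidence, ,
                     drop = FALSE]
  if (nrow(hit) == 0) return(hit)
  hit[order(-hit$score), , drop = FALSE][1, , drop = FALSE]
}

# --- small evidence predicates used by the rule functions -------------------

ev_variant <- function(e, genes = NULL, hgvsp = NULL, classes = NULL,
                       hotspot = NULL, origin = "somatic") {
  v <- e$variants
  if (nrow(v) == 0) return(FALSE)
  if (!is.null(origin) && "origin" %in% names(v)) {
    v <- v[is.na(v$origin) | v$origin %in% origin, , drop = FALSE]
  }
  if (!is.null(genes)) v <- v[v$hugo_symbol %in% genes, , drop = FALSE]
  if (!is.null(hgvsp)) v <- v[v$hgvsp_short %in% hgvsp, , drop = FALSE]
  if (!is.null(classes)) v <- v[v$variant_classification %in% classes, , drop = FALSE]
  if (!is.null(hotspot)) v <- v[isTRUE(hotspot) == dplyr::coalesce(v$hotspot, FALSE), , drop = FALSE]
  nrow(v) > 0
}

ev_gene_status <- function(e, gene) {
  g <- filter(e$gene_cn, .data$gene == !!gene)
  if (nrow(g) == 0) "neutral" else g$status[1]
}

ev_arm_is <- function(e, arms, statuses) {
  a <- filter(e$arm_cn, .data$arm %in% arms, .data$status %in% statuses)
  nrow(a) > 0
}

ev_z <- function(e, gene) {
  x <- filter(e$expression, .data$gene == !!gene)
  if (nrow(x) == 0) NA_real_ else x$z[1]
}

ev_tpm <- function(e, gene) {
  x <- filter(e$expression, .data$gene == !!gene)
  if (nrow(x) == 0) NA_real_ else x$tpm[1]
}

ev_fusion <- function(e, names = NULL, partner = NULL) {
  f <- e$fusions
  if (nrow(f) == 0) return(FALSE)
  hit <- rep(FALSE, nrow(f))
  if (!is.null(names)) hit <- hit | f$fusion_name %in% names
  if (!is.null(partner)) hit <- hit | f$gene5 %in% partner | f$gene3 %in% partner
  any(hit)
}

ev_lof <- function(e, genes, cfg) {
  ev_variant(e, genes = genes, classes = cfg$lof_classes)
}

ev_overexpressed <- function(e, gene, cfg) {
  z <- ev_z(e, gene)
  !is.na(z) && z >= cfg$expr_z_high
}
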