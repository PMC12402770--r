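#' Classify TP53 status per sample
#'
#' Integrates somatic/germline TP53 variants, copy-number deletion,
#' structural-variant disruption and an RNA-based inactivation classifier
#' score into one of three labels, evaluated in order:
#'
#' 1. **activated** — any somatic variant is one of the gain-of-function
#'    changes p.R273C or p.R248W;
#' 2. **lost** — any of: (i) a hotspot-database TP53 mutation; (ii) two or
#'    more distinct TP53 alterations among SNVs (distinct protein
#'    changes), copy-number deletion, and SV disruption, consistent with
#'    biallelic inactivation; (iii) a somatic variant together with an
#'    LFS-associated pathogenic germline variant; (iv) an LFS germline
#'    variant with an inactivation classifier score strictly above
#'    `cfg$tp53_classifier_cutoff` (0.5);
#' 3. **none** otherwise.
#'
#' @param variants Tibble of TP53 variants: `sample_id`, `hgvsp`
#'   (protein change), `origin` (`"somatic"`/`"germline"`), logical
#'   `hotspot_db` (IARC/MSKCC hotspot membership) and `lfs_associated`.
#' @param sample_flags Tibble `sample_id`, logical `cnv_deleted`,
#'   `sv_disrupted`, numeric `classifier_score` (`NA` when no RNA).
#' @param cfg A [rule_config()].
#' @return Tibble `sample_id`, `tp53_status`
#'   (`"activated"`/`"lost"`/`"none"`), `evidence_used`.
#' @examples
#' classify_tp53(
#'   tibble::tibble(sample_id = "BS_1", hgvsp = "p.R273C",
#'     origin = "somatic", hotspot_db = FALSE, lfs_associated = FALSE),
#'   tibble::tibble(sample_id = "BS_1", cnv_deleted = FALSE,
#'     sv_disrupted = FALSE, classifier_score = NA_real_))
#' @export
classify_tp53 <- function(variants, sample_flags, cfg = rule_config()) {
  gof <- c("p.R273C", "p.R248W")
  samples <- union(variants$sample_id, sample_flags$sample_id)
  map_dfr(samples, function(s) {
    v <- filter(variants, .data$sample_id == s)
    f <- filter(sample_flags, .data$sample_id == s)
    cnv_del <- nrow(f) > 0 && isTRUE(any(f$cnv_deleted))
    sv_dis <- nrow(f) > 0 && isTRUE(any(f$sv_disrupted))
    score <- if (nrow(f) > 0) suppressWarnings(max(f$classifier_score, na.rm = TRUE)) else NA_real_
    if (!is.finite(score)) score <- NA_real_
    somatic <- filter(v, .data$origin == "somatic")
    germ_lfs <- any(v$origin == "germline" & v$lfs_associated)
    status <- "none"; used <- character()
    if (any(somatic$hgvsp %in% gof)) {
      status <- "activated"; used <- "gain_of_function_variant"
    } else if (nrow(v) > 0 && any(v$hotspot_db)) {
      status <- "lost"; used <- "hotspot_db_variant"
    } else if (n_distinct(somatic$hgvsp) + cnv_del + sv_dis >= 2) {
      status <- "lost"
      used <- c(if (nrow(somatic)) "somatic_variant",
                if (cnv_del) "cnv_deletion", if (sv_dis) "sv_disruption")
    } else if (nrow(somatic) > 0 && germ_lfs) {
      status <- "lost"; used <- c("somatic_variant", "lfs_germline")
    } else if (germ_lfs && !is.na(score) && score > cfg$tp53_classifier_cutoff) {
      status <- "lost"; used <- c("lfs_germline", "classifier_score")
    }
    tibble(sample_id = s, tp53_status = status,
           evidence_used = paste(used, collapse = ","))
  }) |>
    arrange(.data$sample_id)
}
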